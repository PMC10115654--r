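# Site-saturation-mutagenesis enrichment from pooled sequencing counts:
# enrichment = log10 of (mutant ratio in the peptide-bound pool) over
# (mutant ratio in the expression pool).

#' Read an SSM count table
#'
#' @param path TSV with columns position, aa, boundCount, exprCount.
#' @return data.frame of class \code{SSMCounts}.
#' @export
readSSMCounts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("position", "aa", "boundCount", "exprCount")
  if (!all(need %in% names(df)))
    stop("SSM counts must have columns ", paste(need, collapse = ", "))
  ssmCounts(df)
}

#' Validate an SSM count table
#' @param df data.frame with columns position, aa, boundCount, exprCount.
#' @return the validated data.frame (class \code{SSMCounts}).
#' @export
ssmCounts <- function(df) {
  stopifnot(all(df$boundCount >= 0), all(df$exprCount >= 0))
  class(df) <- c("SSMCounts", "data.frame")
  df
}

#' Compute SSM enrichment values
#'
#' Each variant's ratio is computed within the full pool (count plus
#' pseudocount over pool total plus pseudocount times cells), and the
#' enrichment is \code{E = log10(ratioBound / ratioExpr)}. Entries whose
#' larger raw count is below \code{minCount} are masked. With
#' \code{perPosition = TRUE}, ratios are normalised within each position
#' instead of the full pool.
#'
#' @param counts an [ssmCounts()] data.frame.
#' @param pseudocount added to every count, default 0.5.
#' @param minCount mask threshold on max(bound, expr), default 5.
#' @param perPosition normalise within positions, default FALSE.
#' @return data.frame (position, aa, E, masked) of class
#'   \code{EnrichmentMatrix}.
#' @export
computeEnrichment <- function(counts, pseudocount = 0.5, minCount = 5,
                              perPosition = FALSE) {
  if (sum(counts$boundCount) == 0 || sum(counts$exprCount) == 0)
    stop("contract violation: zero-total pool")
  cells <- nrow(counts)
  if (perPosition) {
    E <- rep(NA_real_, cells)
    for (p in unique(counts$position)) {
      i <- counts$position == p
      nb <- sum(i)
      rb <- (counts$boundCount[i] + pseudocount) /
        (sum(counts$boundCount[i]) + pseudocount * nb)
      re <- (counts$exprCount[i] + pseudocount) /
        (sum(counts$exprCount[i]) + pseudocount * nb)
      E[i] <- log10(rb / re)
    }
  } else {
    rb <- (counts$boundCount + pseudocount) /
      (sum(counts$boundCount) + pseudocount * cells)
    re <- (counts$exprCount + pseudocount) /
      (sum(counts$exprCount) + pseudocount * cells)
    E <- log10(rb / re)
  }
  out <- data.frame(position = counts$position, aa = counts$aa, E = E,
                    masked = pmax(counts$boundCount,
                                  counts$exprCount) < minCount)
  class(out) <- c("EnrichmentMatrix", "data.frame")
  out
}

#' Export an enrichment matrix as a long-format heat-map table
#'
#' One row per (position, mutant aa): position, wild-type aa, mutant aa,
#' E (empty when masked), masked flag, and a wild-type indicator.
#'
#' @param matrix an [computeEnrichment()] result.
#' @param wildtype optional named character: wild-type aa per position.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
exportHeatmapTable <- function(matrix, wildtype = NULL, path) {
  wt <- if (is.null(wildtype)) rep(NA_character_, nrow(matrix)) else
    unname(wildtype[as.character(matrix$position)])
  df <- data.frame(position = matrix$position, wildtypeAA = wt,
                   mutantAA = matrix$aa,
                   E = ifelse(matrix$masked, "", format(matrix$E,
                                                        digits = 10)),
                   masked = matrix$masked,
                   isWildtype = !is.na(wt) & wt == matrix$aa)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read back a heat-map table written by [exportHeatmapTable()]
#' @param path TSV path.
#' @return data.frame with E as numeric (NA where masked).
#' @export
readHeatmapTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(E = "character"))
  df$E <- suppressWarnings(as.numeric(df$E))
  df
}
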