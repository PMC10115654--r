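# Proteome scanning for targetable tandem-triplet sub-sequences, and
# tandem-repeat counting.

#' The designable amino-acid triplet set
#'
#' The twelve tripeptide units for which binder modules exist:
#' LRP PEW PLP IYP PKW IRP LRT LRN LRQ RRN PSR PRQ.
#'
#' @param triplets optional custom character vector of 3-letter (one-letter
#'   alphabet) strings.
#' @return validated uppercase character vector.
#' @export
tripletSet <- function(triplets = c("LRP", "PEW", "PLP", "IYP", "PKW",
                                    "IRP", "LRT", "LRN", "LRQ", "RRN",
                                    "PSR", "PRQ")) {
  triplets <- toupper(triplets)
  ok <- nchar(triplets) == 3L &
    !grepl("[^ACDEFGHIKLMNPQRSTVWY]", triplets)
  if (!all(ok)) stop("invalid triplet(s): ",
                     paste(triplets[!ok], collapse = ", "))
  unique(triplets)
}

#' Scan sequences for runs of designable triplets
#'
#' For each sequence and each of the three frame offsets, reports maximal
#' runs of consecutive in-set triplets of at least \code{minUnits} units.
#' Non-standard letters (X, B, Z, U, ...) break runs. Overlapping hits from
#' different offsets are all reported unless \code{collapse} is TRUE, in
#' which case overlapping hits are merged keeping the longest.
#'
#' @param sequences named character vector of amino-acid sequences, or a
#'   path to a FASTA file (read via Biostrings).
#' @param triplets a [tripletSet()].
#' @param minUnits minimum consecutive units, default 2.
#' @param collapse merge overlapping hits keeping the longest, default
#'   FALSE.
#' @return data.frame (seqId, start0, end, nUnits, units, subseq) ordered
#'   by (seqId, start0); \code{start0} is 0-based, \code{end} exclusive.
#' @export
scanSequences <- function(sequences, triplets = tripletSet(), minUnits = 2L,
                          collapse = FALSE) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- list()
  for (sid in names(sequences)) {
    s <- toupper(sequences[[sid]])
    L <- nchar(s)
    if (!length(triplets) || L < 3L * minUnits) next
    for (off in 0:2) {
      starts <- seq(off + 1L, L - 2L, by = 3L)
      if (!length(starts)) next
      tri <- substring(s, starts, starts + 2L)
      inSet <- tri %in% triplets
      r <- rle(inSet)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= minUnits)) {
        i0 <- starts[begs[k]] - 1L          # 0-based
        nun <- r$lengths[k]
        rows[[length(rows) + 1L]] <-
          data.frame(seqId = sid, start0 = i0, end = i0 + 3L * nun,
                     nUnits = nun,
                     units = paste(tri[begs[k]:ends[k]], collapse = ","),
                     subseq = substr(s, i0 + 1L, i0 + 3L * nun),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqId = character(), start0 = integer(), end = integer(),
               nUnits = integer(), units = character(),
               subseq = character(), stringsAsFactors = FALSE)
  out <- out[order(out$seqId, out$start0), , drop = FALSE]
  rownames(out) <- NULL
  if (collapse && nrow(out)) out <- collapseHits(out)
  out
}

# merge overlapping hits within a sequence, keeping the longest (ties by
# earlier start)
collapseHits <- function(hits) {
  keep <- logical(nrow(hits))
  for (sid in unique(hits$seqId)) {
    idx <- which(hits$seqId == sid)
    h <- hits[idx, ]
    ord <- idx[order(-h$nUnits, h$start0)]
    taken <- matrix(numeric(0), ncol = 2)
    for (i in ord) {
      s <- hits$start0[i]; e <- hits$end[i]
      if (!nrow(taken) || all(e <= taken[, 1] | s >= taken[, 2])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$seqId, out$start0), , drop = FALSE]
}

#' Maximum tandem-repeat count of a unit in a sequence
#'
#' @param sequence amino-acid string.
#' @param unit repeat unit (length >= 1).
#' @return list(count, position) with the maximum number of consecutive
#'   exact copies and the 0-based position of the leftmost maximal run;
#'   count 0 and position NA when absent.
#' @export
tandemRepeatCount <- function(sequence, unit) {
  if (nchar(unit) < 1L) stop("contract violation: empty unit")
  s <- toupper(sequence); u <- toupper(unit)
  L <- nchar(s); k <- nchar(u)
  best <- 0L; bestPos <- NA_integer_
  i <- 1L
  while (i + k - 1L <= L) {
    if (substr(s, i, i + k - 1L) == u) {
      j <- i; cnt <- 0L
      while (j + k - 1L <= L && substr(s, j, j + k - 1L) == u) {
        cnt <- cnt + 1L; j <- j + k
      }
      if (cnt > best) { best <- cnt; bestPos <- i - 1L }
      i <- i + 1L
    } else i <- i + 1L
  }
  list(count = best, position = bestPos)
}

#' Rank scan hits
#'
#' Descending number of units; ties broken by (seqId, start0) ascending;
#' stable.
#'
#' @param hits data.frame from [scanSequences()].
#' @return reordered data.frame.
#' @export
rankHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  out <- hits[order(-hits$nUnits, hits$seqId, hits$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The 103-residue disordered-region fragment of human ZFC3H1
#'
#' The fragment containing the (PLP)x4 targeting sequence followed by
#' PEDPEQPPKPPF, used as the worked proteome-scanning example.
#'
#' @return a single character string (103 residues).
#' @export
zfc3h1Fragment <- function() {
  paste0("LPPPPQVSSLPPLSQPYVEGLCVSLEPLPPLPPLPPLPPEDPEQPPKPPFADEEEEEE",
         "MLLREELLKSLANKRAFKPEETSSNSDPPSPPVLNNSHPVPRSNL")
}
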