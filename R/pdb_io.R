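# PDB reading and writing for BackboneChain objects, through bio3d.

#' Read backbone chains from a PDB file
#'
#' Parses backbone atoms (N, CA, C, O, CB and any side-chain heavy atoms)
#' per chain. Residues missing any of N, CA, C, O raise an error naming
#' the residue. Alternate locations other than blank or 'A' are dropped
#' with a warning ('A' kept).
#'
#' @param path PDB file.
#' @param unitLength,nUnits optional repeat bookkeeping applied to every
#'   chain (0 = non-repeating).
#' @return named list of [BackboneChain-class], one per chain.
#' @export
readBackbonePDB <- function(path, unitLength = 0L, nUnits = 0L) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(at$alt != "" & !is.na(at$alt) & at$alt != "A")) {
    warning("alternate locations found; keeping altloc 'A'")
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  at <- at[at$type == "ATOM", ]
  out <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, ]
    resnos <- unique(sub$resno)
    for (r in resnos) {
      present <- sub$elety[sub$resno == r]
      missing <- setdiff(c("N", "CA", "C", "O"), present)
      if (length(missing))
        stop("residue ", r, " chain ", ch, " missing backbone atom(s): ",
             paste(missing, collapse = ", "))
    }
    atoms <- data.frame(resno = match(sub$resno, resnos),
                        resname = sub$resid, atom = sub$elety,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    out[[ch]] <- new("BackboneChain", atoms = atoms,
                     unitLength = as.integer(unitLength),
                     nUnits = as.integer(nUnits), chainId = ch)
  }
  out
}

#' Write chains to a PDB file
#'
#' One model; protein chain first (id A by convention), peptide chain B;
#' 1-based residue numbering, occupancy 1.00, element column populated
#' from the first letter of the atom name.
#'
#' @param chains a [BackboneChain-class] or list of them.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeBackbonePDB <- function(chains, path) {
  if (methods::is(chains, "BackboneChain")) chains <- list(chains)
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    at <- ch@atoms
    ord <- order(at$resno)
    at <- at[ord, ]
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial,
        formatAtomName(at$atom[i]),
        at$resname[i], ch@chainId, at$resno[i],
        at$x[i], at$y[i], at$z[i], 1.00, 0.00,
        substr(at$atom[i], 1, 1)))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# PDB atom-name column convention: names of length < 4 start in column 14
formatAtomName <- function(nm) {
  ifelse(nchar(nm) >= 4, nm, paste0(" ", nm))
}
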