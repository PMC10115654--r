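# Superhelical-compatibility matching and 2-DOF grid docking with hash
# lookup: peptides and proteins whose superhelical parameters match (for
# some integral multiple of peptide repeat units) are aligned on a common
# z axis; the peptide is rotated about and slid along the axis; docks
# without steric clash are scanned for hash-supported bidentate ladders,
# matched side chains are installed at all repeat-equivalent positions, and
# the rigid placement is refined.

#' Superhelix matching criteria
#'
#' A protein-peptide pair is compatible when, for some multiple k of
#' peptide repeat units, the rise differs by at most \code{maxDeltaRise},
#' the twist by at most \code{maxDeltaTwist}, and the radii differ by at
#' least \code{minDeltaRadius} (the radius gap is what keeps the wrapped
#' peptide from clashing with the protein body).
#'
#' @param maxDeltaRise Angstrom, default 0.2.
#' @param maxDeltaTwist degrees, default 5.
#' @param minDeltaRadius Angstrom, default 4.
#' @param kMax maximum integral multiple of peptide units, default 3.
#' @param signedTwist compare signed twist (TRUE) or |twist| with a
#'   same-handedness requirement (FALSE, default).
#' @return list of class \code{MatchCriteria}.
#' @export
matchCriteria <- function(maxDeltaRise = 0.2, maxDeltaTwist = 5,
                          minDeltaRadius = 4, kMax = 3L,
                          signedTwist = FALSE) {
  stopifnot(maxDeltaRise > 0, maxDeltaTwist > 0, minDeltaRadius > 0,
            kMax >= 1L)
  structure(list(maxDeltaRise = maxDeltaRise, maxDeltaTwist = maxDeltaTwist,
                 minDeltaRadius = minDeltaRadius, kMax = as.integer(kMax),
                 signedTwist = signedTwist),
            class = "MatchCriteria")
}

#' Match a protein and a peptide by superhelical parameters
#'
#' Composes the peptide unit transform k = 1..kMax times, decomposes each
#' composite, and compares against the protein parameters.
#'
#' @param protein,peptideUnit [SuperhelixParams-class] of the protein
#'   repeat and the peptide repeat unit.
#' @param criteria a [matchCriteria()].
#' @return list with \code{pass}, \code{bestK}, and a data.frame
#'   \code{deltas} (k, dRise, dTwist, dRadius, sameHand, pass).
#' @export
matchSuperhelices <- function(protein, peptideUnit,
                              criteria = matchCriteria()) {
  rows <- lapply(seq_len(criteria$kMax), function(k) {
    Tk <- Reduce(composeTransforms,
                 rep(list(buildTransform(peptideUnit)), k))
    pk <- tryCatch(screwDecompose(Tk, peptideUnit@axisPoint +
                                    peptideUnit@radius *
                                    orthoUnit(peptideUnit@axisDirection)),
                   error = function(e) NULL)
    if (is.null(pk))
      return(data.frame(k = k, dRise = NA, dTwist = NA, dRadius = NA,
                        sameHand = NA, pass = FALSE))
    # radius is invariant under composition; carry the unit radius
    dRise <- abs(pk@rise - protein@rise)
    dTw <- if (criteria$signedTwist) {
      d <- abs(pk@twist - protein@twist) %% 360
      min(d, 360 - d)
    } else {
      abs(abs(pk@twist) - abs(protein@twist))
    }
    sameHand <- sign(pk@twist) == sign(protein@twist)
    dRad <- abs(peptideUnit@radius - protein@radius)
    pass <- dRise <= criteria$maxDeltaRise &&
      dTw <= criteria$maxDeltaTwist &&
      dRad >= criteria$minDeltaRadius &&
      (criteria$signedTwist || sameHand)
    data.frame(k = k, dRise = dRise, dTwist = dTw, dRadius = dRad,
               sameHand = sameHand, pass = pass)
  })
  deltas <- do.call(rbind, rows)
  passing <- deltas$k[deltas$pass]
  list(pass = length(passing) > 0,
       bestK = if (length(passing)) min(passing) else NA_integer_,
       deltas = deltas)
}

# some unit vector orthogonal to u
orthoUnit <- function(u) {
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  v / sqrt(sum(v^2))
}

#' Count steric clashes between two chains
#'
#' Backbone-atom pairs (N, CA, C, O) closer than \code{cutoff} plus CB-CB
#' pairs closer than \code{cbCutoff}. A pair at exactly the cutoff is not
#' a clash (strict inequality).
#'
#' @param protein,peptide [BackboneChain-class] objects (the peptide
#'   already at its docked position).
#' @param cutoff backbone cutoff (A), default 2.8.
#' @param cbCutoff CB-CB cutoff (A), default 3.0.
#' @return integer clash count.
#' @export
clashCheck <- function(protein, peptide, cutoff = 2.8, cbCutoff = 3.0) {
  pa <- protein@atoms[protein@atoms$atom %in% c("N", "CA", "C", "O"), ]
  pb <- peptide@atoms[peptide@atoms$atom %in% c("N", "CA", "C", "O"), ]
  n1 <- crossDistCount(as.matrix(pa[, c("x", "y", "z")]),
                       as.matrix(pb[, c("x", "y", "z")]), cutoff)
  ca <- protein@atoms[protein@atoms$atom == "CB", ]
  cb <- peptide@atoms[peptide@atoms$atom == "CB", ]
  n2 <- if (nrow(ca) && nrow(cb))
    crossDistCount(as.matrix(ca[, c("x", "y", "z")]),
                   as.matrix(cb[, c("x", "y", "z")]), cbCutoff) else 0L
  as.integer(n1 + n2)
}

crossDistCount <- function(A, B, cutoff) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sum(d2 < cutoff^2)
}

#' Two-degree-of-freedom grid dock along the shared superhelical axis
#'
#' Both chains must be pre-aligned to the z axis ([alignAxisToZ()]).
#' Enumerates rotations about z in steps of \code{stepR} over a full turn
#' and translations along z in steps of \code{stepT} over one protein
#' repeat rise; clashing placements are discarded.
#'
#' @param protein,peptide aligned [BackboneChain-class] objects.
#' @param stepT translation step (A), default 1.0.
#' @param stepR rotation step (degrees), default 10.
#' @param proteinParams optional precomputed [SuperhelixParams-class] of
#'   the protein (for the rise span).
#' @param axisTol maximum axis deviation (degrees) tolerated before the
#'   inputs are rejected as unaligned, default 1.
#' @return list of [Dock-class] candidates (clash-free).
#' @export
gridDock <- function(protein, peptide, stepT = 1.0, stepR = 10,
                     proteinParams = NULL, axisTol = 1) {
  if (is.null(proteinParams)) proteinParams <- chainSuperhelix(protein)
  pepParams <- tryCatch(chainSuperhelix(peptide, angleTol = 0.1),
                        error = function(e) NULL)
  # the screw axis of a nearly twist-free chain is ill-conditioned; such
  # chains are checked against the line through their unit centroids
  checkAxis <- function(p, chain) {
    u <- if (!is.null(p) && abs(p@twist) >= 5) p@axisDirection else {
      cen <- t(vapply(seq_len(chain@nUnits), function(i)
        colMeans(unitBackboneCoords(chain, i)), numeric(3)))
      svd(sweep(cen, 2, colMeans(cen)))$v[, 1]
    }
    dev <- acos(min(1, abs(sum(u * c(0, 0, 1))))) * 180 / pi
    if (dev > axisTol)
      stop("contract violation: chains must be aligned to z before docking",
           " (axis deviation ", round(dev, 2), " deg)")
  }
  checkAxis(proteinParams, protein)
  checkAxis(pepParams, peptide)
  rots <- seq(0, 360 - stepR, by = stepR)
  span <- proteinParams@rise
  trans <- seq(0, span, by = stepT)
  out <- list()
  for (r in rots) for (tz in trans) {
    xf <- rigidTransform(rotationAboutAxis(c(0, 0, 1), r), c(0, 0, tz))
    pep <- transformChain(peptide, xf)
    cl <- clashCheck(protein, pep)
    if (cl > 0L) next
    out[[length(out) + 1L]] <-
      new("Dock", rotDeg = r, transA = tz, transform = xf,
          matches = emptyMatches(), clashes = 0L, score = NA_real_)
  }
  out
}

emptyMatches <- function() {
  data.frame(protRes = integer(), pepRes = integer(), residue = character(),
             class = character(), chi1 = numeric(), chi2 = numeric(),
             chi3 = numeric(), chi4 = numeric(), score = numeric(),
             equivClass = integer(), stringsAsFactors = FALSE)
}

setMethod("show", "Dock", function(object) {
  cat(sprintf("Dock: rot %.1f deg, trans %.2f A, %d matches, %d clashes%s\n",
              object@rotDeg, object@transA, nrow(object@matches),
              object@clashes, if (object@refined) " (refined)" else ""))
})

# Cbeta-proxy point of every residue: CB when present, else CA displaced
# 1.5 A along the local pseudo-CB direction
cbProxy <- function(chain) {
  res <- sort(unique(chain@atoms$resno))
  out <- matrix(NA_real_, length(res), 3)
  for (i in seq_along(res)) {
    cb <- resAtom(chain, res[i], "CB")
    if (!is.null(cb)) { out[i, ] <- cb; next }
    N <- resAtom(chain, res[i], "N"); CA <- resAtom(chain, res[i], "CA")
    C <- resAtom(chain, res[i], "C")
    v <- placeCB(N, CA, C) - CA
    out[i, ] <- CA + 1.5 * v / sqrt(sum(v^2))
  }
  rownames(out) <- res
  out
}

#' Find hash-supported bidentate interactions for a dock
#'
#' For each protein-peptide residue pair within \code{pairCutoff} (between
#' Cbeta-proxy points), computes the inter-backbone-frame transform and the
#' peptide residue's key torsions, queries each table, installs hit side
#' chains from the stored identity and chi angles, and re-scores them with
#' [evaluateBidentate()]. Matches are propagated to all repeat-equivalent
#' residue pairs and grouped into equivalence classes.
#'
#' @param dock a [Dock-class] from [gridDock()].
#' @param protein the protein [BackboneChain-class].
#' @param peptide the undocked peptide [BackboneChain-class] (the dock's
#'   transform is applied internally).
#' @param tables list of [InteractionHashTable-class] objects.
#' @param pairCutoff Cbeta-proxy distance cutoff (A), default 10.
#' @param criteria re-scoring [hbondCriteria()]; one bin width of
#'   geometric slack is already implied by the hashing, so re-scored
#'   matches keep their realized score but are not re-filtered by the
#'   acceptance windows unless \code{revalidate} is TRUE.
#' @param revalidate drop installed side chains that fail the criteria
#'   windows after installation (default TRUE).
#' @param neighbours passed to [queryHash()].
#' @return the [Dock-class] with its \code{matches} slot filled.
#' @export
findHashMatches <- function(dock, protein, peptide, tables,
                            pairCutoff = 10, criteria = hbondCriteria(),
                            revalidate = TRUE, neighbours = FALSE) {
  if (dock@clashes > 0L) stop("dock must be clash-free")
  pep <- transformChain(peptide, dock@transform)
  protCB <- cbProxy(protein); pepCB <- cbProxy(pep)
  protRes <- as.integer(rownames(protCB))
  pepRes <- as.integer(rownames(pepCB))
  pepTor <- measureTorsions(pep)
  d2 <- outer(rowSums(protCB^2), rowSums(pepCB^2), "+") -
    2 * tcrossprod(protCB, pepCB)
  pepFrames <- lapply(pepRes, function(j) residueFrame(pep, j))
  protFrames <- lapply(protRes, function(i) residueFrame(protein, i))
  rows <- list()
  for (i in seq_along(protRes)) for (j in seq_along(pepRes)) {
    if (d2[i, j] > pairCutoff^2) next
    rel <- composeTransforms(invertTransform(pepFrames[[j]]),
                             protFrames[[i]])
    for (tab in tables) {
      cls <- tab@metadata$class
      tor <- keyTorsions(cls, pepTor$phi[j], pepTor$psi[j],
                         chi1 = pepChi1(pep, pepRes[j]))
      if (any(is.na(tor))) next
      hits <- tryCatch(
        queryHash(tab, rel, tor, tab@metadata$config,
                  neighbours = neighbours),
        error = function(e) list())
      for (h in hits) {
        # install the stored side chain on the protein residue frame
        sc <- tryCatch(installAndScore(h, protein, protRes[i], pep,
                                       pepRes[j], criteria),
                       error = function(e) NULL)
        if (is.null(sc)) next
        if (revalidate && !sc$accept) next
        chis <- c(h$chis, rep(NA_real_, 4 - length(h$chis)))
        rows[[length(rows) + 1L]] <-
          data.frame(protRes = protRes[i], pepRes = pepRes[j],
                     residue = h$residue, class = cls,
                     chi1 = chis[1], chi2 = chis[2], chi3 = chis[3],
                     chi4 = chis[4], score = sc$score, equivClass = NA)
      }
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else emptyMatches()
  m <- propagateEquivalents(m, protein, pep, tables, criteria, revalidate)
  dock@matches <- m
  dock@score <- if (nrow(m)) sum(m$score) else NA_real_
  dock
}

pepChi1 <- function(pep, resno) {
  og <- resAtom(pep, resno, "OG")
  if (is.null(og)) og <- resAtom(pep, resno, "OG1")
  if (is.null(og)) return(NA_real_)
  dihedral(resAtom(pep, resno, "N"), resAtom(pep, resno, "CA"),
           resAtom(pep, resno, "CB"), og)
}

# install a hash entry's side chain on the protein residue and re-score it
# against the peptide target residue
installAndScore <- function(entry, protein, protRes, pep, pepRes, criteria) {
  N <- resAtom(protein, protRes, "N")
  CA <- resAtom(protein, protRes, "CA")
  C <- resAtom(protein, protRes, "C")
  atoms <- buildSideChain(entry$residue, N, CA, C, entry$chis)
  xf <- groupFrameFromAtoms(entry$class, atoms)
  ev <- evaluateBidentate(xf, pep, pepRes, entry$class, criteria)
  list(accept = ev$accept, score = if (is.finite(ev$score)) ev$score else
    softBidentate(xf, targetAtoms(pep, pepRes, entry$class), entry$class,
                  criteria), atoms = atoms)
}

# propagate each found interaction to all repeat-equivalent residue pairs
# and assign equivalence-class ids
propagateEquivalents <- function(m, protein, pep, tables, criteria,
                                 revalidate) {
  if (nrow(m) == 0L) { m$equivClass <- integer(0); return(m) }
  ku <- protein@unitLength; nu <- protein@nUnits
  kp <- pep@unitLength
  if (ku < 1L || kp < 1L) { m$equivClass <- seq_len(nrow(m)); return(m) }
  critByClass <- list()
  key <- function(pr, pp, res) paste(pr, pp, res)
  seen <- vapply(seq_len(nrow(m)),
                 function(i) key(m$protRes[i], m$pepRes[i], m$residue[i]),
                 character(1))
  base <- m; base$equivClass <- NA_integer_
  out <- list(); eq <- 0L
  done <- character(0)
  for (i in seq_len(nrow(base))) {
    k0 <- paste((base$protRes[i] - 1L) %% ku, (base$pepRes[i] - 1L) %% kp,
                base$residue[i], base$class[i])
    if (k0 %in% done) next
    done <- c(done, k0)
    eq <- eq + 1L
    # all equivalent offsets present in both chains
    for (u in seq_len(nu)) {
      pr <- (base$protRes[i] - 1L) %% ku + (u - 1L) * ku + 1L
      shiftUnits <- u - ((base$protRes[i] - 1L) %/% ku + 1L)
      pp <- base$pepRes[i] + shiftUnits * kp
      if (pp < 1L || pp > nResidues(pep)) next
      if (pr > nResidues(protein)) next
      entry <- list(residue = base$residue[i],
                    chis = as.numeric(base[i, c("chi1", "chi2", "chi3",
                                                "chi4")]),
                    class = base$class[i])
      entry$chis <- entry$chis[!is.na(entry$chis)]
      sc <- tryCatch(installAndScore(entry, protein, pr, pep, pp, criteria),
                     error = function(e) NULL)
      if (is.null(sc)) next
      if (revalidate && !sc$accept) next
      chis <- c(entry$chis, rep(NA_real_, 4 - length(entry$chis)))
      out[[length(out) + 1L]] <-
        data.frame(protRes = pr, pepRes = pp, residue = entry$residue,
                   class = entry$class, chi1 = chis[1], chi2 = chis[2],
                   chi3 = chis[3], chi4 = chis[4], score = sc$score,
                   equivClass = eq)
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else emptyMatches()
}

#' Refine a dock by rigid-body minimisation of the bidentate scores
#'
#' Derivative-free pattern search over the six rigid degrees of freedom of
#' the peptide, minimising the summed soft bidentate scores of the dock's
#' matches plus a clash penalty. The refined score never exceeds the
#' initial score and the dock stays clash-free.
#'
#' @param dock a [Dock-class] with at least one match.
#' @param protein,peptide chains as passed to [findHashMatches()].
#' @param criteria an [hbondCriteria()].
#' @param maxit iteration cap (default 200).
#' @return the refined [Dock-class] (slot \code{refined} set; slot
#'   \code{score} updated; attribute \code{converged} records optimizer
#'   status).
#' @export
refineDock <- function(dock, protein, peptide, criteria = hbondCriteria(),
                       maxit = 200) {
  if (nrow(dock@matches) < 1L) stop("refineDock needs >= 1 match")
  m <- dock@matches
  entries <- lapply(seq_len(nrow(m)), function(i) {
    chis <- as.numeric(m[i, c("chi1", "chi2", "chi3", "chi4")])
    list(residue = m$residue[i], chis = chis[!is.na(chis)],
         class = m$class[i], protRes = m$protRes[i], pepRes = m$pepRes[i])
  })
  protFrames <- lapply(entries, function(e) {
    atoms <- buildSideChain(e$residue, resAtom(protein, e$protRes, "N"),
                            resAtom(protein, e$protRes, "CA"),
                            resAtom(protein, e$protRes, "C"), e$chis)
    groupFrameFromAtoms(e$class, atoms)
  })
  pep0 <- transformChain(peptide, dock@transform)
  cen <- colMeans(atomCoords(pep0, "CA"))
  objective <- function(x) {
    pert <- composeTransforms(
      rigidTransform(diag(3), cen),
      composeTransforms(poseTransform(x),
                        rigidTransform(diag(3), -cen)))
    pep <- transformChain(pep0, pert)
    s <- 0
    for (i in seq_along(entries)) {
      tgt <- tryCatch(targetAtoms(pep, entries[[i]]$pepRes,
                                  entries[[i]]$class),
                      error = function(e) NULL)
      if (is.null(tgt)) return(1e6)
      s <- s + softBidentate(protFrames[[i]], tgt, entries[[i]]$class,
                             criteria)
    }
    cl <- clashCheck(protein, pep)
    s + 100 * cl
  }
  fit <- patternSearch(objective, rep(0, 6),
                       step0 = c(rep(0.1, 3), rep(2, 3)),
                       minStep = 1e-4, maxit = maxit)
  pert <- composeTransforms(
    rigidTransform(diag(3), cen),
    composeTransforms(poseTransform(fit$par),
                      rigidTransform(diag(3), -cen)))
  dock@transform <- composeTransforms(pert, dock@transform)
  pepR <- transformChain(peptide, dock@transform)
  dock@clashes <- clashCheck(protein, pepR)
  # re-score matches at the refined pose
  sc <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    tgt <- targetAtoms(pepR, e$pepRes, e$class)
    softBidentate(protFrames[[i]], tgt, e$class, criteria)
  }, numeric(1))
  dock@matches$score <- sc
  dock@score <- fit$value
  dock@refined <- TRUE
  attr(dock, "converged") <- TRUE
  dock
}

#' Trim a peptide to the protein's repeat count
#'
#' Removes whole repeat units symmetrically from the termini (N-terminal
#' first on ties) until the peptide has exactly \code{nUnitsProtein} units.
#'
#' @param peptide a repeat [BackboneChain-class].
#' @param nUnitsProtein target unit count; the peptide must have at least
#'   as many units.
#' @return the trimmed [BackboneChain-class] (residues renumbered from 1).
#' @export
trimPeptide <- function(peptide, nUnitsProtein) {
  k <- peptide@unitLength; n <- peptide@nUnits
  if (n < nUnitsProtein)
    stop("contract violation: peptide has fewer units than the protein")
  drop <- n - nUnitsProtein
  dropN <- ceiling(drop / 2); dropC <- floor(drop / 2)
  res <- sort(unique(peptide@atoms$resno))
  keep <- res[(dropN * k + 1L):(length(res) - dropC * k)]
  at <- peptide@atoms[peptide@atoms$resno %in% keep, ]
  at$resno <- match(at$resno, keep)
  new("BackboneChain", atoms = at, unitLength = k,
      nUnits = as.integer(nUnitsProtein), chainId = peptide@chainId)
}

#' Minimum match-count filter for docks
#'
#' Default threshold: one bidentate interaction per repeat unit shared by
#' the dock.
#'
#' @param docks list of [Dock-class] objects.
#' @param minMatches integer threshold; docks with fewer matches are
#'   discarded.
#' @return filtered list.
#' @export
filterDocksByMatches <- function(docks, minMatches) {
  Filter(function(d) nrow(d@matches) >= minMatches, docks)
}
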