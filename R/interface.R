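# Interface definition, burial and hydrogen-bond satisfaction metrics,
# shape complementarity, design selection thresholds, mutation-scan
# acceptance logic, symmetry bookkeeping and forward-docking convergence —
# all against a pluggable interaction score.

#' Construct a protein-peptide complex
#' @param protein,peptide [BackboneChain-class] objects.
#' @return A [PeptideComplex-class].
#' @export
peptideComplex <- function(protein, peptide) {
  new("PeptideComplex", protein = protein, peptide = peptide)
}

setMethod("show", "PeptideComplex", function(object) {
  cat(sprintf("PeptideComplex: protein %d residues / peptide %d residues\n",
              nResidues(object@protein), nResidues(object@peptide)))
})

#' Interface definition by neighbour distance
#'
#' @param designableRange any-atom distance (A) within which residues are
#'   designable, default 9.
#' @param minimizeRange distance within which residues are movable during
#'   minimisation, default 11 (must be >= designableRange).
#' @return list of class \code{InterfaceDefinition}.
#' @export
interfaceDefinition <- function(designableRange = 9, minimizeRange = 11) {
  stopifnot(minimizeRange >= designableRange)
  structure(list(designableRange = designableRange,
                 minimizeRange = minimizeRange),
            class = "InterfaceDefinition")
}

#' Interface residue membership
#'
#' Residues with any-atom minimum distance to the other chain at or below
#' the designable range are designable; at or below the minimisation range
#' are movable. Designable is always a subset of movable.
#'
#' @param complex a [PeptideComplex-class].
#' @param defn an [interfaceDefinition()].
#' @return list with \code{proteinDesignable}, \code{proteinMovable},
#'   \code{peptideDesignable}, \code{peptideMovable} (residue numbers).
#' @export
interfaceResidues <- function(complex, defn = interfaceDefinition()) {
  a <- complex@protein@atoms; b <- complex@peptide@atoms
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("contract violation: two chains required")
  A <- as.matrix(a[, c("x", "y", "z")]); B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  minByRes <- function(d2m, resnos) {
    v <- apply(d2m, 1, min)
    vapply(split(v, resnos), min, numeric(1))
  }
  dA <- sqrt(minByRes(d2, a$resno))
  dB <- sqrt(minByRes(t(d2), b$resno))
  list(proteinDesignable = as.integer(names(dA))[dA <= defn$designableRange],
       proteinMovable = as.integer(names(dA))[dA <= defn$minimizeRange],
       peptideDesignable = as.integer(names(dB))[dB <= defn$designableRange],
       peptideMovable = as.integer(names(dB))[dB <= defn$minimizeRange])
}

# --- solvent accessibility (Shrake-Rupley dot sampling) -------------------

vdwRadius <- function(atomNames) {
  r <- rep(1.7, length(atomNames))
  r[grepl("^N", atomNames)] <- 1.55
  r[grepl("^O", atomNames)] <- 1.52
  r[grepl("^S", atomNames)] <- 1.8
  r[atomNames == "H"] <- 1.0
  r
}

# quasi-uniform sphere dots (golden spiral)
sphereDots <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param xyz n x 3 coordinate matrix.
#' @param radii per-atom van der Waals radii (A).
#' @param probe probe radius (A), default 1.4.
#' @param nDots dots per atom, default 256.
#' @return numeric vector of per-atom SASA (A^2).
#' @export
atomSASA <- function(xyz, radii, probe = 1.4, nDots = 256) {
  n <- nrow(xyz)
  dots <- sphereDots(nDots)
  R <- radii + probe
  out <- numeric(n)
  d2all <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(dots * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nDots)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      free <- free & d2 > R[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(free) / nDots
  }
  out
}

# polar atom inventory of a chain: backbone N (donor, except PRO/first) and
# O (acceptor), plus side-chain polar atoms we build (amide N/O,
# carboxylate O, hydroxyl O)
polarAtoms <- function(chain) {
  at <- chain@atoms
  don <- at$atom == "N" & at$resname != "PRO" |
    at$atom %in% c("ND2", "NE2", "OG", "OG1", "NE", "NH1", "NH2")
  acc <- at$atom %in% c("O", "OD1", "OE1", "OD2", "OE2", "OG", "OG1")
  bb <- at$atom %in% c("N", "O")
  data.frame(idx = seq_len(nrow(at)), resno = at$resno, atom = at$atom,
             donor = don, acceptor = acc, backbone = bb)
}

#' Count buried unsatisfied interface hydrogen-bond groups
#'
#' A buried polar atom (SASA below \code{burialCutoff}) is unsatisfied when
#' no partner in the complex forms a hydrogen bond with it under a relaxed
#' distance criterion (donor-acceptor heavy-atom distance window). Counts
#' are split into backbone and side-chain groups, over interface residues.
#'
#' @param complex a [PeptideComplex-class].
#' @param criteria an [hbondCriteria()] (distance window used).
#' @param burialCutoff per-atom SASA (A^2) below which an atom counts as
#'   buried, default 5.
#' @return list(unsatBB, unsatSC).
#' @export
countUnsatHbonds <- function(complex, criteria = hbondCriteria(),
                             burialCutoff = 5) {
  allAtoms <- rbind(cbind(complex@protein@atoms, chain = "A"),
                    cbind(complex@peptide@atoms, chain = "B"))
  xyz <- as.matrix(allAtoms[, c("x", "y", "z")])
  sasa <- atomSASA(xyz, vdwRadius(allAtoms$atom))
  polA <- polarAtoms(complex@protein)
  polB <- polarAtoms(complex@peptide)
  polB$idx <- polB$idx + nrow(complex@protein@atoms)
  pol <- rbind(cbind(polA, chain = "A"), cbind(polB, chain = "B"))
  pol <- pol[pol$donor | pol$acceptor, ]
  iface <- interfaceResidues(complex)
  inIface <- (pol$chain == "A" & pol$resno %in% iface$proteinDesignable) |
    (pol$chain == "B" & pol$resno %in% iface$peptideDesignable)
  pol <- pol[inIface, ]
  unsatBB <- 0L; unsatSC <- 0L
  for (i in seq_len(nrow(pol))) {
    if (sasa[pol$idx[i]] >= burialCutoff) next
    # satisfied if any complementary polar atom is within the window
    partners <- pol[pol$chain != pol$chain[i] | pol$resno != pol$resno[i], ]
    partners <- partners[(pol$donor[i] & partners$acceptor) |
                           (pol$acceptor[i] & partners$donor), ]
    sat <- FALSE
    if (nrow(partners)) {
      d <- sqrt(rowSums(sweep(xyz[partners$idx, , drop = FALSE], 2,
                              xyz[pol$idx[i], ])^2))
      sat <- any(d >= criteria$dMin & d <= criteria$dMax)
    }
    if (!sat) {
      if (pol$backbone[i]) unsatBB <- unsatBB + 1L
      else unsatSC <- unsatSC + 1L
    }
  }
  list(unsatBB = unsatBB, unsatSC = unsatSC)
}

# --- shape complementarity ------------------------------------------------

# canonical molecular frame: covariance eigenvectors with signs fixed by
# third moments, so the frame co-rotates with the molecule and dot
# sampling is exactly invariant under global rigid motion
canonicalMolFrame <- function(xyz) {
  if (nrow(xyz) < 2L) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:2) {
    m3 <- sum((X %*% V[, j])^3)
    if (abs(m3) > 1e-9 && m3 < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

# dot-sampled molecular surface of a chain: dots on atom spheres not
# occluded by any other atom of the same chain, with outward normals
surfaceDots <- function(chain, dotDensity = 8) {
  at <- chain@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- vdwRadius(at$atom)
  V <- canonicalMolFrame(xyz)
  pts <- list(); nrm <- list()
  for (i in seq_len(nrow(xyz))) {
    nD <- max(16L, as.integer(round(dotDensity * 4 * pi * radii[i]^2)))
    dots <- sphereDots(nD) %*% t(V)
    p <- sweep(dots * radii[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nD)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      if (sum((xyz[j, ] - xyz[i, ])^2) > (radii[i] + radii[j])^2) next
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      free <- free & d2 > radii[j]^2
    }
    if (any(free)) {
      pts[[length(pts) + 1L]] <- p[free, , drop = FALSE]
      nrm[[length(nrm) + 1L]] <- dots[free, , drop = FALSE]
    }
  }
  list(points = do.call(rbind, pts), normals = do.call(rbind, nrm))
}

#' Interface shape complementarity
#'
#' Lawrence-Colman-style statistic on dot-sampled molecular surfaces: for
#' every buried interface dot on one surface, the nearest dot on the other
#' surface is found and the normal-alignment function
#' \code{S = (n_a . -n_b) * exp(-w * max(0, d - d0)^2)} evaluated; the
#' statistic is the average of the two per-surface medians, in [-1, 1].
#' \code{d0} is a contact tolerance below which no distance penalty
#' applies.
#'
#' @param complex a [PeptideComplex-class].
#' @param probeSpan a dot belongs to the buried interface when its gap to
#'   the other chain's van der Waals surface is below this span
#'   (A; default 2.8, a probe diameter) - solvent-exposed dots are
#'   excluded.
#' @param w distance weight (A^-2), default 0.5.
#' @param d0 contact tolerance (A), default 1.5.
#' @param dotDensity dots per A^2, default 8.
#' @return sc value in [-1, 1].
#' @export
shapeComplementarity <- function(complex, probeSpan = 2.8, w = 0.5,
                                 d0 = 1.5, dotDensity = 8) {
  sa <- surfaceDots(complex@protein, dotDensity)
  sb <- surfaceDots(complex@peptide, dotDensity)
  atomsOf <- function(chain) {
    list(xyz = as.matrix(chain@atoms[, c("x", "y", "z")]),
         r = vdwRadius(chain@atoms$atom))
  }
  aA <- atomsOf(complex@protein); aB <- atomsOf(complex@peptide)
  half <- function(s1, s2, other) {
    # buried: gap to the other chain's vdW surface below the probe span
    dAt <- outer(rowSums(s1$points^2), rowSums(other$xyz^2), "+") -
      2 * tcrossprod(s1$points, other$xyz)
    dAt[dAt < 0] <- 0
    gap <- sweep(sqrt(dAt), 2, other$r)
    buried <- apply(gap, 1, min) <= probeSpan
    if (!any(buried)) return(NA_real_)
    p1 <- s1$points[buried, , drop = FALSE]
    d2 <- outer(rowSums(p1^2), rowSums(s2$points^2), "+") -
      2 * tcrossprod(p1, s2$points)
    d2[d2 < 0] <- 0
    nearest <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
    align <- -rowSums(s1$normals[buried, , drop = FALSE] *
                        s2$normals[nearest, , drop = FALSE])
    s <- align * exp(-w * pmax(0, dmin - d0)^2)
    stats::median(s)
  }
  v <- c(half(sa, sb, aB), half(sb, sa, aA))
  if (all(is.na(v))) stop("undefined value: empty interface")
  mean(v, na.rm = TRUE)
}

# --- design selection -----------------------------------------------------

#' Design selection thresholds
#'
#' Defaults: interaction-energy proxy <= -35, shape complementarity
#' >= 0.65, buried unsatisfied backbone hydrogen bonds <= 2, side chain
#' <= 4, per-residue peptide strain <= 0.9.
#'
#' @param ddg,sc,unsatBB,unsatSC,pepRes the five thresholds.
#' @return named list.
#' @export
selectionThresholds <- function(ddg = -35.0, sc = 0.65, unsatBB = 2L,
                                unsatSC = 4L, pepRes = 0.9) {
  list(ddg = ddg, sc = sc, unsatBB = unsatBB, unsatSC = unsatSC,
       pepRes = pepRes)
}

#' Apply the design selection filter
#'
#' Pass iff ddg <= ddg threshold AND sc >= sc threshold AND unsatBB <=
#' threshold AND unsatSC <= threshold AND peptide residue score <=
#' threshold.
#'
#' @param metrics list or one-row data.frame with elements \code{ddg},
#'   \code{sc}, \code{unsatBB}, \code{unsatSC}, \code{pepRes}.
#' @param thresholds a [selectionThresholds()].
#' @return list(pass, reasons) where reasons names the failing criteria
#'   (empty when passing).
#' @export
selectDesigns <- function(metrics, thresholds = selectionThresholds()) {
  fails <- character(0)
  if (!(metrics$ddg <= thresholds$ddg)) fails <- c(fails, "ddg")
  if (!(metrics$sc >= thresholds$sc)) fails <- c(fails, "sc")
  if (!(metrics$unsatBB <= thresholds$unsatBB)) fails <- c(fails, "unsatBB")
  if (!(metrics$unsatSC <= thresholds$unsatSC)) fails <- c(fails, "unsatSC")
  if (!(metrics$pepRes <= thresholds$pepRes)) fails <- c(fails, "pepRes")
  list(pass = length(fails) == 0L, reasons = fails)
}

# --- symmetry bookkeeping -------------------------------------------------

#' Build a symmetry map for a repeat complex
#'
#' Positions at the same offset within each repeat unit form one linked
#' equivalence class; linked classes enforce identical residue identity
#' across units during design and scanning.
#'
#' @param unitLength residues per repeat unit.
#' @param nUnits number of units.
#' @return object of class \code{SymmetryMap}: list of classes, each
#'   \code{list(positions, linked)}.
#' @export
symmetryMap <- function(unitLength, nUnits) {
  classes <- lapply(seq_len(unitLength), function(o) {
    list(positions = o + unitLength * (seq_len(nUnits) - 1L), linked = TRUE)
  })
  structure(list(classes = classes, unitLength = unitLength,
                 nUnits = nUnits), class = "SymmetryMap")
}

#' Break the symmetry of selected repeat units
#'
#' Positions belonging to the named units are split out of their linked
#' classes into singleton (unlinked) classes, so their identities can be
#' redesigned independently; all other classes are unchanged.
#'
#' @param map a [symmetryMap()].
#' @param unitIndices integer unit numbers to unlink.
#' @return the modified map.
#' @export
breakSymmetry <- function(map, unitIndices) {
  if (!length(unitIndices)) return(map)
  if (any(unitIndices < 1L | unitIndices > map$nUnits))
    stop("contract violation: unit index out of range")
  sel <- unlist(lapply(unitIndices, function(u)
    (u - 1L) * map$unitLength + seq_len(map$unitLength)))
  newClasses <- list()
  for (cl in map$classes) {
    keep <- setdiff(cl$positions, sel)
    broken <- intersect(cl$positions, sel)
    if (length(keep))
      newClasses[[length(newClasses) + 1L]] <-
        list(positions = keep, linked = cl$linked)
    for (p in broken)
      newClasses[[length(newClasses) + 1L]] <-
        list(positions = p, linked = FALSE)
  }
  map$classes <- newClasses
  map
}

#' Positions equivalent to a given position under a symmetry map
#' @param map a [symmetryMap()].
#' @param position residue position.
#' @return integer vector of linked positions (including the input).
#' @export
equivalentPositions <- function(map, position) {
  for (cl in map$classes)
    if (position %in% cl$positions)
      return(if (cl$linked) cl$positions else position)
  position
}

# --- mutation scans -------------------------------------------------------

aminoAcids3 <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Hydrophobic / hydrophilic classification
#' @param resname 3-letter code(s).
#' @return logical: hydrophobic?
#' @export
isHydrophobic <- function(resname) {
  resname %in% c("ALA", "VAL", "ILE", "LEU", "MET", "PHE", "TRP", "TYR",
                 "PRO")
}

#' Peptide-side mutation scan
#'
#' Scans every non-proline, non-exempt peptide position against all
#' nineteen non-cysteine amino acids (the scan set excludes cysteine; the
#' wild-type identity is included in the candidate set). For each
#' candidate, the binding-score change is computed with \code{scoreFn}
#' applied symmetrically across the symmetry map, and the mutation is
#' accepted iff delta DDG = DDG_after - DDG_before exceeds
#' \code{acceptDelta}.
#'
#' \code{scoreFn(complex, mutations)} must return a DDG-like score for the
#' complex with \code{mutations} (data.frame position/resname) applied to
#' the peptide.
#'
#' @param complex a [PeptideComplex-class].
#' @param scoreFn pluggable scoring function (see above).
#' @param map a [symmetryMap()] for the peptide.
#' @param exempt integer positions exempt from scanning (hash-anchored
#'   positions making designed hydrogen bonds).
#' @param acceptDelta acceptance threshold on delta DDG, default 1.0.
#' @return data.frame (position, from, to, ddgBefore, ddgAfter, delta,
#'   accepted); proline and exempt positions contribute no rows.
#' @export
peptideMutationScan <- function(complex, scoreFn,
                                map = symmetryMap(
                                  complex@peptide@unitLength,
                                  complex@peptide@nUnits),
                                exempt = integer(), acceptDelta = 1.0) {
  resn <- residueNames(complex@peptide)
  positions <- seq_len(min(length(resn), map$unitLength))
  candidates <- setdiff(aminoAcids3(), "CYS")
  before <- scoreFn(complex, NULL)
  rows <- list()
  for (pos in positions) {
    if (resn[pos] == "PRO") next
    if (pos %in% exempt) next
    eq <- equivalentPositions(map, pos)
    for (aa in setdiff(candidates, resn[pos])) {
      mut <- data.frame(position = eq, resname = aa)
      after <- scoreFn(complex, mut)
      delta <- after - before
      rows[[length(rows) + 1L]] <-
        data.frame(position = pos, from = resn[pos], to = aa,
                   ddgBefore = before, ddgAfter = after, delta = delta,
                   accepted = delta > acceptDelta)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), from = character(), to = character(),
               ddgBefore = numeric(), ddgAfter = numeric(),
               delta = numeric(), accepted = logical())
}

#' Protein interface retention scan
#'
#' For each designed protein interface position, the contribution is
#' assessed by delta DDG under \code{scoreFn}. Designed hydrophobic
#' positions that were originally hydrophilic are retained iff
#' delta DDG <= -5.0; designed hydropathic (hydrophilic) positions iff
#' delta DDG <= -2.0; others are reverted.
#'
#' @param positions data.frame with columns position, original, designed
#'   (3-letter codes).
#' @param deltas named numeric: delta DDG per position (mutation back to
#'   original minus designed, i.e. the binding contribution of the
#'   designed identity).
#' @param hydrophobicThreshold default -5.0.
#' @param hydropathicThreshold default -2.0.
#' @return data.frame with a \code{retained} column.
#' @export
proteinInterfaceScan <- function(positions, deltas,
                                 hydrophobicThreshold = -5.0,
                                 hydropathicThreshold = -2.0) {
  out <- positions
  out$delta <- deltas[as.character(positions$position)]
  hydroFromPhil <- isHydrophobic(positions$designed) &
    !isHydrophobic(positions$original)
  thr <- ifelse(hydroFromPhil, hydrophobicThreshold, hydropathicThreshold)
  out$threshold <- thr
  out$retained <- out$delta <= thr
  out
}

# --- forward docking ------------------------------------------------------

#' Forward-docking convergence assessment
#'
#' Regenerates peptide conformers at the designed sequence, re-docks each
#' against the untouched protein, scores with \code{scoreFn}, sorts, and
#' declares the design converged iff (i) every one of the top 20 docks is
#' within \code{rmsdTop} backbone RMSD of the single best-scoring dock
#' (funnel convergence) and (ii) the RMSD of the top-20 average backbone
#' to the design pose is below \code{rmsdToDesign}.
#'
#' @param complex the designed [PeptideComplex-class] (protein aligned to
#'   z; peptide at the designed pose).
#' @param scoreFn function(proteinChain, dockedPeptideChain) -> score
#'   (lower is better).
#' @param nConformers conformers to generate (default 10000; scale down
#'   for testing).
#' @param rngSeed seed.
#' @param rama a [ramaModel()].
#' @param stepT,stepR dock grid steps.
#' @param polish continuously optimise each conformer's rotation and
#'   slide around its best grid point (removes grid quantisation from the
#'   convergence measures), default TRUE.
#' @param rmsdTop threshold (A) for criterion (i), default 2.0.
#' @param rmsdToDesign threshold (A) for criterion (ii), default 1.5.
#' @param minScoreable docks required for a verdict, default 20.
#' @return list(converged, verdict = "converged"/"not_converged"/
#'   "inconclusive", topRMSD, designRMSD, nScored).
#' @export
forwardDockAssess <- function(complex, scoreFn, nConformers = 10000,
                              rngSeed = 1, rama = NULL, stepT = 1.0,
                              stepR = 20, polish = TRUE, rmsdTop = 2.0,
                              rmsdToDesign = 1.5, minScoreable = 20L) {
  if (is.null(rama)) rama <- defaultRamaModel()
  protein <- complex@protein
  design <- complex@peptide
  k <- design@unitLength; n <- design@nUnits
  resn <- residueNames(design)[seq_len(k)]
  protParams <- chainSuperhelix(protein)
  set.seed(rngSeed)
  poses <- list(); scores <- numeric(0)
  for (i in seq_len(nConformers)) {
    pep <- tryCatch(
      sampleRepeatPeptide(k, n, rama, resnames = resn,
                          rngSeed = rngSeed + i),
      error = function(e) NULL)
    if (is.null(pep)) next
    pepA <- tryCatch(alignForDocking(pep), error = function(e) NULL)
    if (is.null(pepA)) next
    # register the conformer on the design's z span; the residual offset
    # within one repeat rise is covered by the dock grid
    dz <- mean(atomCoords(design, "CA")[, 3]) -
      mean(atomCoords(pepA, "CA")[, 3])
    pepA <- transformChain(pepA, rigidTransform(diag(3), c(0, 0, dz)))
    docks <- tryCatch(
      gridDock(protein, pepA, stepT = stepT, stepR = stepR,
               proteinParams = protParams),
      error = function(e) list())
    if (!length(docks)) next
    ds <- vapply(docks, function(d)
      scoreFn(protein, transformChain(pepA, d@transform)), numeric(1))
    b <- which.min(ds)
    bestX <- docks[[b]]@transform
    bestS <- ds[b]
    if (polish) {
      f <- function(x) {
        xf <- composeTransforms(
          rigidTransform(rotationAboutAxis(c(0, 0, 1), x[1]),
                         c(0, 0, x[2])), bestX)
        scoreFn(protein, transformChain(pepA, xf))
      }
      fit <- patternSearch(f, c(0, 0), step0 = c(stepR / 2, stepT / 2),
                           minStep = 1e-2, maxit = 25)
      cand <- composeTransforms(
        rigidTransform(rotationAboutAxis(c(0, 0, 1), fit$par[1]),
                       c(0, 0, fit$par[2])), bestX)
      # accept the polished placement only if it stays clash-free
      if (is.finite(fit$value) && fit$value <= bestS &&
          clashCheck(protein, transformChain(pepA, cand)) == 0L) {
        bestX <- cand
        bestS <- fit$value
      }
    }
    poses[[length(poses) + 1L]] <- transformChain(pepA, bestX)
    scores <- c(scores, bestS)
  }
  if (length(scores) < minScoreable)
    return(list(converged = FALSE, verdict = "inconclusive",
                topRMSD = NA_real_, designRMSD = NA_real_,
                nScored = length(scores)))
  top <- order(scores)[seq_len(min(20L, length(scores)))]
  bb <- lapply(poses[top], function(p)
    as.matrix(p@atoms[p@atoms$atom %in% c("N", "CA", "C", "O"),
                      c("x", "y", "z")]))
  pair <- max(vapply(bb, function(x) coordRMSD(x, bb[[1]]), numeric(1)))
  avg <- Reduce(`+`, bb) / length(bb)
  designBB <- as.matrix(design@atoms[design@atoms$atom %in%
                                       c("N", "CA", "C", "O"),
                                     c("x", "y", "z")])
  dRMSD <- coordRMSD(avg, designBB)
  conv <- pair < rmsdTop && dRMSD < rmsdToDesign
  list(converged = conv,
       verdict = if (conv) "converged" else "not_converged",
       topRMSD = pair, designRMSD = dRMSD, nScored = length(scores))
}

# --- pluggable interaction score -----------------------------------------

#' Simplified pairwise interaction score (DDG proxy)
#'
#' A documented stand-in for a physical binding energy: the sum of matched
#' bidentate geometric scores (each match contributes \code{matchBonus}
#' plus its geometric score), a Lennard-Jones-like cross-chain contact
#' term, and a hard clash penalty. The scale is calibrated so that a
#' six-unit bidentate-ladder design scores near the -35 selection
#' threshold; no parity with any physical force field is claimed.
#'
#' @param complex a [PeptideComplex-class].
#' @param matches data.frame of matched interactions (a [Dock-class]
#'   \code{matches} slot); NULL for none.
#' @param matchBonus per-match favourable contribution, default -5.
#' @param epsilon contact-term well depth, default 0.15.
#' @param sigma contact distance (A), default 3.6.
#' @param clashPenalty per-clash penalty, default +25.
#' @return numeric score (lower = more favourable).
#' @export
scoreComplex <- function(complex, matches = NULL, matchBonus = -5,
                         epsilon = 0.15, sigma = 3.6, clashPenalty = 25) {
  A <- as.matrix(complex@protein@atoms[, c("x", "y", "z")])
  B <- as.matrix(complex@peptide@atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 1e-6] <- 1e-6
  d <- sqrt(d2)
  near <- d < 8
  lj <- 0
  if (any(near)) {
    r <- d[near]
    # attractive branch only; overlap is handled by the clash penalty
    lj <- sum(pmin(4 * epsilon * ((sigma / r)^12 - (sigma / r)^6), 0))
  }
  cl <- clashCheck(complex@protein, complex@peptide)
  ms <- if (!is.null(matches) && nrow(matches))
    sum(matchBonus + matches$score) else 0
  lj + ms + clashPenalty * cl
}

#' Per-residue peptide strain proxy
#'
#' Mean over peptide residues of the Ramachandran log-density deficit
#' relative to the basin optimum (0 at ideal basin torsions, larger for
#' strained conformations), used as the peptide apo-score analogue.
#'
#' @param peptide a [BackboneChain-class].
#' @param rama a [ramaModel()].
#' @return numeric strain (>= 0, score units).
#' @export
peptideResidueScore <- function(peptide, rama = NULL) {
  if (is.null(rama)) rama <- defaultRamaModel()
  tor <- measureTorsions(peptide)
  cls <- ramaClasses(residueNames(peptide))
  ref <- vapply(unique(cls), function(cl)
    ramaLogDensity(rama, -75, 145, cl), numeric(1))
  refMax <- vapply(unique(cls), function(cl) {
    cand <- rbind(c(-63, -43), c(-120, 130), c(-75, 145), c(60, 45))
    max(apply(cand, 1, function(p) ramaLogDensity(rama, p[1], p[2], cl)))
  }, numeric(1))
  names(refMax) <- unique(cls)
  ok <- !is.na(tor$phi) & !is.na(tor$psi)
  dev <- vapply(which(ok), function(i)
    max(0, refMax[[cls[i]]] -
          ramaLogDensity(rama, tor$phi[i], tor$psi[i], cls[i])),
    numeric(1))
  mean(dev) / 10
}
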