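# Torsion-space backbone construction (NeRF), torsion measurement,
# polyproline II builders and repeat-peptide sampling.

#' Ideal backbone residue geometry
#'
#' Bond lengths and angles used for internal-to-Cartesian construction.
#' Values are standard ideal peptide geometry.
#'
#' @param nca,cac,cn,co bond lengths in Angstrom (N-CA, CA-C, C-N, C=O).
#' @param ncac,cacn,cnca,caco bond angles in degrees (N-CA-C, CA-C-N,
#'   C-N-CA, CA-C-O).
#' @return list of class \code{ResidueGeometry}.
#' @export
residueGeometry <- function(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231,
                            ncac = 111.2, cacn = 116.2, cnca = 121.7,
                            caco = 120.8) {
  g <- list(nca = nca, cac = cac, cn = cn, co = co,
            ncac = ncac, cacn = cacn, cnca = cnca, caco = caco)
  stopifnot(all(unlist(g[1:4]) > 1), all(unlist(g[1:4]) < 2),
            all(unlist(g[5:8]) > 90), all(unlist(g[5:8]) < 140))
  class(g) <- "ResidueGeometry"
  g
}

# Place atom D given A, B, C by bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg). Natural extension reference frame (NeRF).
placeAtom <- function(A, B, C, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-10) stop("degenerate reference frame in placeAtom")
  nrm <- nrm / nl
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2], nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

# Fast internal builder: backbone N/CA/C coordinates only, as one
# (3n) x 3 matrix in N, CA, C residue order. Used in optimisation loops
# where the data-frame container would dominate the cost.
buildBackboneCoords <- function(phi, psi, omega = NULL,
                                g = residueGeometry()) {
  n <- length(phi)
  if (is.null(omega)) omega <- rep(180, n)
  out <- matrix(NA_real_, 3L * n, 3L)
  N <- c(0, 0, 0); CA <- c(g$nca, 0, 0)
  a <- g$ncac * pi / 180
  C <- CA + c(-g$cac * cos(a), g$cac * sin(a), 0)
  out[1, ] <- N; out[2, ] <- CA; out[3, ] <- C
  for (i in seq_len(n - 1L) + 1L) {
    N2 <- placeAtom(N, CA, C, g$cn, g$cacn, psi[i - 1L])
    CA2 <- placeAtom(CA, C, N2, g$nca, g$cnca, omega[i - 1L])
    C2 <- placeAtom(C, N2, CA2, g$cac, g$ncac, phi[i])
    out[3L * i - 2L, ] <- N2; out[3L * i - 1L, ] <- CA2; out[3L * i, ] <- C2
    N <- N2; CA <- CA2; C <- C2
  }
  out
}

# Signed dihedral A-B-C-D in degrees, in (-180, 180].
dihedral <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bondAngle <- function(A, B, C) {
  v1 <- A - B; v2 <- C - B
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

normTorsion <- function(x) {
  x <- ((x + 180) %% 360) - 180
  x[x == -180] <- 180
  x
}

#' Build a backbone chain from torsions
#'
#' Sequential internal-to-Cartesian (NeRF) construction with ideal bond
#' lengths and angles. \code{torsions} is a data frame (or matrix) with one
#' row per residue and columns \code{phi}, \code{psi}, \code{omega}
#' (peptide-bond omega following the residue; the last residue's omega and
#' the first residue's phi are not used). CB atoms are added for non-glycine
#' residues at ideal tetrahedral geometry.
#'
#' @param torsions data.frame/matrix with columns phi, psi, omega (degrees).
#' @param resnames character vector of 3-letter residue names, recycled.
#' @param geometry a [residueGeometry()] list.
#' @param unitLength,nUnits repeat-unit bookkeeping (0 = non-repeating).
#' @param chainId chain identifier.
#' @return A [BackboneChain-class].
#' @export
buildBackbone <- function(torsions, resnames = "ALA",
                          geometry = residueGeometry(),
                          unitLength = 0L, nUnits = 0L, chainId = "A") {
  torsions <- as.data.frame(torsions)
  n <- nrow(torsions)
  if (n < 1L) stop("contract violation: empty torsion list")
  if (is.null(torsions$omega)) torsions$omega <- 180
  torsions$phi <- normTorsion(torsions$phi)
  torsions$psi <- normTorsion(torsions$psi)
  torsions$omega <- normTorsion(torsions$omega)
  resnames <- rep_len(toupper(resnames), n)
  g <- geometry
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  # canonical first-residue placement
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$nca, 0, 0)
  a <- g$ncac * pi / 180
  C[1, ] <- CA[1, ] + c(-g$cac * cos(a), g$cac * sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$cn, g$cacn,
                          torsions$psi[i - 1])
      CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ], g$nca, g$cnca,
                           torsions$omega[i - 1])
      C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ], g$cac, g$ncac,
                          torsions$phi[i])
    }
    # carbonyl O: dihedral N-CA-C-O = psi + 180 (trans to the next N)
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], g$co, g$caco,
                        torsions$psi[i] + 180)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    at <- data.frame(resno = i, resname = resnames[i],
                     atom = c("N", "CA", "C", "O"),
                     x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
                     y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
                     z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
                     stringsAsFactors = FALSE)
    if (resnames[i] != "GLY") {
      cb <- placeCB(N[i, ], CA[i, ], C[i, ])
      at <- rbind(at, data.frame(resno = i, resname = resnames[i],
                                 atom = "CB", x = cb[1], y = cb[2], z = cb[3]))
    }
    rows[[i]] <- at
  }
  atoms <- do.call(rbind, rows)
  ch <- new("BackboneChain", atoms = atoms, unitLength = as.integer(unitLength),
            nUnits = as.integer(nUnits), chainId = chainId)
  attr(ch, "torsions") <- torsions
  ch
}

# ideal CB from backbone frame: bond CA-CB 1.521, angle N-CA-CB 110.4,
# improper dihedral C-N-CA-CB = -122.6 (L-amino-acid chirality)
placeCB <- function(N, CA, C) {
  placeAtom(C, N, CA, 1.521, 110.4, -122.6)
}

#' Measure backbone torsions from coordinates
#'
#' @param chain a [BackboneChain-class].
#' @return data.frame with columns phi, psi, omega per residue (NA where
#'   undefined: phi of residue 1; psi/omega of the last residue's omega).
#' @export
measureTorsions <- function(chain) {
  xyz <- backboneArray(chain)
  n <- dim(xyz)[1]
  phi <- psi <- omg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral(xyz[i - 1, "C", ], xyz[i, "N", ], xyz[i, "CA", ],
                         xyz[i, "C", ])
    if (i < n) {
      psi[i] <- dihedral(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                         xyz[i + 1, "N", ])
      omg[i] <- dihedral(xyz[i, "CA", ], xyz[i, "C", ], xyz[i + 1, "N", ],
                         xyz[i + 1, "CA", ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omg)
}

# n x atom x 3 array of backbone coordinates (N, CA, C, O)
backboneArray <- function(chain) {
  at <- chain@atoms[chain@atoms$atom %in% c("N", "CA", "C", "O"), ]
  res <- sort(unique(at$resno))
  arr <- array(NA_real_, c(length(res), 4, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  for (j in seq_along(res)) {
    sub <- at[at$resno == res[j], ]
    arr[j, sub$atom, ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  arr
}

#' Number of residues in a chain
#' @param chain a [BackboneChain-class].
#' @return integer.
#' @export
nResidues <- function(chain) length(unique(chain@atoms$resno))

#' Coordinates of one atom type across residues
#' @param chain a [BackboneChain-class].
#' @param atom atom name, default "CA".
#' @return n x 3 matrix.
#' @export
atomCoords <- function(chain, atom = "CA") {
  at <- chain@atoms[chain@atoms$atom == atom, ]
  at <- at[order(at$resno), ]
  as.matrix(at[, c("x", "y", "z")])
}

#' Residue names of a chain
#' @param chain a [BackboneChain-class].
#' @return character vector of 3-letter codes.
#' @export
residueNames <- function(chain) {
  at <- chain@atoms[!duplicated(chain@atoms$resno), ]
  at$resname[order(at$resno)]
}

setMethod("show", "BackboneChain", function(object) {
  cat(sprintf("BackboneChain %s: %d residues (%d atoms)",
              object@chainId, nResidues(object), nrow(object@atoms)))
  if (object@unitLength > 0L)
    cat(sprintf(", %d x %d-residue repeat units",
                object@nUnits, object@unitLength))
  cat("\n")
})

#' Build an ideal polyproline II chain
#'
#' Canonical PPII torsions (phi = -75, psi = +145, omega = 180), a
#' left-handed helix with roughly three residues per turn.
#'
#' @param nResidues chain length, >= 1.
#' @param prolinePositions integer positions named PRO; others ALA unless
#'   \code{resnames} given.
#' @param resnames optional explicit 3-letter names (recycled).
#' @param unitLength repeat bookkeeping (default 3).
#' @return A [BackboneChain-class].
#' @export
buildPPII <- function(nResidues, prolinePositions = integer(),
                      resnames = NULL, unitLength = 3L) {
  stopifnot(nResidues >= 1)
  tor <- data.frame(phi = rep(-75, nResidues), psi = rep(145, nResidues),
                    omega = rep(180, nResidues))
  if (is.null(resnames)) {
    resnames <- rep("ALA", nResidues)
    resnames[prolinePositions] <- "PRO"
  }
  nu <- if (unitLength > 0) nResidues %/% unitLength else 0L
  buildBackbone(tor, resnames, unitLength = unitLength, nUnits = nu,
                chainId = "B")
}

#' Peptide sequence (one-letter) to 3-letter residue names
#' @param seq one-letter amino-acid string.
#' @return character vector of 3-letter codes.
#' @export
seqToResnames <- function(seq) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  letters1 <- strsplit(toupper(seq), "")[[1]]
  out <- map[letters1]
  if (anyNA(out)) stop("unknown amino-acid letter in sequence")
  unname(out)
}

#' Sample a Ramachandran-filtered repeat peptide
#'
#' Draws one (phi, psi) pair per residue of the repeat unit from the
#' Ramachandran model, rejecting pairs below the acceptance threshold and
#' built chains with intra-chain steric clashes, then repeats the unit
#' torsions exactly across all units.
#'
#' @param unitLength 2 or 3 residues per unit.
#' @param nUnits 4 to 6 repeat units.
#' @param rama a [ramaModel()].
#' @param resnames residue names for one unit (recycled across units).
#' @param rngSeed integer seed; the sample is deterministic given the seed.
#' @param maxTries rejection-sampling cap (default 10000).
#' @return A [BackboneChain-class]; torsions identical across units.
#' @export
sampleRepeatPeptide <- function(unitLength, nUnits, rama = ramaModel(),
                                resnames = NULL, rngSeed = 1,
                                maxTries = 10000) {
  stopifnot(unitLength %in% c(2L, 3L), nUnits >= 2L)
  set.seed(rngSeed)
  if (is.null(resnames)) resnames <- rep("ALA", unitLength)
  resnames <- rep_len(resnames, unitLength)
  classes <- ramaClasses(rep_len(resnames, unitLength * nUnits))
  for (try in seq_len(maxTries)) {
    unit <- vapply(seq_len(unitLength), function(j) {
      ramaSamplePair(rama, classes[j], maxTries = maxTries)
    }, numeric(2))
    tor <- data.frame(phi = rep(unit[1, ], nUnits),
                      psi = rep(unit[2, ], nUnits), omega = 180)
    ch <- buildBackbone(tor, rep_len(resnames, unitLength * nUnits),
                        unitLength = unitLength, nUnits = nUnits,
                        chainId = "B")
    if (selfClashCount(ch) == 0L) return(ch)
  }
  stop("sampling failure: could not draw a clash-free repeat peptide")
}

# intra-chain clash rule shared with the docking module: backbone heavy-atom
# pairs from non-adjacent residues closer than 2.8 A
selfClashCount <- function(chain, cutoff = 2.8) {
  at <- chain@atoms[chain@atoms$atom %in% c("N", "CA", "C", "O", "CB"), ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  res <- at$resno
  d <- as.matrix(dist(xyz))
  sep <- abs(outer(res, res, "-"))
  sum(d < cutoff & sep >= 2 & upper.tri(d))
}

#' Extend a peptide with a non-repeating flank
#'
#' Keeps the core backbone fixed (coordinates bit-identical to the input)
#' and models the flank sequence by Ramachandran-biased sampling, building
#' the flank by internal-to-Cartesian continuation directly in the core's
#' frame. Only clash-free extended conformers are returned.
#'
#' @param core a [BackboneChain-class]; its coordinates are not moved.
#' @param flankSequence one-letter amino-acid string for the flank.
#' @param rama a [ramaModel()].
#' @param nSamples number of conformers to return.
#' @param cTerminal logical: attach at the C terminus (default) or N.
#' @param rngSeed integer seed.
#' @param maxTries rejection cap per conformer.
#' @return list of [BackboneChain-class] conformers (length nSamples), or
#'   \code{list(core)} for an empty flank.
#' @export
extendPeptideFlank <- function(core, flankSequence, rama = ramaModel(),
                               nSamples = 10, cTerminal = TRUE, rngSeed = 1,
                               maxTries = 10000) {
  if (nchar(flankSequence) == 0L) return(list(core))
  set.seed(rngSeed)
  flankNames <- seqToResnames(flankSequence)
  nf <- length(flankNames)
  classes <- ramaClasses(flankNames)
  out <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      flankTor <- t(vapply(seq_len(nf), function(j) {
        ramaSamplePair(rama, classes[j], maxTries = maxTries)
      }, numeric(2)))
      tor <- data.frame(phi = flankTor[, 1], psi = flankTor[, 2], omega = 180)
      cand <- if (cTerminal) continueCterm(core, tor, flankNames)
              else continueNterm(core, tor, flankNames)
      if (selfClashCount(cand) > 0L) next
      ok <- TRUE
      break
    }
    if (!ok) stop("sampling failure: could not extend flank without clashes")
    out[[s]] <- cand
  }
  out
}

# NeRF continuation of a chain at the C terminus; junction psi/omega are
# taken as ideal PPII continuation values (145, 180).
continueCterm <- function(core, tor, resnames, junctionPsi = 145,
                          g = residueGeometry()) {
  arr <- backboneArray(core)
  n0 <- dim(arr)[1]
  prevN <- arr[n0, "N", ]; prevCA <- arr[n0, "CA", ]; prevC <- arr[n0, "C", ]
  psiPrev <- junctionPsi
  rows <- list()
  nf <- nrow(tor)
  for (i in seq_len(nf)) {
    N <- placeAtom(prevN, prevCA, prevC, g$cn, g$cacn, psiPrev)
    CA <- placeAtom(prevCA, prevC, N, g$nca, g$cnca, 180)
    C <- placeAtom(prevC, N, CA, g$cac, g$ncac, tor$phi[i])
    O <- placeAtom(N, CA, C, g$co, g$caco, tor$psi[i] + 180)
    resno <- n0 + i
    at <- data.frame(resno = resno, resname = resnames[i],
                     atom = c("N", "CA", "C", "O"),
                     x = c(N[1], CA[1], C[1], O[1]),
                     y = c(N[2], CA[2], C[2], O[2]),
                     z = c(N[3], CA[3], C[3], O[3]))
    if (resnames[i] != "GLY") {
      cb <- placeCB(N, CA, C)
      at <- rbind(at, data.frame(resno = resno, resname = resnames[i],
                                 atom = "CB", x = cb[1], y = cb[2], z = cb[3]))
    }
    rows[[i]] <- at
    prevN <- N; prevCA <- CA; prevC <- C; psiPrev <- tor$psi[i]
  }
  ch <- core
  ch@atoms <- rbind(core@atoms, do.call(rbind, rows))
  ch@unitLength <- 0L; ch@nUnits <- 0L
  ch
}

# NeRF continuation at the N terminus (built backwards); junction phi is
# the core's first phi equivalent, taken as ideal PPII (-75).
continueNterm <- function(core, tor, resnames, junctionPhi = -75,
                          g = residueGeometry()) {
  arr <- backboneArray(core)
  nextN <- arr[1, "N", ]; nextCA <- arr[1, "CA", ]; nextC <- arr[1, "C", ]
  phiNext <- junctionPhi
  nf <- nrow(tor)
  rows <- list()
  for (i in rev(seq_len(nf))) {
    C <- placeAtom(nextC, nextCA, nextN, g$cn, g$cnca, phiNext)
    CA <- placeAtom(nextCA, nextN, C, g$cac, g$cacn, 180)
    N <- placeAtom(nextN, C, CA, g$nca, g$ncac, tor$psi[i])
    O <- placeAtom(N, CA, C, g$co, g$caco, tor$psi[i] + 180)
    at <- data.frame(resno = i, resname = resnames[i],
                     atom = c("N", "CA", "C", "O"),
                     x = c(N[1], CA[1], C[1], O[1]),
                     y = c(N[2], CA[2], C[2], O[2]),
                     z = c(N[3], CA[3], C[3], O[3]))
    if (resnames[i] != "GLY") {
      cb <- placeCB(N, CA, C)
      at <- rbind(at, data.frame(resno = i, resname = resnames[i],
                                 atom = "CB", x = cb[1], y = cb[2], z = cb[3]))
    }
    rows[[i]] <- at
    nextN <- N; nextCA <- CA; nextC <- C; phiNext <- tor$phi[i]
  }
  coreAtoms <- core@atoms
  coreAtoms$resno <- coreAtoms$resno + nf
  ch <- core
  ch@atoms <- rbind(do.call(rbind, rows), coreAtoms)
  ch@unitLength <- 0L; ch@nUnits <- 0L
  ch
}
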