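# Hydrogen-bond geometry, bidentate interaction classes, and their
# geometric scoring. The geometric score is a stand-in for a physical
# hydrogen-bond energy: zero at ideal geometry (donor-acceptor 2.9 A,
# linear donor-H...acceptor, 120 degrees at the acceptor base) and a
# weighted sum of squared deviations otherwise.

#' Hydrogen-bond acceptance criteria and scoring weights
#'
#' @param dMin,dMax donor-acceptor heavy-atom distance window (A),
#'   default 2.6 to 3.4.
#' @param dhaMin minimum donor-H...acceptor angle (degrees), default 140.
#' @param habMin minimum H...acceptor-base angle (degrees), default 90.
#' @param dIdeal ideal donor-acceptor distance (A), default 2.9.
#' @param sdD,sdA scale of distance (A) and angle (degrees) deviations in
#'   the score.
#' @return list of class \code{HbondCriteria}.
#' @export
hbondCriteria <- function(dMin = 2.6, dMax = 3.4, dhaMin = 140, habMin = 90,
                          dIdeal = 2.9, sdD = 0.3, sdA = 40) {
  structure(list(dMin = dMin, dMax = dMax, dhaMin = dhaMin, habMin = habMin,
                 dIdeal = dIdeal, sdD = sdD, sdA = sdA),
            class = "HbondCriteria")
}

#' The bidentate interaction classes
#'
#' \itemize{
#' \item \code{AMIDE_BB_SAME}: Asn/Gln side-chain amide to the backbone
#'   N-H and C=O of a single residue.
#' \item \code{AMIDE_BB_CONSEC}: Asn/Gln amide to the C=O of residue i and
#'   the N-H of residue i+1.
#' \item \code{CARBOX_2NH}: Asp/Glu carboxylate to the N-H groups of two
#'   successive residues.
#' \item \code{AMIDE_SC_SERTHR}: Asn/Gln amide to a backbone N-H plus the
#'   side-chain oxygen of a serine or threonine.
#' \item \code{PI_PI}, \code{CATION_PI}: aromatic stacking geometries
#'   (6-dimensional keys; no hydrogen bonds).
#' }
#' @export
bidentateClasses <- function() {
  c("AMIDE_BB_SAME", "AMIDE_BB_CONSEC", "CARBOX_2NH", "AMIDE_SC_SERTHR",
    "PI_PI", "CATION_PI")
}

# key dimensionality per class (6 rigid-body + extra torsions)
classTorsionCount <- function(class) {
  switch(class,
         AMIDE_BB_SAME = 2L, AMIDE_BB_CONSEC = 2L, CARBOX_2NH = 2L,
         AMIDE_SC_SERTHR = 2L, PI_PI = 0L, CATION_PI = 0L,
         stop("unknown bidentate class: ", class))
}

# which protein-side residue types carry each class's functional group
classResidues <- function(class) {
  switch(class,
         AMIDE_BB_SAME = c("ASN", "GLN"),
         AMIDE_BB_CONSEC = c("ASN", "GLN"),
         CARBOX_2NH = c("ASP", "GLU"),
         AMIDE_SC_SERTHR = c("ASN", "GLN"),
         PI_PI = c("PHE", "TYR"),
         CATION_PI = "ARG",
         stop("unknown bidentate class: ", class))
}

# --- functional group templates in local frames ---------------------------
# Geometry matches the side-chain topology table exactly (angles sum to
# 360 in the sp2 plane), so inverse-rotamer placements reproduce the group
# without residual.
# amide: carbonyl C at origin, O along +x, plane z = 0
amideGroupLocal <- function() {
  ocn <- (360 - 120.8 - 116.4) * pi / 180
  N <- 1.328 * c(cos(ocn), sin(ocn), 0)
  toC <- -N / sqrt(sum(N^2))
  h <- function(angDeg) {
    a <- angDeg * pi / 180
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    N + 1.01 * as.numeric(rot %*% toC)
  }
  occ <- -120.8 * pi / 180
  list(C = c(0, 0, 0), O = c(1.231, 0, 0), N = N,
       H1 = h(120), H2 = h(-120),
       CATT = 1.516 * c(cos(occ), sin(occ), 0))
}

# carboxylate: C at origin, O1 along +x
carboxGroupLocal <- function() {
  oco <- (360 - 2 * 118.4) * pi / 180
  occ <- -118.4 * pi / 180
  list(C = c(0, 0, 0), O1 = c(1.25, 0, 0),
       O2 = 1.25 * c(cos(oco), sin(oco), 0),
       CATT = 1.516 * c(cos(occ), sin(occ), 0))
}

# six-membered aromatic ring: centroid at origin, normal +z, CG on +x
ringGroupLocal <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  xy <- 1.39 * cbind(cos(ang), sin(ang), 0)
  atoms <- split(xy, row(xy))
  names(atoms) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  atoms$CATT <- c(1.39 + 1.51, 0, 0)
  atoms
}

# guanidinium: CZ at origin, NH1 along +x, plane z = 0
guanidiniumGroupLocal <- function() {
  a <- 120 * pi / 180
  list(CZ = c(0, 0, 0), NH1 = c(1.33, 0, 0),
       NH2 = 1.33 * c(cos(a), sin(a), 0),
       NE = 1.33 * c(cos(-a), sin(-a), 0))
}

groupLocal <- function(class) {
  switch(class,
         AMIDE_BB_SAME = , AMIDE_BB_CONSEC = , AMIDE_SC_SERTHR =
           amideGroupLocal(),
         CARBOX_2NH = carboxGroupLocal(),
         PI_PI = ringGroupLocal(),
         CATION_PI = guanidiniumGroupLocal())
}

# place the group atoms with a rigid transform
groupAtoms <- function(class, xform) {
  lapply(groupLocal(class), function(p) applyTransform(xform, p))
}

# --- residue backbone frame ----------------------------------------------
#' Orthonormal backbone frame of a residue
#'
#' Origin at CA, x toward N, z along x cross (C - CA), y completing the
#' right-handed frame. Returned as the local-to-global [RigidTransform-class].
#'
#' @param N,CA,C backbone atom coordinates (length-3).
#' @return A [RigidTransform-class].
#' @export
backboneFrame <- function(N, CA, C) {
  x <- N - CA; x <- x / sqrt(sum(x^2))
  v <- C - CA
  z <- c(x[2] * v[3] - x[3] * v[2], x[3] * v[1] - x[1] * v[3],
         x[1] * v[2] - x[2] * v[1])
  z <- z / sqrt(sum(z^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rigidTransform(cbind(x, y, z), CA)
}

residueFrame <- function(chain, resIndex) {
  at <- chain@atoms[chain@atoms$resno == resIndex, ]
  getA <- function(nm) {
    r <- at[at$atom == nm, ]
    if (nrow(r) == 0) stop("missing atom ", nm, " in residue ", resIndex)
    as.numeric(r[1, c("x", "y", "z")])
  }
  backboneFrame(getA("N"), getA("CA"), getA("C"))
}

# --- backbone amide hydrogens --------------------------------------------
# explicit H atoms are honoured if present; otherwise H is constructed from
# the previous residue's C (bisector placement). Residue 1 and proline have
# no amide H.
amideH <- function(chain, resIndex) {
  at <- chain@atoms
  hrow <- at[at$resno == resIndex & at$atom == "H", ]
  if (nrow(hrow) > 0) return(as.numeric(hrow[1, c("x", "y", "z")]))
  res <- at[at$resno == resIndex, ]
  if (nrow(res) == 0) stop("no residue ", resIndex)
  if (res$resname[1] == "PRO") return(NULL)
  prevC <- at[at$resno == resIndex - 1 & at$atom == "C", ]
  if (nrow(prevC) == 0) return(NULL)
  N <- as.numeric(res[res$atom == "N", c("x", "y", "z")])
  CA <- as.numeric(res[res$atom == "CA", c("x", "y", "z")])
  Cp <- as.numeric(prevC[1, c("x", "y", "z")])
  u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
  u2 <- (CA - N) / sqrt(sum((CA - N)^2))
  d <- -(u1 + u2); d <- d / sqrt(sum(d^2))
  N + 1.01 * d
}

resAtom <- function(chain, resIndex, name) {
  r <- chain@atoms[chain@atoms$resno == resIndex &
                     chain@atoms$atom == name, ]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, c("x", "y", "z")])
}

# --- hydrogen-bond scoring -----------------------------------------------
# one hydrogen bond D(-H)...A(-B); returns list(ok, score) or ok = FALSE
hbondEval <- function(D, H, A, B, crit) {
  d <- sqrt(sum((D - A)^2))
  if (d < crit$dMin || d > crit$dMax) return(list(ok = FALSE, score = Inf))
  dha <- bondAngle(D, H, A)
  if (dha < crit$dhaMin) return(list(ok = FALSE, score = Inf))
  hab <- bondAngle(H, A, B)
  if (hab < crit$habMin) return(list(ok = FALSE, score = Inf))
  s <- ((d - crit$dIdeal) / crit$sdD)^2 + ((dha - 180) / crit$sdA)^2 +
    ((hab - 120) / crit$sdA)^2
  list(ok = TRUE, score = s)
}

#' Extract the target atoms a bidentate class interacts with
#'
#' Pulled out once per fragment so repeated evaluations (Monte Carlo,
#' refinement) avoid re-querying the atom table. Errors on missing atoms.
#'
#' @param chain [BackboneChain-class] fragment.
#' @param resIndex target residue index.
#' @param class a [bidentateClasses()] string.
#' @return named list of atom coordinates.
#' @export
targetAtoms <- function(chain, resIndex, class) {
  need <- function(x, what) {
    if (is.null(x)) stop("contract violation: missing atom (", what,
                         ") for class ", class)
    x
  }
  if (class %in% c("PI_PI", "CATION_PI")) {
    ringAtoms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    pos <- lapply(ringAtoms, function(a) resAtom(chain, resIndex, a))
    if (any(vapply(pos, is.null, logical(1))))
      stop("contract violation: target residue lacks an aromatic ring")
    names(pos) <- ringAtoms
    return(pos)
  }
  switch(class,
    AMIDE_BB_SAME = list(
      O = need(resAtom(chain, resIndex, "O"), "O_i"),
      C = need(resAtom(chain, resIndex, "C"), "C_i"),
      N = need(resAtom(chain, resIndex, "N"), "N_i"),
      H = need(amideH(chain, resIndex), "H_i")),
    # consecutive residues: the amide bridges the N-H of residue i and the
    # C=O of residue i+1 (the O_i/H_i+1 pair is coplanar in the rigid
    # trans-peptide unit and cannot be bridged by a single amide group)
    AMIDE_BB_CONSEC = list(
      O = need(resAtom(chain, resIndex + 1, "O"), "O_i+1"),
      C = need(resAtom(chain, resIndex + 1, "C"), "C_i+1"),
      N = need(resAtom(chain, resIndex, "N"), "N_i"),
      H = need(amideH(chain, resIndex), "H_i")),
    CARBOX_2NH = list(
      N1 = need(resAtom(chain, resIndex, "N"), "N_i"),
      H1 = need(amideH(chain, resIndex), "H_i"),
      N2 = need(resAtom(chain, resIndex + 1, "N"), "N_i+1"),
      H2 = need(amideH(chain, resIndex + 1), "H_i+1")),
    AMIDE_SC_SERTHR = {
      OG <- resAtom(chain, resIndex, "OG")
      if (is.null(OG)) OG <- resAtom(chain, resIndex, "OG1")
      list(N = need(resAtom(chain, resIndex, "N"), "N_i"),
           H = need(amideH(chain, resIndex), "H_i"),
           OG = need(OG, "OG (Ser/Thr side-chain oxygen)"),
           CB = need(resAtom(chain, resIndex, "CB"), "CB_i"))
    },
    stop("unknown bidentate class: ", class))
}

# core evaluator against precomputed target atoms
bidentateCore <- function(groupXform, tgt, class, criteria) {
  grp <- groupAtoms(class, groupXform)
  two <- switch(class,
    AMIDE_BB_SAME = {
      b1a <- hbondEval(grp$N, grp$H1, tgt$O, tgt$C, criteria)
      b1b <- hbondEval(grp$N, grp$H2, tgt$O, tgt$C, criteria)
      b1 <- if (b1a$score <= b1b$score) b1a else b1b
      list(b1, hbondEval(tgt$N, tgt$H, grp$O, grp$C, criteria))
    },
    AMIDE_BB_CONSEC = {
      b1a <- hbondEval(grp$N, grp$H1, tgt$O, tgt$C, criteria)
      b1b <- hbondEval(grp$N, grp$H2, tgt$O, tgt$C, criteria)
      b1 <- if (b1a$score <= b1b$score) b1a else b1b
      list(b1, hbondEval(tgt$N, tgt$H, grp$O, grp$C, criteria))
    },
    CARBOX_2NH = list(
      hbondEval(tgt$N1, tgt$H1, grp$O1, grp$C, criteria),
      hbondEval(tgt$N2, tgt$H2, grp$O2, grp$C, criteria)),
    AMIDE_SC_SERTHR = {
      b2a <- hbondEval(grp$N, grp$H1, tgt$OG, tgt$CB, criteria)
      b2b <- hbondEval(grp$N, grp$H2, tgt$OG, tgt$CB, criteria)
      list(hbondEval(tgt$N, tgt$H, grp$O, grp$C, criteria),
           if (b2a$score <= b2b$score) b2a else b2b)
    },
    stop("unknown bidentate class: ", class))
  if (!two[[1]]$ok || !two[[2]]$ok)
    return(list(accept = FALSE, score = Inf))
  list(accept = TRUE, score = two[[1]]$score + two[[2]]$score)
}

#' Evaluate a bidentate interaction
#'
#' Places the class's side-chain functional group with \code{groupXform}
#' and tests its two component interactions against a backbone fragment.
#' The placement is accepted only when both component hydrogen bonds
#' satisfy the criteria; the score is the sum of the component scores
#' (0 at ideal geometry).
#'
#' For \code{PI_PI} and \code{CATION_PI} the "fragment" must carry an
#' aromatic ring on the target residue; acceptance is centroid distance
#' <= 5.5 A and interplanar (or cation-offset) angle <= 30 degrees.
#'
#' @param groupXform [RigidTransform-class] placing the group's local frame.
#' @param chain [BackboneChain-class] fragment carrying the target
#'   residue(s) (explicit H atoms honoured when present).
#' @param resIndex index of the target residue.
#' @param class a [bidentateClasses()] string.
#' @param criteria an [hbondCriteria()].
#' @return list(accept = logical, score = numeric; Inf when rejected).
#' @export
evaluateBidentate <- function(groupXform, chain, resIndex, class,
                              criteria = hbondCriteria()) {
  if (class %in% c("PI_PI", "CATION_PI")) {
    grp <- groupAtoms(class, groupXform)
    return(evaluateStack(grp, chain, resIndex, class))
  }
  tgt <- targetAtoms(chain, resIndex, class)
  bidentateCore(groupXform, tgt, class, criteria)
}

# pi-pi / cation-pi stacking acceptance; defaults are package choices
# (centroid distance <= 5.5 A, angle <= 30 degrees), not literature-fit.
evaluateStack <- function(grp, chain, resIndex, class,
                          maxDist = 5.5, maxAngle = 30) {
  ringAtoms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  pos <- lapply(ringAtoms, function(a) resAtom(chain, resIndex, a))
  if (any(vapply(pos, is.null, logical(1))))
    stop("contract violation: target residue lacks an aromatic ring")
  M <- do.call(rbind, pos)
  cen <- colMeans(M)
  sv <- svd(sweep(M, 2, cen))
  nrm <- sv$v[, 3]
  if (class == "PI_PI") {
    cen2 <- colMeans(do.call(rbind, grp[ringAtoms]))
    sv2 <- svd(sweep(do.call(rbind, grp[ringAtoms]), 2, cen2))
    nrm2 <- sv2$v[, 3]
    d <- sqrt(sum((cen - cen2)^2))
    ang <- acos(min(1, abs(sum(nrm * nrm2)))) * 180 / pi
  } else {
    cz <- grp$CZ
    d <- sqrt(sum((cen - cz)^2))
    v <- (cz - cen) / d
    ang <- acos(min(1, abs(sum(nrm * v)))) * 180 / pi
  }
  if (d > maxDist || ang > maxAngle)
    return(list(accept = FALSE, score = Inf))
  list(accept = TRUE, score = ((d - 3.8) / 1.0)^2 + (ang / 30)^2)
}
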