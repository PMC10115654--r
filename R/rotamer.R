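# Side-chain construction (forward, from the backbone out) and inverse
# rotamer enumeration (backbone placements implied by a fixed functional
# group). The rotamer set is canonical chi values {-60, 60, 180} per
# rotatable bond, with internal-clash pruning; terminal sp2 groups are
# rigid relative to the last chi.

# side-chain topology: each atom placed by NeRF from three prior atoms.
# torsion entries: "chi1".."chi4" look up the chi vector; numbers are fixed
# offsets added to the previous chi reference ("+chiK:off" handled below).
sideChainTopology <- function(resType) {
  switch(resType,
    ASN = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.516, angle = 112.6, tor = "chi1"),
      list(atom = "OD1", ref = c("CA", "CB", "CG"), bond = 1.231, angle = 120.8, tor = "chi2"),
      list(atom = "ND2", ref = c("CA", "CB", "CG"), bond = 1.328, angle = 116.4, tor = "chi2+180")),
    GLN = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.520, angle = 114.1, tor = "chi1"),
      list(atom = "CD",  ref = c("CA", "CB", "CG"), bond = 1.516, angle = 112.6, tor = "chi2"),
      list(atom = "OE1", ref = c("CB", "CG", "CD"), bond = 1.231, angle = 120.8, tor = "chi3"),
      list(atom = "NE2", ref = c("CB", "CG", "CD"), bond = 1.328, angle = 116.4, tor = "chi3+180")),
    ASP = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.516, angle = 112.6, tor = "chi1"),
      list(atom = "OD1", ref = c("CA", "CB", "CG"), bond = 1.250, angle = 118.4, tor = "chi2"),
      list(atom = "OD2", ref = c("CA", "CB", "CG"), bond = 1.250, angle = 118.4, tor = "chi2+180")),
    GLU = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.520, angle = 114.1, tor = "chi1"),
      list(atom = "CD",  ref = c("CA", "CB", "CG"), bond = 1.516, angle = 112.6, tor = "chi2"),
      list(atom = "OE1", ref = c("CB", "CG", "CD"), bond = 1.250, angle = 118.4, tor = "chi3"),
      list(atom = "OE2", ref = c("CB", "CG", "CD"), bond = 1.250, angle = 118.4, tor = "chi3+180")),
    SER = list(
      list(atom = "OG",  ref = c("N", "CA", "CB"),  bond = 1.417, angle = 110.8, tor = "chi1")),
    THR = list(
      list(atom = "OG1", ref = c("N", "CA", "CB"),  bond = 1.433, angle = 109.5, tor = "chi1")),
    PHE = , TYR = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.502, angle = 113.8, tor = "chi1"),
      list(atom = "CD1", ref = c("CA", "CB", "CG"), bond = 1.390, angle = 120.8, tor = "chi2"),
      list(atom = "CD2", ref = c("CA", "CB", "CG"), bond = 1.390, angle = 120.8, tor = "chi2+180"),
      list(atom = "CE1", ref = c("CB", "CG", "CD1"), bond = 1.390, angle = 120.0, tor = 180),
      list(atom = "CE2", ref = c("CB", "CG", "CD2"), bond = 1.390, angle = 120.0, tor = 180),
      list(atom = "CZ",  ref = c("CG", "CD1", "CE1"), bond = 1.390, angle = 120.0, tor = 0)),
    ARG = list(
      list(atom = "CG",  ref = c("N", "CA", "CB"),  bond = 1.520, angle = 114.1, tor = "chi1"),
      list(atom = "CD",  ref = c("CA", "CB", "CG"), bond = 1.520, angle = 111.5, tor = "chi2"),
      list(atom = "NE",  ref = c("CB", "CG", "CD"), bond = 1.460, angle = 112.0, tor = "chi3"),
      list(atom = "CZ",  ref = c("CG", "CD", "NE"), bond = 1.330, angle = 124.2, tor = "chi4"),
      list(atom = "NH1", ref = c("CD", "NE", "CZ"), bond = 1.330, angle = 120.0, tor = 0),
      list(atom = "NH2", ref = c("CD", "NE", "CZ"), bond = 1.330, angle = 120.0, tor = 180)),
    stop("no side-chain topology for ", resType))
}

#' Number of chi angles carried by a hash entry for a residue type
#' @param resType 3-letter residue type.
#' @return integer chi count (Asn 2, Gln 3, Asp 2, Glu 3, Ser/Thr 1, ...).
#' @export
chiCount <- function(resType) {
  switch(resType, ASN = 2L, GLN = 3L, ASP = 2L, GLU = 3L, SER = 1L,
         THR = 1L, PHE = 2L, TYR = 2L, ARG = 4L,
         stop("no chi count for ", resType))
}

#' Build side-chain atoms forward from a backbone
#'
#' @param resType 3-letter residue type with a defined topology.
#' @param N,CA,C backbone coordinates.
#' @param chis numeric chi angles (degrees), length [chiCount()].
#' @return named list of atom coordinates (including CB).
#' @export
buildSideChain <- function(resType, N, CA, C, chis) {
  stopifnot(length(chis) == chiCount(resType))
  atoms <- list(N = N, CA = CA, C = C, CB = placeCB(N, CA, C))
  for (step in sideChainTopology(resType)) {
    tor <- step$tor
    tval <- if (is.numeric(tor)) {
      tor
    } else if (grepl("\\+180$", tor)) {
      chis[as.integer(sub("chi(\\d)\\+180", "\\1", tor))] + 180
    } else {
      chis[as.integer(sub("chi", "", tor))]
    }
    atoms[[step$atom]] <- placeAtom(atoms[[step$ref[1]]],
                                    atoms[[step$ref[2]]],
                                    atoms[[step$ref[3]]],
                                    step$bond, step$angle, tval)
  }
  atoms
}

# functional-group frame (local-to-global RigidTransform) from built atoms,
# matching the group templates in hbond.R
groupFrameFromAtoms <- function(class, atoms) {
  f3 <- function(C, O, thirdInPlane) {
    x <- (O - C) / sqrt(sum((O - C)^2))
    v <- thirdInPlane - C
    z <- c(x[2] * v[3] - x[3] * v[2], x[3] * v[1] - x[1] * v[3],
           x[1] * v[2] - x[2] * v[1])
    z <- z / sqrt(sum(z^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    rigidTransform(cbind(x, y, z), C)
  }
  if (class %in% c("AMIDE_BB_SAME", "AMIDE_BB_CONSEC", "AMIDE_SC_SERTHR")) {
    if (!is.null(atoms$OE1)) f3(atoms$CD, atoms$OE1, atoms$NE2)
    else f3(atoms$CG, atoms$OD1, atoms$ND2)
  } else if (class == "CARBOX_2NH") {
    if (!is.null(atoms$OE1)) f3(atoms$CD, atoms$OE1, atoms$OE2)
    else f3(atoms$CG, atoms$OD1, atoms$OD2)
  } else if (class == "PI_PI") {
    ring <- do.call(rbind, atoms[c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")])
    cen <- colMeans(ring)
    x <- (atoms$CG - cen) / sqrt(sum((atoms$CG - cen)^2))
    v <- atoms$CD1 - cen
    z <- c(x[2] * v[3] - x[3] * v[2], x[3] * v[1] - x[1] * v[3],
           x[1] * v[2] - x[2] * v[1])
    z <- z / sqrt(sum(z^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    rigidTransform(cbind(x, y, z), cen)
  } else if (class == "CATION_PI") {
    f3(atoms$CZ, atoms$NH1, atoms$NH2)
  } else stop("unknown class ", class)
}

# canonical backbone used to express rotamer geometry in a fixed frame
canonicalBackbone <- function(g = residueGeometry()) {
  N <- c(0, 0, 0); CA <- c(g$nca, 0, 0)
  a <- g$ncac * pi / 180
  C <- CA + c(-g$cac * cos(a), g$cac * sin(a), 0)
  list(N = N, CA = CA, C = C)
}

#' Enumerate inverse rotamers for a functional-group placement
#'
#' For each chi combination from the canonical rotamer set, computes the
#' backbone placement from which building the side chain forward with those
#' chi angles reproduces the requested functional-group placement exactly,
#' and prunes combinations whose side chain clashes internally.
#'
#' @param groupXform [RigidTransform-class] placing the group frame.
#' @param resType 3-letter residue type.
#' @param rotamerSet chi values per rotatable bond (default c(-60, 60, 180)).
#' @param class interaction class (selects the group-frame definition);
#'   default inferred from \code{resType}.
#' @return list of entries, each \code{list(frame, chis, atoms)} where
#'   \code{frame} is the backbone [RigidTransform-class] (canonical
#'   N/CA/C frame mapped into the global frame) and \code{atoms} the
#'   globally placed side-chain atoms.
#' @export
inverseRotamers <- function(groupXform, resType,
                            rotamerSet = c(-60, 60, 180), class = NULL) {
  if (is.null(class))
    class <- switch(resType, ASN = , GLN = "AMIDE_BB_SAME",
                    ASP = , GLU = "CARBOX_2NH",
                    PHE = , TYR = "PI_PI", ARG = "CATION_PI",
                    SER = , THR = "AMIDE_SC_SERTHR")
  nchi <- chiCount(resType)
  combos <- as.matrix(expand.grid(rep(list(rotamerSet), nchi)))
  bb <- canonicalBackbone()
  out <- list()
  for (r in seq_len(nrow(combos))) {
    chis <- as.numeric(combos[r, ])
    atoms <- buildSideChain(resType, bb$N, bb$CA, bb$C, chis)
    if (internalClash(atoms, resType = resType)) next
    gLoc <- groupFrameFromAtoms(class, atoms)
    # backbone placement carrying the canonical group onto the target
    place <- composeTransforms(groupXform, invertTransform(gLoc))
    globalAtoms <- lapply(atoms, function(p) applyTransform(place, p))
    frame <- backboneFrame(globalAtoms$N, globalAtoms$CA, globalAtoms$C)
    out[[length(out) + 1L]] <- list(frame = frame, chis = chis,
                                    atoms = globalAtoms)
  }
  out
}

# internal clash: atom pairs at bond-graph distance >= 3 closer than 2.7 A
# (1-2 and 1-3 pairs are constrained by valence geometry, not clashes)
internalClash <- function(atoms, cutoff = 2.7, resType = NULL) {
  nm <- names(atoms)
  M <- do.call(rbind, atoms)
  bonds <- rbind(c("N", "CA"), c("CA", "C"), c("CA", "CB"))
  if (!is.null(resType)) {
    for (step in sideChainTopology(resType))
      bonds <- rbind(bonds, c(step$ref[3], step$atom))
  } else {
    # fall back: consecutive heavy-atom chain after CB, branches to prior
    prev <- "CB"
    for (a in setdiff(nm, c("N", "CA", "C", "CB"))) {
      bonds <- rbind(bonds, c(prev, a))
      prev <- a
    }
  }
  bonds <- bonds[bonds[, 1] %in% nm & bonds[, 2] %in% nm, , drop = FALSE]
  n <- length(nm)
  adj <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  for (r in seq_len(nrow(bonds))) {
    adj[bonds[r, 1], bonds[r, 2]] <- TRUE
    adj[bonds[r, 2], bonds[r, 1]] <- TRUE
  }
  # graph distance up to 2 via boolean matrix powers
  reach2 <- adj | (adj %*% adj > 0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (reach2[i, j]) next
    if (sqrt(sum((M[i, ] - M[j, ])^2)) < cutoff) return(TRUE)
  }
  FALSE
}
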