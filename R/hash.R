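# Geometric hashing of bidentate interaction geometries. The relative
# rigid-body transform between the two residues' backbone frames plus (for
# the hydrogen-bond classes) two torsion angles is discretised onto a fixed
# grid and packed into a single integer key (mixed-radix; the full key
# space is ~2.9e11, held exactly in a double). Entries under a key record
# the protein-side residue identity and its chi angles.

#' Hash binning configuration
#'
#' @param transBin translation bin width (A), default 1.0.
#' @param transRange half-range per translation axis (A), default 16.
#' @param rotBin Euler z-y-z rotation bin width (degrees), default 15.
#' @param torBin torsion bin width (degrees), default 10.
#' @return list of class \code{HashConfig}, with per-dimension bin counts.
#' @export
hashConfig <- function(transBin = 1.0, transRange = 16, rotBin = 15,
                       torBin = 10) {
  nT <- as.integer(ceiling(2 * transRange / transBin))
  nA <- as.integer(round(360 / rotBin))
  nB <- as.integer(round(180 / rotBin))
  nTor <- as.integer(round(360 / torBin))
  # full 8D key space must stay below 2^53 for exact double arithmetic
  stopifnot(nT^3 * nA^2 * nB * nTor^2 < 2^53)
  structure(list(transBin = transBin, transRange = transRange,
                 rotBin = rotBin, torBin = torBin,
                 nT = nT, nA = nA, nB = nB, nTor = nTor),
            class = "HashConfig")
}

# Euler z-y-z angles (degrees) of a rotation matrix, alpha/gamma in
# [-180, 180), beta in [0, 180]
eulerZYZ <- function(R) {
  R <- unname(R)
  beta <- acos(max(-1, min(1, R[3, 3]))) * 180 / pi
  if (abs(R[3, 3]) > 1 - 1e-10) {
    alpha <- atan2(R[2, 1], R[1, 1]) * 180 / pi * sign(R[3, 3])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    gamma <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

# per-dimension bin indices for a transform + torsions
hashBins <- function(transform, torsions, config) {
  t <- transform@translation
  if (any(abs(t) >= config$transRange))
    stop("translation out of hash range (", config$transRange, " A)")
  tb <- floor((t + config$transRange) / config$transBin)
  eu <- eulerZYZ(transform@rotation)
  bBin <- min(floor(eu["beta"] / config$rotBin), config$nB - 1L)
  wrapBin <- function(a) {
    a <- a %% 360
    floor(a / config$rotBin) %% config$nA
  }
  if (bBin == 0L || bBin == config$nB - 1L) {
    # pole-adjacent merge: alpha and gamma are degenerate; fold into one
    comb <- if (bBin == 0L) eu["alpha"] + eu["gamma"]
            else eu["alpha"] - eu["gamma"]
    aBin <- wrapBin(comb); gBin <- 0L
  } else {
    aBin <- wrapBin(eu["alpha"]); gBin <- wrapBin(eu["gamma"])
  }
  torB <- if (length(torsions)) {
    floor((normTorsion(torsions) + 180) / config$torBin) %% config$nTor
  } else integer(0)
  as.numeric(c(tb, aBin, bBin, gBin, torB))
}

#' Encode an interaction geometry as a hash key
#'
#' Deterministic and total on the configured ranges: two inputs falling in
#' the same bin on every dimension map to the same key; inputs differing in
#' any one bin map to different keys.
#'
#' @param transform [RigidTransform-class] between the two residues'
#'   backbone frames (target-residue frame to side-chain-residue frame).
#' @param torsions numeric of length 0 or 2: extra torsion dimensions
#'   (phi/psi, or phi/chi1 for the Ser/Thr class); length 0 for the
#'   6-dimensional classes.
#' @param config a [hashConfig()].
#' @return a single numeric key (exact integer value).
#' @export
encodeKey <- function(transform, torsions, config = hashConfig()) {
  stopifnot(length(torsions) %in% c(0L, 2L))
  b <- hashBins(transform, torsions, config)
  radix <- c(config$nT, config$nT, config$nT, config$nA, config$nB,
             config$nA, rep(config$nTor, length(torsions)))
  key <- 0
  for (i in seq_along(b)) key <- key * radix[i] + b[i]
  key
}

# neighbour keys: +-1 bin in every dimension (cartesian product)
neighbourKeys <- function(transform, torsions, config) {
  b <- hashBins(transform, torsions, config)
  radix <- c(config$nT, config$nT, config$nT, config$nA, config$nB,
             config$nA, rep(config$nTor, length(torsions)))
  circular <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                rep(TRUE, length(torsions)))
  offs <- expand.grid(rep(list(-1:1), length(b)))
  keys <- apply(offs, 1, function(o) {
    bb <- b + o
    for (i in seq_along(bb)) {
      if (circular[i]) bb[i] <- bb[i] %% radix[i]
      else if (bb[i] < 0 || bb[i] >= radix[i]) return(NA_real_)
    }
    k <- 0
    for (i in seq_along(bb)) k <- k * radix[i] + bb[i]
    k
  })
  unique(keys[!is.na(keys)])
}

#' Create an empty interaction hash table
#'
#' @param class a [bidentateClasses()] string.
#' @param config a [hashConfig()].
#' @param seed,nSteps provenance metadata.
#' @return An [InteractionHashTable-class].
#' @export
emptyHashTable <- function(class, config = hashConfig(), seed = NA_integer_,
                           nSteps = 0L) {
  new("InteractionHashTable", env = new.env(hash = TRUE, parent = emptyenv()),
      metadata = list(class = class, config = config, seed = seed,
                      nSteps = nSteps))
}

hashInsert <- function(table, key, entry) {
  ks <- sprintf("%.0f", key)
  cur <- if (exists(ks, table@env, inherits = FALSE))
    get(ks, table@env) else list()
  assign(ks, c(cur, list(entry)), table@env)
  invisible(table)
}

#' Number of keys / entries in a hash table
#' @param table an [InteractionHashTable-class].
#' @return list(nKeys, nEntries).
#' @export
hashTableSize <- function(table) {
  ks <- ls(table@env)
  list(nKeys = length(ks),
       nEntries = sum(vapply(ks, function(k)
         length(get(k, table@env)), integer(1))))
}

setMethod("show", "InteractionHashTable", function(object) {
  sz <- hashTableSize(object)
  cat(sprintf("InteractionHashTable [%s]: %d keys, %d entries (seed %s, %d MC steps)\n",
              object@metadata$class, sz$nKeys, sz$nEntries,
              as.character(object@metadata$seed), object@metadata$nSteps))
})

#' Query a hash table
#'
#' Exact-bin lookup by default; with \code{neighbours = TRUE} all keys
#' within one bin per dimension are also searched.
#'
#' @param table an [InteractionHashTable-class].
#' @param transform,torsions the query geometry (see [encodeKey()]).
#' @param config a [hashConfig()]; must match the table's configuration.
#' @param neighbours logical, default FALSE.
#' @return list of entries (possibly empty).
#' @export
queryHash <- function(table, transform, torsions, config = hashConfig(),
                      neighbours = FALSE) {
  tc <- table@metadata$config
  if (!identical(unclass(tc)[c("transBin", "transRange", "rotBin", "torBin")],
                 unclass(config)[c("transBin", "transRange", "rotBin",
                                   "torBin")]))
    stop("hash config mismatch between query and table")
  keys <- if (neighbours) neighbourKeys(transform, torsions, config)
          else encodeKey(transform, torsions, config)
  out <- list()
  for (k in keys) {
    ks <- sprintf("%.0f", k)
    if (exists(ks, table@env, inherits = FALSE))
      out <- c(out, get(ks, table@env))
  }
  out
}

# --- Monte Carlo sampling of bidentate placements -------------------------

# three-residue fragment with the target at residue 2; all residues share
# (phi, psi). Ser/Thr targets carry an OG placed with chi1.
mcFragment <- function(phi, psi, class, chi1 = -60) {
  resn <- if (class == "AMIDE_SC_SERTHR") c("ALA", "SER", "ALA")
          else rep("ALA", 3)
  ch <- buildBackbone(data.frame(phi = rep(phi, 3), psi = rep(psi, 3),
                                 omega = 180), resn)
  if (class == "AMIDE_SC_SERTHR") {
    arr <- backboneArray(ch)
    og <- buildSideChain("SER", arr[2, "N", ], arr[2, "CA", ],
                         arr[2, "C", ], chi1)$OG
    ch@atoms <- rbind(ch@atoms,
                      data.frame(resno = 2, resname = "SER", atom = "OG",
                                 x = og[1], y = og[2], z = og[3]))
  }
  ch
}

# soft (windowless) bidentate deviation score used to seed and refine; same
# deviation terms as the hard score, finite everywhere. tgt is a
# precomputed targetAtoms() list.
softBidentate <- function(groupXform, tgt, class, criteria) {
  grp <- groupAtoms(class, groupXform)
  soft1 <- function(D, H, A, B) {
    d <- sqrt(sum((D - A)^2))
    dha <- bondAngle(D, H, A); hab <- bondAngle(H, A, B)
    ((d - criteria$dIdeal) / criteria$sdD)^2 +
      ((dha - 180) / criteria$sdA)^2 + ((hab - 120) / criteria$sdA)^2
  }
  g <- function(nm) grp[[nm]]
  switch(class,
    AMIDE_BB_SAME =
      min(soft1(g("N"), g("H1"), tgt$O, tgt$C),
          soft1(g("N"), g("H2"), tgt$O, tgt$C)) +
        soft1(tgt$N, tgt$H, g("O"), g("C")),
    AMIDE_BB_CONSEC =
      min(soft1(g("N"), g("H1"), tgt$O, tgt$C),
          soft1(g("N"), g("H2"), tgt$O, tgt$C)) +
        soft1(tgt$N, tgt$H, g("O"), g("C")),
    CARBOX_2NH =
      soft1(tgt$N1, tgt$H1, g("O1"), g("C")) +
        soft1(tgt$N2, tgt$H2, g("O2"), g("C")),
    AMIDE_SC_SERTHR =
      soft1(tgt$N, tgt$H, g("O"), g("C")) +
        min(soft1(g("N"), g("H1"), tgt$OG, tgt$CB),
            soft1(g("N"), g("H2"), tgt$OG, tgt$CB)),
    stop("soft score undefined for class ", class))
}

# simple derivative-free compass/pattern search; f is minimised; monotone
patternSearch <- function(f, x0, step0, minStep = 1e-4, maxit = 200) {
  x <- x0; fx <- f(x); step <- step0
  for (it in seq_len(maxit)) {
    improved <- FALSE
    for (i in seq_along(x)) for (s in c(1, -1)) {
      xt <- x; xt[i] <- xt[i] + s * step[i]
      ft <- f(xt)
      if (ft < fx) { x <- xt; fx <- ft; improved <- TRUE }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < minStep)) break
    }
  }
  list(par = x, value = fx)
}

# 6-DOF parametrisation of a group transform around a base pose
poseTransform <- function(x) {
  R <- rotationAboutAxis(c(1, 0, 0), x[4]) %*%
       rotationAboutAxis(c(0, 1, 0), x[5]) %*%
       rotationAboutAxis(c(0, 0, 1), x[6])
  rigidTransform(R, x[1:3])
}

# find a criteria-passing group placement against a fragment by multistart
# pattern search on the soft score (deterministic given the RNG state)
# rigid transform mapping local points p1 -> q1 and p2 -> q2, with the
# remaining spin about the q1-q2 axis set to spinDeg
twoPointSpinTransform <- function(p1, p2, q1, q2, spinDeg) {
  a <- (p2 - p1); a <- a / sqrt(sum(a^2))
  b <- (q2 - q1); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  R0 <- if (s < 1e-12) {
    if (cth > 0) diag(3) else {
      w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ax <- c(a[2] * w[3] - a[3] * w[2], a[3] * w[1] - a[1] * w[3],
              a[1] * w[2] - a[2] * w[1])
      rotationAboutAxis(ax, 180)
    }
  } else rotationAboutAxis(v, atan2(s, cth) * 180 / pi)
  R <- rotationAboutAxis(b, spinDeg) %*% R0
  rigidTransform(R, q1 - as.numeric(R %*% p1))
}

# unit vector making the ideal acceptor-approach angle with axis u, at
# azimuth omega around it
coneDir <- function(u, halfAngleDeg, omegaDeg) {
  u <- u / sqrt(sum(u^2))
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  h <- halfAngleDeg * pi / 180; o <- omegaDeg * pi / 180
  cos(h) * u + sin(h) * (cos(o) * e1 + sin(o) * e2)
}

# Deterministic anchored seeding: one component bond is constructed at
# ideal geometry analytically (two free angles: acceptor-approach azimuth
# and spin about the bond), the free angles are scanned on a 15-degree
# grid, and the best grid points are refined by pattern search on the
# soft score.
seedPlacement <- function(chain, resIndex, class, criteria) {
  tgt <- targetAtoms(chain, resIndex, class)
  loc <- groupLocal(class)
  # anchored bond: group-as-donor for amide classes (H1 -> backbone O),
  # group-as-acceptor for carboxylate (O1 <- backbone H) and Ser/Thr
  # (group O <- backbone H)
  donorAnchored <- class %in% c("AMIDE_BB_SAME", "AMIDE_BB_CONSEC")
  if (donorAnchored) { A <- tgt$O; B <- tgt$C }  # CONSEC: O of residue i+1
  grid <- expand.grid(w1 = seq(0, 345, by = 15), w2 = seq(0, 345, by = 15))
  poses <- vector("list", nrow(grid)); scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w1 <- grid$w1[i]; w2 <- grid$w2[i]
    xf <- if (donorAnchored) {
      u <- (A - B)
      v <- coneDir(u, 60, w1)           # H...A-B = 120 at the acceptor
      qN <- A + criteria$dIdeal * v
      qH <- A + (criteria$dIdeal - 1.01) * v
      twoPointSpinTransform(loc$N, loc$H1, qN, qH, w2)
    } else if (class == "CARBOX_2NH") {
      D <- tgt$N1; H <- tgt$H1
      qA <- D + criteria$dIdeal * (H - D) / sqrt(sum((H - D)^2))
      u <- (qA - H)
      w <- coneDir(u, 60, w1)           # base C on the acceptor cone
      qC <- qA + 1.25 * w
      twoPointSpinTransform(loc$O1, loc$C, qA, qC, w2)
    } else {                             # AMIDE_SC_SERTHR
      D <- tgt$N; H <- tgt$H
      qA <- D + criteria$dIdeal * (H - D) / sqrt(sum((H - D)^2))
      u <- (qA - H)
      w <- coneDir(u, 60, w1)
      qC <- qA + 1.231 * w
      twoPointSpinTransform(loc$O, loc$C, qA, qC, w2)
    }
    poses[[i]] <- xf
    scores[i] <- softBidentate(xf, tgt, class, criteria)
  }
  ord <- order(scores)
  best <- NULL; bestScore <- Inf
  for (i in ord[seq_len(min(6, length(ord)))]) {
    # refine in 6-DOF pose coordinates around the grid pose
    base <- poses[[i]]
    f <- function(x) {
      pert <- poseTransform(x)
      org <- base@translation
      softBidentate(composeTransforms(
        rigidTransform(diag(3), org),
        composeTransforms(pert, composeTransforms(
          rigidTransform(diag(3), -org), base))), tgt, class, criteria)
    }
    fit <- patternSearch(f, rep(0, 6), step0 = c(rep(0.4, 3), rep(10, 3)),
                         maxit = 150)
    if (fit$value < bestScore) {
      bestScore <- fit$value
      org <- base@translation
      best <- composeTransforms(
        rigidTransform(diag(3), org),
        composeTransforms(poseTransform(fit$par), composeTransforms(
          rigidTransform(diag(3), -org), base)))
    }
    hard <- bidentateCore(best, tgt, class, criteria)
    if (hard$accept && hard$score < 0.5) break
  }
  hard <- bidentateCore(best, tgt, class, criteria)
  if (!hard$accept)
    stop("could not seed a criteria-passing ", class,
         " placement (best soft score ", round(bestScore, 2), ")")
  list(xform = best, score = hard$score)
}

#' Monte Carlo sampling of low-score bidentate placements
#'
#' Metropolis sampling over the rigid-body pose of the side-chain
#' functional group relative to a backbone fragment, and the fragment's
#' backbone torsions. Rigid-body proposals draw Euler angles from
#' N(0 deg, 60 deg) and translations from N(0 A, 1 A) per axis; torsion
#' proposals redraw (phi, psi) from the Ramachandran model. Proposals that
#' lose either component interaction are discarded; otherwise moves are
#' accepted when the score improves or with probability
#' exp(-delta score / T).
#'
#' @param class a hydrogen-bond [bidentateClasses()] string.
#' @param criteria an [hbondCriteria()].
#' @param nSteps number of MC steps (>= 0).
#' @param rngSeed integer seed; output is deterministic given the seed.
#' @param rama a [ramaModel()] for torsion redraws.
#' @param temperature Metropolis temperature in score units (default 1).
#' @return list of accepted placements, each
#'   \code{list(relXform, phi, psi, chi1, score)} where \code{relXform} is
#'   the group pose expressed in the target residue's backbone frame.
#' @export
mcSampleBidentate <- function(class, criteria = hbondCriteria(),
                              nSteps = 1000, rngSeed = 1,
                              rama = NULL, temperature = 1) {
  stopifnot(nSteps >= 0)
  if (nSteps == 0) return(list())
  if (is.null(rama)) rama <- defaultRamaModel()
  set.seed(rngSeed)
  # class-specific starting torsions: each class's bidentate geometry is
  # satisfiable only in parts of the Ramachandran torus (carboxylate
  # bridging of successive N-H needs alpha-like turns; the consecutive
  # amide bridge needs extended psi < 0 or left-handed conformations)
  start <- switch(class,
                  AMIDE_BB_SAME = c(-75, 145),
                  AMIDE_BB_CONSEC = c(-90, -140),
                  CARBOX_2NH = c(-63, -43),
                  AMIDE_SC_SERTHR = c(-75, 145),
                  c(-75, 145))
  phi <- start[1]; psi <- start[2]; chi1 <- -60
  frag <- mcFragment(phi, psi, class, chi1)
  tgt <- targetAtoms(frag, 2L, class)
  seed <- seedPlacement(frag, 2L, class, criteria)
  xf <- seed$xform; score <- seed$score
  out <- list()
  for (i in seq_len(nSteps)) {
    moveTor <- stats::runif(1) < 0.3
    if (moveTor) {
      p <- ramaSamplePair(rama, "generic")
      nphi <- p[1]; npsi <- p[2]
      nchi1 <- if (class == "AMIDE_SC_SERTHR")
        sample(c(-60, 60, 180), 1) else chi1
      nfrag <- mcFragment(nphi, npsi, class, nchi1)
      ntgt <- targetAtoms(nfrag, 2L, class)
      nxf <- xf
    } else {
      ang <- stats::rnorm(3, 0, 60)
      tr <- stats::rnorm(3, 0, 1)
      pert <- rigidTransform(
        rotationAboutAxis(c(1, 0, 0), ang[1]) %*%
          rotationAboutAxis(c(0, 1, 0), ang[2]) %*%
          rotationAboutAxis(c(0, 0, 1), ang[3]), tr)
      # perturb about the group's own origin
      org <- applyTransform(xf, c(0, 0, 0))
      toOrg <- rigidTransform(diag(3), -org)
      nxf <- composeTransforms(invertTransform(toOrg),
                               composeTransforms(pert,
                                                 composeTransforms(toOrg, xf)))
      nphi <- phi; npsi <- psi; nchi1 <- chi1; nfrag <- frag; ntgt <- tgt
    }
    ev <- bidentateCore(nxf, ntgt, class, criteria)
    if (!ev$accept) next
    if (ev$score <= score ||
        stats::runif(1) < exp(-(ev$score - score) / temperature)) {
      xf <- nxf; score <- ev$score
      phi <- nphi; psi <- npsi; chi1 <- nchi1; frag <- nfrag; tgt <- ntgt
      rel <- composeTransforms(invertTransform(residueFrame(frag, 2L)), xf)
      out[[length(out) + 1L]] <-
        list(relXform = rel, phi = phi, psi = psi, chi1 = chi1,
             score = score)
    }
  }
  out
}

# torsion pair entering the key for a class
keyTorsions <- function(class, phi, psi, chi1 = NA_real_) {
  if (classTorsionCount(class) == 0L) return(numeric(0))
  if (class == "AMIDE_SC_SERTHR") c(phi, chi1) else c(phi, psi)
}

#' Build a hash table from sampled placements
#'
#' For every placement and every surviving inverse rotamer of every
#' residue type carrying the class's functional group, one entry is stored
#' under the key of the (target-frame to side-chain-backbone-frame)
#' transform plus the key torsions.
#'
#' @param placements output of [mcSampleBidentate()].
#' @param class interaction class.
#' @param config a [hashConfig()].
#' @param seed,nSteps provenance metadata for the table.
#' @param rotamerSet canonical chi values (default c(-60, 60, 180)).
#' @return An [InteractionHashTable-class].
#' @export
hashTableFromPlacements <- function(placements, class,
                                    config = hashConfig(),
                                    seed = NA_integer_, nSteps = NA_integer_,
                                    rotamerSet = c(-60, 60, 180)) {
  tab <- emptyHashTable(class, config, seed, nSteps)
  for (p in placements) {
    for (resType in classResidues(class)) {
      rots <- inverseRotamers(p$relXform, resType, rotamerSet, class)
      for (r in rots) {
        rel <- r$frame     # already relative to the target frame
        tor <- keyTorsions(class, p$phi, p$psi, p$chi1)
        key <- tryCatch(encodeKey(rel, tor, config), error = function(e) NULL)
        if (is.null(key)) next
        hashInsert(tab, key,
                   list(residue = resType, chis = r$chis, class = class,
                        score = p$score))
      }
    }
  }
  tab
}

#' Sample and hash bidentate geometries in one call
#'
#' Runs [mcSampleBidentate()] and stores every accepted placement's
#' surviving inverse rotamers via [hashTableFromPlacements()].
#'
#' @inheritParams mcSampleBidentate
#' @param config a [hashConfig()].
#' @return An [InteractionHashTable-class] with provenance metadata.
#' @export
buildHashTable <- function(class, config = hashConfig(), nSteps = 1000,
                           rngSeed = 1, criteria = hbondCriteria(),
                           rama = NULL) {
  pl <- mcSampleBidentate(class, criteria, nSteps, rngSeed, rama)
  hashTableFromPlacements(pl, class, config, seed = rngSeed, nSteps = nSteps)
}

#' Export a hash table to TSV (lossless)
#'
#' @param table an [InteractionHashTable-class].
#' @param path output file.
#' @return invisibly, the number of rows written.
#' @export
exportHashTSV <- function(table, path) {
  ks <- sort(ls(table@env))
  rows <- list()
  for (k in ks) {
    for (e in get(k, table@env)) {
      chis <- c(e$chis, rep(NA_real_, 4 - length(e$chis)))
      rows[[length(rows) + 1L]] <-
        data.frame(key = k, class = e$class, residue = e$residue,
                   chi1 = chis[1], chi2 = chis[2], chi3 = chis[3],
                   chi4 = chis[4], score = e$score)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), class = character(), residue = character(),
               chi1 = numeric(), chi2 = numeric(), chi3 = numeric(),
               chi4 = numeric(), score = numeric())
  md <- table@metadata
  hdr <- sprintf("# class=%s seed=%s nSteps=%s transBin=%g transRange=%g rotBin=%g torBin=%g",
                 md$class, as.character(md$seed), as.character(md$nSteps),
                 md$config$transBin, md$config$transRange, md$config$rotBin,
                 md$config$torBin)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(nrow(df))
}

#' Import a hash table from its TSV export
#' @param path file written by [exportHashTSV()].
#' @return An [InteractionHashTable-class].
#' @export
importHashTSV <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(x) strsplit(x, "=")[[1]][2]),
    vapply(kv, function(x) strsplit(x, "=")[[1]][1], character(1)))
  cfg <- hashConfig(transBin = as.numeric(meta$transBin),
                    transRange = as.numeric(meta$transRange),
                    rotBin = as.numeric(meta$rotBin),
                    torBin = as.numeric(meta$torBin))
  tab <- emptyHashTable(meta$class, cfg, as.integer(meta$seed),
                        suppressWarnings(as.integer(meta$nSteps)))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          colClasses = c(key = "character"))
  for (i in seq_len(nrow(df))) {
    chis <- as.numeric(df[i, c("chi1", "chi2", "chi3", "chi4")])
    chis <- chis[!is.na(chis)]
    hashInsert(tab, as.numeric(df$key[i]),
               list(residue = df$residue[i], chis = chis,
                    class = df$class[i], score = df$score[i]))
  }
  tab
}
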