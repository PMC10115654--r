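# Shared fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- force(expr)
  .fixtureCache[[name]]
}

smallRama <- function() memo("rama", ramaModel(nCalib = 1500))

# planted Gln-ladder fixture shared across docking and interface tests
planted <- function() memo("planted",
  plantedLadderFixture(nUnits = 6, rngSeed = 42, nSteps = 400))

# independent cylinder-fit oracle: axis from PCA of CA positions, rise as
# mean axial spacing, twist from successive azimuthal angles
cylinderFitOracle <- function(ca) {
  cen <- colMeans(ca)
  X <- sweep(ca, 2, cen)
  ax <- svd(X)$v[, 1]
  z <- X %*% ax
  if (mean(diff(z)) < 0) { ax <- -ax; z <- -z }
  rise <- mean(diff(z))
  # azimuth in the plane orthogonal to the axis
  e1 <- svd(X)$v[, 2]
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  ang <- atan2(X %*% e2, X %*% e1) * 180 / pi
  dtw <- diff(ang) %% 360
  dtw[dtw > 180] <- dtw[dtw > 180] - 360
  list(rise = rise, twist = mean(dtw))
}

# regex-based independent oracle for the triplet scanner: per frame, map
# in-set triplets to '1' and find runs of '1{minUnits,}' with gregexpr
scanOracle <- function(sequences, triplets, minUnits = 2L) {
  rows <- list()
  for (sid in names(sequences)) {
    s <- toupper(sequences[[sid]]); L <- nchar(s)
    for (off in 0:2) {
      starts <- seq(off + 1L, L - 2L, by = 3L)
      if (length(starts) < 1L) next
      tri <- substring(s, starts, starts + 2L)
      code <- paste(ifelse(tri %in% triplets, "1", "0"), collapse = "")
      m <- gregexpr(sprintf("1{%d,}", minUnits), code)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      for (i in seq_along(m)) {
        s0 <- starts[m[i]] - 1L
        rows[[length(rows) + 1L]] <-
          data.frame(seqId = sid, start0 = s0,
                     end = s0 + 3L * len[i], nUnits = len[i])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqId = character(), start0 = integer(), end = integer(),
               nUnits = integer())
  out <- out[order(out$seqId, out$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# flat slab of tightly packed pseudo-atoms in the z = z0 plane (fine
# spacing keeps the dot-sampled surface nearly flat)
slabChain <- function(z0, chainId = "A", spacing = 0.5, width = 10) {
  g <- expand.grid(x = seq(0, width, spacing), y = seq(0, width, spacing))
  at <- data.frame(resno = 1L, resname = "ALA", atom = "C",
                   x = g$x, y = g$y, z = z0)
  new("BackboneChain", atoms = at, unitLength = 0L, nUnits = 0L,
      chainId = chainId)
}

singleAtomChain <- function(x, y, z, chainId = "A") {
  new("BackboneChain",
      atoms = data.frame(resno = 1L, resname = "ALA", atom = "C",
                         x = x, y = y, z = z),
      unitLength = 0L, nUnits = 0L, chainId = chainId)
}

backboneXYZ <- function(chain) {
  as.matrix(chain@atoms[chain@atoms$atom %in% c("N", "CA", "C", "O"),
                        c("x", "y", "z")])
}
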