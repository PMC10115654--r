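# Bidentate geometry evaluation, inverse rotamers and geometric hashing.

# fabricate a minimal target fragment at exactly ideal geometry for the
# single-residue amide class: both component bonds at d = 2.9, linear
# donor-H-acceptor, 120-degree acceptor-base angles. Explicit H atoms are
# honoured by the evaluator, so no torsion-consistent backbone is needed.
idealSameFixture <- function(shift1 = 0, shift2 = 0) {
  loc <- superdock:::amideGroupLocal()
  w <- c(cos(pi / 3), sin(pi / 3), 0)            # 120 deg from C->O at O
  Nbb <- loc$O + (2.9 + shift2) * w
  Hbb <- Nbb - 1.01 * w
  u1 <- (loc$H1 - loc$N) / sqrt(sum((loc$H1 - loc$N)^2))
  Obb <- loc$N + (2.9 + shift1) * u1
  # base C at 120 deg from the H1 ray, in a fixed plane
  hdir <- (loc$H1 - Obb) / sqrt(sum((loc$H1 - Obb)^2))
  perp <- c(-hdir[2], hdir[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  cdir <- cos(2 * pi / 3) * hdir + sin(2 * pi / 3) * perp
  Cbb <- Obb + 1.231 * cdir
  at <- rbind(
    data.frame(resno = 1, resname = "ALA", atom = "N",
               x = Nbb[1], y = Nbb[2], z = Nbb[3]),
    data.frame(resno = 1, resname = "ALA", atom = "H",
               x = Hbb[1], y = Hbb[2], z = Hbb[3]),
    data.frame(resno = 1, resname = "ALA", atom = "O",
               x = Obb[1], y = Obb[2], z = Obb[3]),
    data.frame(resno = 1, resname = "ALA", atom = "C",
               x = Cbb[1], y = Cbb[2], z = Cbb[3]))
  new("BackboneChain", atoms = at, unitLength = 0L, nUnits = 0L,
      chainId = "B")
}

test_that("evaluateBidentate scores ideal geometry as exactly zero", {
  frag <- idealSameFixture()
  ev <- evaluateBidentate(identityTransform(), frag, 1L, "AMIDE_BB_SAME")
  expect_true(ev$accept)
  expect_lt(ev$score, 1e-9)
})

test_that("a bond outside the distance window rejects the placement", {
  frag <- idealSameFixture(shift1 = 1.6)   # donor-acceptor at 4.5 A
  ev <- evaluateBidentate(identityTransform(), frag, 1L, "AMIDE_BB_SAME")
  expect_false(ev$accept)
  expect_equal(ev$score, Inf)
})

test_that("symmetric +0.2 A stretches score as the hand-computed sum", {
  frag <- idealSameFixture(shift1 = 0.2, shift2 = 0.2)
  ev <- evaluateBidentate(identityTransform(), frag, 1L, "AMIDE_BB_SAME")
  expect_true(ev$accept)
  expect_equal(ev$score, 2 * (0.2 / 0.3)^2, tolerance = 1e-6)
})

test_that("missing atoms are a contract violation", {
  frag <- idealSameFixture()
  frag@atoms <- frag@atoms[frag@atoms$atom != "O", ]
  expect_error(evaluateBidentate(identityTransform(), frag, 1L,
                                 "AMIDE_BB_SAME"), "missing atom")
})

test_that("MC sampling: empty at zero steps, deterministic, revalidates", {
  expect_identical(mcSampleBidentate("AMIDE_BB_SAME", nSteps = 0), list())
  rama <- smallRama()
  a <- mcSampleBidentate("AMIDE_BB_SAME", nSteps = 250, rngSeed = 11,
                         rama = rama)
  b <- mcSampleBidentate("AMIDE_BB_SAME", nSteps = 250, rngSeed = 11,
                         rama = rama)
  expect_identical(a, b)
  expect_gt(length(a), 0)
  expect_lt(length(a), 250)
  # every accepted placement re-validates under evaluateBidentate
  for (p in a) {
    frag <- superdock:::mcFragment(p$phi, p$psi, "AMIDE_BB_SAME")
    xf <- composeTransforms(superdock:::residueFrame(frag, 2L), p$relXform)
    ev <- evaluateBidentate(xf, frag, 2L, "AMIDE_BB_SAME")
    expect_true(ev$accept)
    expect_equal(ev$score, p$score, tolerance = 1e-9)
  }
})

test_that("acceptance predicate is monotone in the criteria", {
  rama <- smallRama()
  pl <- memo("mc_same",
             mcSampleBidentate("AMIDE_BB_SAME", nSteps = 250, rngSeed = 11,
                               rama = rama))
  # perturb accepted placements slightly to spread scores
  set.seed(4)
  frames <- lapply(pl, function(p) {
    frag <- superdock:::mcFragment(p$phi, p$psi, "AMIDE_BB_SAME")
    xf <- composeTransforms(superdock:::residueFrame(frag, 2L), p$relXform)
    xf@translation <- xf@translation + rnorm(3, sd = 0.15)
    list(frag = frag, xf = xf)
  })
  countAccepted <- function(crit) {
    sum(vapply(frames, function(f)
      evaluateBidentate(f$xf, f$frag, 2L, "AMIDE_BB_SAME", crit)$accept,
      logical(1)))
  }
  loose <- hbondCriteria()
  tighter <- hbondCriteria(dMin = 2.7, dMax = 3.2, dhaMin = 155)
  tightest <- hbondCriteria(dMin = 2.8, dMax = 3.0, dhaMin = 170,
                            habMin = 110)
  n1 <- countAccepted(loose); n2 <- countAccepted(tighter)
  n3 <- countAccepted(tightest)
  expect_gte(n1, n2)
  expect_gte(n2, n3)
})

test_that("inverse rotamers are forward-consistent and bounded", {
  rama <- smallRama()
  pl <- memo("mc_same",
             mcSampleBidentate("AMIDE_BB_SAME", nSteps = 250, rngSeed = 11,
                               rama = rama))
  p <- pl[[1]]
  # Gln: 3 chi -> at most 27 combinations survive pruning
  rots <- inverseRotamers(p$relXform, "GLN", class = "AMIDE_BB_SAME")
  expect_gt(length(rots), 0)
  expect_lte(length(rots), 27)
  grpTarget <- superdock:::groupAtoms("AMIDE_BB_SAME", p$relXform)
  for (r in rots[seq_len(min(5, length(rots)))]) {
    fwd <- buildSideChain("GLN", r$atoms$N, r$atoms$CA, r$atoms$C, r$chis)
    expect_lt(max(abs(fwd$OE1 - grpTarget$O)), 1e-3)
    expect_lt(max(abs(fwd$NE2 - grpTarget$N)), 1e-3)
    expect_lt(max(abs(fwd$CD - grpTarget$C)), 1e-3)
  }
  # Ser for the Ser/Thr-class amide partner side is Asn/Gln; Ser itself
  # has 1 chi and at most 3 frames in any class that uses it
  expect_equal(chiCount("SER"), 1L)
  expect_equal(chiCount("ASN"), 2L)
  expect_equal(chiCount("GLN"), 3L)
  expect_equal(chiCount("ASP"), 2L)
  expect_equal(chiCount("GLU"), 3L)
  # round trip: frame from a known rotamer inverts to itself
  bb <- superdock:::canonicalBackbone()
  chis <- c(-60, 180, 60)
  atoms <- buildSideChain("GLN", bb$N, bb$CA, bb$C, chis)
  gx <- superdock:::groupFrameFromAtoms("AMIDE_BB_SAME", atoms)
  rots2 <- inverseRotamers(gx, "GLN", class = "AMIDE_BB_SAME")
  hit <- vapply(rots2, function(r)
    all(r$chis == chis) && max(abs(r$atoms$CA - bb$CA)) < 1e-3 &&
      max(abs(r$atoms$N - bb$N)) < 1e-3, logical(1))
  expect_true(any(hit))
})

# transform whose translation/rotation/torsion coordinates sit at bin
# centres of the default config
binCentreCase <- function(tx, ty, tz, a, b, g, t1, t2) {
  cfg <- hashConfig()
  tr <- c(-cfg$transRange + (c(tx, ty, tz) + 0.5) * cfg$transBin)
  eul <- c((a + 0.5) * cfg$rotBin - 180, (b + 0.5) * cfg$rotBin,
           (g + 0.5) * cfg$rotBin - 180)
  R <- rotationAboutAxis(c(0, 0, 1), eul[1]) %*%
    rotationAboutAxis(c(0, 1, 0), eul[2]) %*%
    rotationAboutAxis(c(0, 0, 1), eul[3])
  list(transform = rigidTransform(R, tr),
       torsions = c(-180 + (c(t1, t2) + 0.5) * cfg$torBin),
       euler = eul)
}

test_that("encodeKey is deterministic, local and bin-sensitive", {
  cs <- binCentreCase(17, 12, 20, 10, 5, 3, 9, 22)
  k0 <- encodeKey(cs$transform, cs$torsions)
  expect_identical(k0, encodeKey(cs$transform, cs$torsions))
  # 0.01 A jitter within the bin: same key
  t2 <- cs$transform; t2@translation <- t2@translation + 0.01
  expect_identical(encodeKey(t2, cs$torsions), k0)
  # one full translation bin: different key
  t3 <- cs$transform; t3@translation <- t3@translation + c(1, 0, 0)
  expect_false(encodeKey(t3, cs$torsions) == k0)
  # one torsion bin: different key
  expect_false(encodeKey(cs$transform, cs$torsions + c(10, 0)) == k0)
  # out-of-range translation errors
  t4 <- cs$transform; t4@translation <- c(20, 0, 0)
  expect_error(encodeKey(t4, cs$torsions), "out of hash range")
})

test_that("store/query round trip: 1000 stored placements, 100% hit", {
  tab <- emptyHashTable("AMIDE_BB_SAME")
  set.seed(99)
  cases <- lapply(1:1000, function(i) {
    binCentreCase(sample(0:31, 1), sample(0:31, 1), sample(0:31, 1),
                  sample(0:23, 1), sample(1:10, 1), sample(0:23, 1),
                  sample(0:35, 1), sample(0:35, 1))
  })
  for (i in seq_along(cases)) {
    superdock:::hashInsert(tab, encodeKey(cases[[i]]$transform,
                                          cases[[i]]$torsions),
                           list(residue = "GLN", chis = c(-60, 60, 180),
                                class = "AMIDE_BB_SAME", score = i))
  }
  hits <- vapply(cases, function(cs)
    length(queryHash(tab, cs$transform, cs$torsions)) > 0, logical(1))
  expect_equal(mean(hits), 1.0)
})

test_that("locality: quarter-bin perturbations hit, two-bin shifts miss", {
  tab <- emptyHashTable("AMIDE_BB_SAME")
  set.seed(77)
  cases <- lapply(1:200, function(i)
    binCentreCase(sample(2:29, 1), sample(2:29, 1), sample(2:29, 1),
                  sample(0:23, 1), sample(2:9, 1), sample(0:23, 1),
                  sample(0:35, 1), sample(0:35, 1)))
  for (i in seq_along(cases))
    superdock:::hashInsert(tab, encodeKey(cases[[i]]$transform,
                                          cases[[i]]$torsions),
                           list(residue = "GLN", chis = c(-60, 60, 180),
                                class = "AMIDE_BB_SAME", score = i))
  cfg <- hashConfig()
  hitQ <- vapply(cases, function(cs) {
    dtr <- runif(3, -0.25, 0.25) * cfg$transBin
    deu <- runif(3, -0.25, 0.25) * cfg$rotBin
    dto <- runif(2, -0.25, 0.25) * cfg$torBin
    eul <- cs$euler + deu
    R <- rotationAboutAxis(c(0, 0, 1), eul[1]) %*%
      rotationAboutAxis(c(0, 1, 0), eul[2]) %*%
      rotationAboutAxis(c(0, 0, 1), eul[3])
    q <- rigidTransform(R, cs$transform@translation + dtr)
    length(queryHash(tab, q, cs$torsions + dto)) > 0
  }, logical(1))
  expect_gte(mean(hitQ), 0.95)
  hit2 <- vapply(seq_along(cases), function(i) {
    q <- cases[[i]]$transform
    q@translation <- q@translation + c(2 * cfg$transBin, 0, 0)
    any(vapply(queryHash(tab, q, cases[[i]]$torsions), function(e)
      identical(e$score, i), logical(1)))
  }, logical(1))
  expect_equal(mean(hit2), 0)
})

test_that("neighbour-bin search finds entries one bin off", {
  cs <- binCentreCase(10, 10, 10, 5, 5, 5, 5, 5)
  tab <- emptyHashTable("AMIDE_BB_SAME")
  superdock:::hashInsert(tab, encodeKey(cs$transform, cs$torsions),
                         list(residue = "ASN", chis = c(-60, 60),
                              class = "AMIDE_BB_SAME", score = 0))
  q <- cs$transform
  q@translation <- q@translation + c(1, 0, 0)
  expect_length(queryHash(tab, q, cs$torsions), 0)
  expect_length(queryHash(tab, q, cs$torsions, neighbours = TRUE), 1)
})

test_that("query rejects a mismatched config", {
  tab <- emptyHashTable("AMIDE_BB_SAME", hashConfig())
  cs <- binCentreCase(10, 10, 10, 5, 5, 5, 5, 5)
  expect_error(queryHash(tab, cs$transform, cs$torsions,
                         config = hashConfig(transBin = 0.5)),
               "config mismatch")
})

test_that("built tables re-instantiate within one bin of slack and
           serialise deterministically", {
  rama <- smallRama()
  pl <- memo("mc_same",
             mcSampleBidentate("AMIDE_BB_SAME", nSteps = 250, rngSeed = 11,
                               rama = rama))
  tab <- hashTableFromPlacements(pl, "AMIDE_BB_SAME", seed = 11,
                                 nSteps = 250)
  sz <- hashTableSize(tab)
  expect_gt(sz$nEntries, 0)
  # empty table from zero steps
  t0 <- buildHashTable("AMIDE_BB_SAME", nSteps = 0, rngSeed = 1)
  expect_equal(hashTableSize(t0)$nKeys, 0)
  expect_equal(t0@metadata$class, "AMIDE_BB_SAME")
  # re-instantiation: every stored entry, rebuilt from its placement's
  # geometry, passes criteria relaxed by one bin width of slack
  relaxed <- hbondCriteria(dMin = 2.6 - 1.0, dMax = 3.4 + 1.0,
                           dhaMin = 140 - 15, habMin = 90 - 15)
  for (p in pl[seq_len(min(5, length(pl)))]) {
    frag <- superdock:::mcFragment(p$phi, p$psi, "AMIDE_BB_SAME")
    for (resType in c("ASN", "GLN")) {
      rots <- inverseRotamers(p$relXform, resType, class = "AMIDE_BB_SAME")
      for (r in rots[seq_len(min(3, length(rots)))]) {
        fr <- superdock:::residueFrame(frag, 2L)
        atoms <- lapply(r$atoms, function(a) applyTransform(fr, a))
        gx <- superdock:::groupFrameFromAtoms("AMIDE_BB_SAME", atoms)
        ev <- evaluateBidentate(gx, frag, 2L, "AMIDE_BB_SAME", relaxed)
        expect_true(ev$accept)
      }
    }
  }
  # TSV export round trip is byte-stable
  f1 <- tempfile(); f2 <- tempfile()
  exportHashTSV(tab, f1)
  tab2 <- importHashTSV(f1)
  exportHashTSV(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(hashTableSize(tab2), sz)
})
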