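# Torsion-space backbone construction and peptide sampling.

test_that("single residue and torsion normalisation base cases", {
  ch <- buildBackbone(data.frame(phi = 0, psi = 0, omega = 180))
  expect_equal(nResidues(ch), 1L)
  expect_equal(unname(atomCoords(ch, "N")[1, ]), c(0, 0, 0))
  # out-of-range torsions are normalised, not rejected
  ch2 <- buildBackbone(data.frame(phi = 270, psi = -190, omega = 540))
  tor <- attr(ch2, "torsions")
  expect_equal(tor$phi, -90)
  expect_equal(tor$psi, 170)
  expect_equal(tor$omega, 180)
  expect_error(buildBackbone(data.frame(phi = numeric(), psi = numeric())),
               "empty")
})

test_that("torsion round trip over random torsion sets (1e-4 deg)", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    tt <- data.frame(phi = runif(n, -179, 179), psi = runif(n, -179, 179),
                     omega = runif(n, 160, 200))
    bb <- buildBackbone(tt)
    mm <- measureTorsions(bb)
    dphi <- abs(mm$phi[-1] - tt$phi[-1])
    dpsi <- abs(((mm$psi[-n] - tt$psi[-n] + 180) %% 360) - 180)
    domg <- abs(((mm$omega[-n] - tt$omega[-n] + 180) %% 360) - 180)
    expect_lt(max(dphi), 1e-4)
    expect_lt(max(dpsi), 1e-4)
    expect_lt(max(domg), 1e-4)
  }
})

test_that("built chains carry ideal bond geometry", {
  g <- residueGeometry()
  ch <- buildBackbone(data.frame(phi = rep(-75, 6), psi = rep(145, 6),
                                 omega = 180))
  N <- atomCoords(ch, "N"); CA <- atomCoords(ch, "CA")
  C <- atomCoords(ch, "C")
  expect_equal(unname(sqrt(rowSums((CA - N)^2))), rep(g$nca, 6),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(rowSums((C - CA)^2))), rep(g$cac, 6),
               tolerance = 1e-6)
  cn <- unname(sqrt(rowSums((N[-1, ] - C[-6, ])^2)))
  expect_equal(cn, rep(g$cn, 5), tolerance = 1e-6)
})

test_that("canonical PPII has about three residues per turn", {
  ch <- buildBackbone(data.frame(phi = rep(-75, 12), psi = rep(145, 12),
                                 omega = 180), "ALA",
                      unitLength = 1L, nUnits = 12L)
  p <- chainSuperhelix(ch)
  expect_equal(360 / abs(p@twist), 3, tolerance = 0.15)
  expect_lt(p@twist, 0)    # left-handed
})

test_that("alpha-helix torsions give ~1.5 A rise per residue", {
  ch <- buildBackbone(data.frame(phi = rep(-57, 12), psi = rep(-47, 12),
                                 omega = 180), "ALA",
                      unitLength = 1L, nUnits = 12L)
  p <- chainSuperhelix(ch)
  expect_equal(p@rise, 1.5, tolerance = 0.1)
  ora <- cylinderFitOracle(atomCoords(ch, "CA"))
  expect_equal(p@rise, ora$rise, tolerance = 0.1)
})

test_that("buildPPII names prolines and has helical i->i+3 spacing", {
  ch <- buildPPII(18, prolinePositions = seq(1, 18, by = 3))
  expect_equal(ch@nUnits, 6L)
  rn <- residueNames(ch)
  expect_true(all(rn[seq(1, 18, 3)] == "PRO"))
  expect_true(all(rn[seq(2, 18, 3)] == "ALA"))
  ch1 <- ch; ch1@unitLength <- 1L; ch1@nUnits <- 18L
  p <- chainSuperhelix(ch1)
  expect_equal(p@twist, -120, tolerance = 1)
  # i -> i+3 axial separation is 3x the per-residue rise
  al <- alignAxisToZ(ch1, chainSuperhelix(ch1))
  ca <- atomCoords(al, "CA")
  dz3 <- abs(ca[4:18, 3] - ca[1:15, 3])
  expect_equal(mean(dz3), 3 * p@rise, tolerance = 1e-3)
})

test_that("sampleRepeatPeptide: lengths, determinism, repeat exactness", {
  rama <- smallRama()
  for (cfg in list(c(2, 4), c(3, 6), c(2, 6), c(3, 4))) {
    ch <- sampleRepeatPeptide(cfg[1], cfg[2], rama, rngSeed = 9)
    expect_equal(nResidues(ch), cfg[1] * cfg[2])
    tor <- attr(ch, "torsions")
    # torsions repeat exactly across units
    ref <- tor$phi[seq_len(cfg[1])]
    expect_equal(tor$phi, rep(ref, cfg[2]))
    # unit-to-unit superposition rmsd < 1e-6
    for (u in seq_len(cfg[2] - 1)) {
      a <- superdock:::unitBackboneCoords(ch, u)
      b <- superdock:::unitBackboneCoords(ch, u + 1)
      expect_lt(superpose(a, b)$rmsd, 1e-6)
    }
  }
  a <- sampleRepeatPeptide(3, 5, rama, rngSeed = 77)
  b <- sampleRepeatPeptide(3, 5, rama, rngSeed = 77)
  expect_identical(a@atoms, b@atoms)
})

test_that("sampled peptides pass the Ramachandran filter and clash check", {
  rama <- smallRama()
  for (seed in 1:25) {
    ch <- sampleRepeatPeptide(3, 4, rama, rngSeed = seed)
    tor <- attr(ch, "torsions")
    for (j in 1:3)
      expect_true(ramaAccept(rama, tor$phi[j], tor$psi[j], "generic"))
    expect_equal(superdock:::selfClashCount(ch), 0L)
  }
})

test_that("DHR fixture realises its target and repeats exactly", {
  tgt <- new("SuperhelixParams", rise = 9.3, twist = -40, radius = 12,
             axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
  ch <- generateDHRFixture(helixLen = 20, loopLen = 3, nUnits = 4,
                           target = tgt, rngSeed = 7, nStarts = 10)
  a <- attr(ch, "achieved")
  expect_lt(abs(a@rise - 9.3), 0.1)
  expect_lt(abs(a@twist - (-40)), 1)
  expect_lt(abs(a@radius - 12), 0.5)
  p <- chainSuperhelix(ch)
  expect_lt(abs(p@rise - 9.3), 0.1)
  # first 4 units of a 6-unit build from the same seed superpose exactly
  ch6 <- generateDHRFixture(helixLen = 20, loopLen = 3, nUnits = 6,
                            target = tgt, rngSeed = 7, nStarts = 10)
  k <- ch@unitLength
  a4 <- superdock:::unitBackboneCoords(ch, 1)
  b4 <- superdock:::unitBackboneCoords(ch6, 1)
  expect_lt(max(abs(a4 - b4)), 1e-9)
  # a target outside the curation filter is still *built*; the filter
  # rejects it downstream
  tgtWide <- new("SuperhelixParams", rise = 5, twist = -40, radius = 20,
                 axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
  chW <- generateDHRFixture(helixLen = 20, loopLen = 3, nUnits = 2,
                            target = tgtWide, rngSeed = 11, nStarts = 10)
  expect_false(dhrGeometryFilter(attr(chW, "achieved")))
  expect_true(dhrGeometryFilter(attr(ch, "achieved")))
})

test_that("flank extension keeps the core bit-identical", {
  rama <- smallRama()
  core <- buildPPII(12, resnames = rep(c("PRO", "LEU", "PRO"), 4))
  ext <- extendPeptideFlank(core, "PEDPEQPPKPPF", rama, nSamples = 3,
                            rngSeed = 3)
  expect_length(ext, 3)
  for (e in ext) {
    expect_equal(nResidues(e), 24L)
    nc <- nrow(core@atoms)
    expect_identical(e@atoms[seq_len(nc), c("x", "y", "z")],
                     core@atoms[, c("x", "y", "z")])
    expect_equal(superdock:::selfClashCount(e), 0L)
  }
  # empty flank returns the core unchanged
  expect_identical(extendPeptideFlank(core, "", rama)[[1]], core)
  # determinism
  e2 <- extendPeptideFlank(core, "PEDPEQPPKPPF", rama, nSamples = 3,
                           rngSeed = 3)
  expect_identical(lapply(ext, slot, "atoms"), lapply(e2, slot, "atoms"))
  # N-terminal attachment renumbers the core after the flank
  extN <- extendPeptideFlank(core, "GSG", rama, nSamples = 1,
                             cTerminal = FALSE, rngSeed = 4)[[1]]
  expect_equal(nResidues(extN), 15L)
  expect_equal(residueNames(extN)[1:3], c("GLY", "SER", "GLY"))
})
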