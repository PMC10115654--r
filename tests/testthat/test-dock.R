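# Superhelix matching, grid docking and the planted-ladder pipeline.

test_that("matchSuperhelices applies the rise/twist/radius thresholds", {
  mk <- function(rise, twist, radius)
    new("SuperhelixParams", rise = rise, twist = twist, radius = radius,
        axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
  prot <- mk(9.0, 60, 10)
  # peptide unit that composes to (9.0, 60 deg) at k = 3 and differs by
  # 7 A in radius: pass
  pep <- mk(3.0, 20, 3)
  r <- matchSuperhelices(prot, pep, matchCriteria())
  expect_true(r$pass)
  expect_equal(r$bestK, 3L)
  expect_equal(r$deltas$dRadius[3], 7, tolerance = 1e-9)
  # rise off by 0.3 A after composition (3 x 3.1 = 9.3): fail
  r2 <- matchSuperhelices(prot, mk(3.1, 20, 3), matchCriteria())
  expect_false(r2$pass)
  expect_gt(r2$deltas$dRise[3], 0.2)
  # radius gap of only 2 A: fail
  r3 <- matchSuperhelices(prot, mk(3.0, 20, 8), matchCriteria())
  expect_false(r3$pass)
  # twist off by 6 deg at k = 3 (3 x 22 = 66): fail; within 5 at 21.5: pass
  expect_false(matchSuperhelices(prot, mk(3.0, 22, 3),
                                 matchCriteria())$pass)
  expect_true(matchSuperhelices(prot, mk(3.0, 21.5, 3),
                                matchCriteria())$pass)
})

test_that("tightening match criteria never admits more pairs", {
  set.seed(31)
  mk <- function(rise, twist, radius)
    new("SuperhelixParams", rise = rise, twist = twist, radius = radius,
        axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
  prot <- mk(9.0, 60, 10)
  peps <- lapply(1:60, function(i)
    mk(runif(1, 2.8, 3.2), runif(1, 18, 22), runif(1, 2, 8)))
  count <- function(crit)
    sum(vapply(peps, function(p)
      matchSuperhelices(prot, p, crit)$pass, logical(1)))
  loose <- matchCriteria(maxDeltaRise = 0.3, maxDeltaTwist = 8,
                         minDeltaRadius = 3)
  mid <- matchCriteria()
  tight <- matchCriteria(maxDeltaRise = 0.1, maxDeltaTwist = 2,
                         minDeltaRadius = 6)
  expect_gte(count(loose), count(mid))
  expect_gte(count(mid), count(tight))
})

test_that("clash counting conventions", {
  a <- buildPPII(6)
  far <- transformChain(buildPPII(6), rigidTransform(diag(3), c(50, 0, 0)))
  expect_equal(clashCheck(a, far), 0L)
  expect_gte(clashCheck(a, a), nResidues(a))
  # a pair at exactly the cutoff is not a clash
  p1 <- singleAtomChain(0, 0, 0)
  p1@atoms$atom <- "CA"
  p2 <- singleAtomChain(2.8, 0, 0, "B")
  p2@atoms$atom <- "CA"
  expect_equal(clashCheck(p1, p2), 0L)
  p2@atoms$x <- 2.8 - 1e-9
  expect_equal(clashCheck(p1, p2), 1L)
})

test_that("grid enumeration and degenerate dock cases", {
  fx <- planted()
  pp <- chainSuperhelix(fx$protein)
  docks <- gridDock(fx$protein, fx$peptide, stepR = 10,
                    proteinParams = pp)
  rots <- unique(vapply(docks, slot, numeric(1), "rotDeg"))
  expect_lte(length(rots), 36)
  expect_true(all(rots %in% seq(0, 350, by = 10)))
  # a dense chain docked against itself at the same radius: every grid
  # point clashes
  docks0 <- gridDock(fx$peptide, fx$peptide, stepR = 30,
                     proteinParams = chainSuperhelix(fx$peptide))
  expect_length(docks0, 0)
  # unaligned input is a contract violation
  tilted <- transformChain(fx$peptide,
                           rigidTransform(rotationAboutAxis(c(1, 0, 0), 20),
                                          c(0, 0, 0)))
  expect_error(gridDock(fx$protein, tilted, proteinParams = pp),
               "aligned")
})

test_that("planted ladder is recovered through match-dock-hash-refine", {
  fx <- planted()
  pp <- chainSuperhelix(fx$protein)
  up <- chainSuperhelix(fx$peptide)
  # superhelix parameters match at k = 1 with a clear radius gap
  mr <- matchSuperhelices(pp, up, matchCriteria())
  expect_true(mr$pass)
  docks <- gridDock(fx$protein, fx$peptide, proteinParams = pp)
  docks <- lapply(docks, function(d)
    findHashMatches(d, fx$protein, fx$peptide, list(fx$table)))
  surv <- filterDocksByMatches(docks, fx$protein@nUnits)
  expect_gte(length(surv), 1)
  best <- surv[[which.max(vapply(surv, function(d) nrow(d@matches),
                                 integer(1)))]]
  # matches cover every repeat unit, in one equivalence class
  expect_equal(sort(best@matches$pepRes), fx$targetResidues)
  expect_equal(length(unique(best@matches$equivClass)), 1L)
  ref <- refineDock(best, fx$protein, fx$peptide)
  expect_equal(ref@clashes, 0L)
  pepRef <- transformChain(fx$peptide, ref@transform)
  rms <- coordRMSD(backboneXYZ(pepRef), backboneXYZ(fx$peptide))
  expect_lt(rms, 0.5)
})

test_that("a rotated-away dock yields no hash matches", {
  fx <- planted()
  xf <- rigidTransform(rotationAboutAxis(c(0, 0, 1), 173), c(0, 0, 0.4))
  d <- new("Dock", rotDeg = 173, transA = 0.4, transform = xf,
           matches = superdock:::emptyMatches(), clashes = 0L)
  pep <- transformChain(fx$peptide, xf)
  if (clashCheck(fx$protein, pep) == 0L) {
    d2 <- findHashMatches(d, fx$protein, fx$peptide, list(fx$table))
    expect_equal(nrow(d2@matches), 0L)
  } else succeed("rotated pose clashes; discarded before hashing")
})

test_that("raising the match-count threshold never keeps more docks", {
  fx <- planted()
  pp <- chainSuperhelix(fx$protein)
  docks <- memo("plantedDocks", {
    ds <- gridDock(fx$protein, fx$peptide, proteinParams = pp)
    lapply(ds, function(d)
      findHashMatches(d, fx$protein, fx$peptide, list(fx$table)))
  })
  n <- vapply(0:7, function(thr) length(filterDocksByMatches(docks, thr)),
              integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("screw-symmetry maps the surviving dock onto itself", {
  fx <- planted()
  pp <- chainSuperhelix(fx$protein)
  docks <- memo("plantedDocks", {
    ds <- gridDock(fx$protein, fx$peptide, proteinParams = pp)
    lapply(ds, function(d)
      findHashMatches(d, fx$protein, fx$peptide, list(fx$table)))
  })
  surv <- filterDocksByMatches(docks, 1L)
  best <- surv[[which.max(vapply(surv, function(d) nrow(d@matches),
                                 integer(1)))]]
  # apply the protein's repeat screw to the docked peptide: matches per
  # shared unit are preserved up to end effects (one unit slides off)
  sym <- buildTransform(pp)
  pepSym <- transformChain(transformChain(fx$peptide, best@transform), sym)
  expect_equal(clashCheck(fx$protein, pepSym), 0L)
  d2 <- new("Dock", rotDeg = NA_real_, transA = NA_real_,
            transform = composeTransforms(sym, best@transform),
            matches = superdock:::emptyMatches(), clashes = 0L)
  d2 <- findHashMatches(d2, fx$protein, fx$peptide, list(fx$table))
  expect_gte(nrow(d2@matches), nrow(best@matches) - 1L)
})

test_that("refinement is monotone and stable at an optimum", {
  fx <- planted()
  pp <- chainSuperhelix(fx$protein)
  docks <- memo("plantedDocks", {
    ds <- gridDock(fx$protein, fx$peptide, proteinParams = pp)
    lapply(ds, function(d)
      findHashMatches(d, fx$protein, fx$peptide, list(fx$table)))
  })
  best <- filterDocksByMatches(docks, fx$protein@nUnits)[[1]]
  ref1 <- refineDock(best, fx$protein, fx$peptide)
  expect_lte(ref1@score, sum(best@matches$score) + 1e-9)
  # refining an already-refined pose changes little
  ref2 <- refineDock(ref1, fx$protein, fx$peptide)
  expect_lte(ref2@score, ref1@score + 1e-9)
  p1 <- transformChain(fx$peptide, ref1@transform)
  p2 <- transformChain(fx$peptide, ref2@transform)
  expect_lt(coordRMSD(backboneXYZ(p1), backboneXYZ(p2)), 0.05)
  expect_error(refineDock(new("Dock", rotDeg = 0, transA = 0,
                              transform = identityTransform(),
                              matches = superdock:::emptyMatches(),
                              clashes = 0L),
                          fx$protein, fx$peptide), ">= 1 match")
})

test_that("trimPeptide removes whole units symmetrically", {
  pep8 <- buildPPII(24)   # 8 units of 3
  t6 <- trimPeptide(pep8, 6)
  expect_equal(t6@nUnits, 6L)
  expect_equal(nResidues(t6), 18L)
  # one unit from each end: kept residues were 4..21
  expect_equal(t6@atoms$x[t6@atoms$atom == "CA"][1],
               pep8@atoms$x[pep8@atoms$atom == "CA"][4])
  # equal units: unchanged
  expect_equal(trimPeptide(pep8, 8)@atoms, pep8@atoms)
  # 5 -> 4: the N-terminal unit goes first on ties
  pep5 <- buildPPII(15)
  t4 <- trimPeptide(pep5, 4)
  expect_equal(t4@atoms$x[t4@atoms$atom == "CA"][1],
               pep5@atoms$x[pep5@atoms$atom == "CA"][4])
  expect_error(trimPeptide(buildPPII(9), 4), "fewer units")
})
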