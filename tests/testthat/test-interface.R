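# Interface metrics, selection thresholds, scans and forward docking.

test_that("interface membership follows the two distance ranges", {
  a <- buildPPII(6)
  bFar <- transformChain(buildPPII(6), rigidTransform(diag(3), c(50, 0, 0)))
  bFar@chainId <- "B"
  ir <- interfaceResidues(peptideComplex(a, bFar))
  expect_length(ir$proteinDesignable, 0)
  expect_length(ir$peptideMovable, 0)
  # constructed distances: single atoms at 8.5 and 10.5 A
  prot <- new("BackboneChain",
              atoms = data.frame(resno = c(1, 2), resname = "ALA",
                                 atom = "CA", x = c(8.5, 10.5), y = 0,
                                 z = 0),
              unitLength = 0L, nUnits = 0L, chainId = "A")
  pep <- singleAtomChain(0, 0, 0, "B")
  ir2 <- interfaceResidues(peptideComplex(prot, pep))
  expect_equal(ir2$proteinDesignable, 1L)
  expect_equal(sort(ir2$proteinMovable), c(1L, 2L))
  # designable is always a subset of movable
  b <- transformChain(buildPPII(6), rigidTransform(diag(3), c(0, 7, 0)))
  b@chainId <- "B"
  ir3 <- interfaceResidues(peptideComplex(a, b))
  expect_true(all(ir3$proteinDesignable %in% ir3$proteinMovable))
  expect_true(all(ir3$peptideDesignable %in% ir3$peptideMovable))
})

# helper: protein chain with the planted Gln side chains installed
installMatches <- function(fx) {
  prot <- fx$protein
  rows <- list()
  for (u in seq_len(prot@nUnits)) {
    at <- function(nm) resAtom(prot, u, nm)
    sc <- buildSideChain("GLN", at("N"), at("CA"), at("C"),
                         fx$rotamer$chis)
    for (nm in c("CG", "CD", "OE1", "NE2"))
      rows[[length(rows) + 1L]] <-
        data.frame(resno = u, resname = "GLN", atom = nm,
                   x = sc[[nm]][1], y = sc[[nm]][2], z = sc[[nm]][3])
  }
  prot@atoms <- rbind(prot@atoms, do.call(rbind, rows))
  prot
}

test_that("unsatisfied-H-bond counts: exposure, ladder removal, and
           monotonicity in the criteria", {
  # a peptide alone next to a distant partner: nothing buried
  a <- buildPPII(6)
  far <- transformChain(buildPPII(6), rigidTransform(diag(3), c(50, 0, 0)))
  far@chainId <- "B"
  un <- countUnsatHbonds(peptideComplex(a, far))
  expect_equal(un$unsatBB + un$unsatSC, 0L)
  # planted ladder: adding the Gln side chains satisfies peptide carbonyls
  fx <- planted()
  bare <- peptideComplex(fx$protein, fx$peptide)
  withSC <- peptideComplex(installMatches(fx), fx$peptide)
  u1 <- countUnsatHbonds(bare)
  u2 <- countUnsatHbonds(withSC)
  expect_lte(u2$unsatBB, u1$unsatBB)
  # loosening the distance window never increases the counts
  loose <- hbondCriteria(dMin = 2.2, dMax = 4.0)
  u3 <- countUnsatHbonds(bare, loose)
  expect_lte(u3$unsatBB, u1$unsatBB)
  expect_lte(u3$unsatSC, u1$unsatSC)
})

test_that("shape complementarity separates flat fits from point contacts", {
  # flat complementary slabs at a uniform 1.5 A surface gap
  lower <- slabChain(0, "A")
  upper <- slabChain(1.7 + 1.5 + 1.7, "B")
  scSlab <- shapeComplementarity(peptideComplex(lower, upper))
  expect_gte(scSlab, 0.9)
  # convex sphere against convex sphere: point contact, poor Sc
  s1 <- singleAtomChain(0, 0, 0, "A")
  s2 <- singleAtomChain(0, 0, 3.4, "B")
  scSph <- shapeComplementarity(peptideComplex(s1, s2))
  expect_lt(scSph, 0.5)
  # invariant under global rigid motion
  fx <- planted()
  cx <- peptideComplex(fx$protein, fx$peptide)
  sc0 <- shapeComplementarity(cx)
  xf <- rigidTransform(rotationAboutAxis(c(2, 1, 3), 57), c(5, -3, 11))
  cx2 <- peptideComplex(transformChain(fx$protein, xf),
                        transformChain(fx$peptide, xf))
  expect_equal(shapeComplementarity(cx2), sc0, tolerance = 1e-6)
  # empty interface is an error
  farB <- transformChain(fx$peptide, rigidTransform(diag(3), c(99, 0, 0)))
  expect_error(shapeComplementarity(peptideComplex(fx$protein, farB)),
               "empty interface")
})

test_that("selection is the stated conjunction, against an independent
           predicate", {
  mk <- function(ddg, sc, bb, sc2, pr)
    list(ddg = ddg, sc = sc, unsatBB = bb, unsatSC = sc2, pepRes = pr)
  expect_true(selectDesigns(mk(-40, 0.70, 1, 3, 0.5))$pass)
  r <- selectDesigns(mk(-30, 0.70, 1, 3, 0.5))
  expect_false(r$pass); expect_equal(r$reasons, "ddg")
  r <- selectDesigns(mk(-40, 0.60, 1, 3, 0.5))
  expect_false(r$pass); expect_equal(r$reasons, "sc")
  expect_false(selectDesigns(mk(-40, 0.70, 3, 3, 0.5))$pass)
  expect_false(selectDesigns(mk(-40, 0.70, 1, 5, 0.5))$pass)
  expect_false(selectDesigns(mk(-40, 0.70, 1, 3, 1.0))$pass)
  # boundary values pass (<=, >= semantics)
  expect_true(selectDesigns(mk(-35, 0.65, 2, 4, 0.9))$pass)
  # randomized vectors against an independently coded predicate
  set.seed(55)
  for (i in 1:300) {
    m <- mk(runif(1, -50, -20), runif(1, 0.4, 0.9), sample(0:4, 1),
            sample(0:6, 1), runif(1, 0, 1.5))
    indep <- (m$ddg <= -35) & (m$sc >= 0.65) & (m$unsatBB <= 2) &
      (m$unsatSC <= 4) & (m$pepRes <= 0.9)
    expect_identical(selectDesigns(m)$pass, indep)
  }
})

test_that("peptide mutation scan: exemptions, candidate set, acceptance", {
  pep <- buildPPII(12, resnames = rep(c("PRO", "LEU", "PRO"), 4))
  pep@unitLength <- 3L; pep@nUnits <- 4L
  prot <- transformChain(buildPPII(12), rigidTransform(diag(3), c(7, 0, 0)))
  cx <- peptideComplex(prot, pep)
  # toy score: a fixed bonus per mutated position containing TRP
  scoreFn <- function(complex, mutations) {
    if (is.null(mutations)) return(-10)
    -10 + ifelse(any(mutations$resname == "TRP"), 1.5, 0.5) *
      (length(unique(mutations$position)) > 0)
  }
  tab <- peptideMutationScan(cx, scoreFn)
  # prolines (positions 1 and 3 of the unit) are never scanned
  expect_true(all(tab$position == 2))
  # 19 candidates minus the wild type itself
  expect_equal(nrow(tab), 18)
  expect_false("CYS" %in% tab$to)
  expect_false("LEU" %in% tab$to)
  # delta +1.5 accepted, +0.5 rejected
  expect_true(all(tab$accepted[tab$to == "TRP"]))
  expect_true(all(!tab$accepted[tab$to != "TRP"]))
  # exempt positions are skipped
  tab2 <- peptideMutationScan(cx, scoreFn, exempt = 2L)
  expect_equal(nrow(tab2), 0)
  # symmetry: the mutation is applied to all equivalent positions
  seen <- new.env(); seen$pos <- NULL
  scoreFn2 <- function(complex, mutations) {
    if (!is.null(mutations)) seen$pos <- mutations$position
    -10
  }
  invisible(peptideMutationScan(cx, scoreFn2))
  expect_equal(sort(seen$pos), c(2L, 5L, 8L, 11L))
})

test_that("protein interface scan applies the two retention thresholds", {
  pos <- data.frame(position = 1:4,
                    original = c("SER", "LYS", "LEU", "ASN"),
                    designed = c("LEU", "TRP", "ILE", "GLN"))
  deltas <- c("1" = -6, "2" = -4, "3" = -2.5, "4" = -2.5)
  r <- proteinInterfaceScan(pos, deltas)
  # hydrophobic-from-hydrophilic: threshold -5
  expect_true(r$retained[1])    # -6 <= -5
  expect_false(r$retained[2])   # -4 > -5 -> reverted
  # hydropathic (originally hydrophobic, or hydrophilic designed): -2
  expect_true(r$retained[3])    # -2.5 <= -2
  expect_true(r$retained[4])
  r2 <- proteinInterfaceScan(pos, c("1" = -6, "2" = -4, "3" = -1,
                                    "4" = -1))
  expect_false(r2$retained[3])
})

test_that("symmetry maps link, break and enumerate positions", {
  m <- symmetryMap(3, 6)
  expect_length(m$classes, 3)
  expect_equal(equivalentPositions(m, 5), c(2, 5, 8, 11, 14, 17))
  b <- breakSymmetry(m, c(3, 4))
  # units 3-4 (positions 7..12) are now singletons
  expect_equal(equivalentPositions(b, 8), 8)
  expect_equal(equivalentPositions(b, 2), c(2, 5, 14, 17))
  # unlink none / all
  expect_identical(breakSymmetry(m, integer()), m)
  allB <- breakSymmetry(m, 1:6)
  for (p in 1:18) expect_equal(equivalentPositions(allB, p), p)
  expect_error(breakSymmetry(m, 7), "out of range")
})

test_that("forward docking calls convergence from the score landscape", {
  fx <- planted()
  cx <- peptideComplex(fx$protein, fx$peptide)
  designBB <- backboneXYZ(fx$peptide)
  # score = backbone distance to the designed pose: converges
  scoreRMSD <- function(protein, pep) coordRMSD(backboneXYZ(pep), designBB)
  rama <- smallRama()
  # conformer generator redraws torsions near the design's (same rama)
  r1 <- forwardDockAssess(cx, scoreRMSD, nConformers = 40, rngSeed = 5,
                          rama = rama, stepR = 30, minScoreable = 10L)
  expect_equal(r1$verdict, "not_converged")  # random PPII conformers spread
  # with the design itself among the conformers and a tight score the
  # verdict flips... instead verify determinism and the count gate
  r1b <- forwardDockAssess(cx, scoreRMSD, nConformers = 40, rngSeed = 5,
                           rama = rama, stepR = 30, minScoreable = 10L)
  expect_identical(r1[c("verdict", "topRMSD", "designRMSD")],
                   r1b[c("verdict", "topRMSD", "designRMSD")])
  # fewer scoreable docks than required: inconclusive
  r2 <- forwardDockAssess(cx, scoreRMSD, nConformers = 5, rngSeed = 5,
                          rama = rama, stepR = 30)
  expect_equal(r2$verdict, "inconclusive")
  # random scores: not converged with overwhelming probability
  set.seed(8)
  scoreRand <- function(protein, pep) runif(1)
  r3 <- forwardDockAssess(cx, scoreRand, nConformers = 40, rngSeed = 6,
                          rama = rama, stepR = 30, minScoreable = 10L)
  expect_false(r3$converged)
})

test_that("forward docking converges when the plant dominates the
           landscape", {
  # conformers drawn with the planted torsions exactly reproduce the
  # peptide; scored by distance-to-plant, the top docks cluster at the
  # plant within the grid resolution
  fx <- planted()
  cx <- peptideComplex(fx$protein, fx$peptide)
  designBB <- backboneXYZ(fx$peptide)
  scoreRMSD <- function(protein, pep) coordRMSD(backboneXYZ(pep), designBB)
  # narrow rama: a model whose basins collapse onto the planted torsions
  narrow <- ramaModel(nCalib = 400)
  for (cl in names(narrow$classes)) {
    narrow$classes[[cl]] <- list(list(mu = c(fx$placement$phi,
                                             fx$placement$psi),
                                      sd = c(0.3, 0.3), w = 1))
    narrow$threshold[cl] <- -1e9
  }
  r <- forwardDockAssess(cx, scoreRMSD, nConformers = 25, rngSeed = 9,
                         rama = narrow, stepT = 0.5, stepR = 5,
                         minScoreable = 20L)
  expect_equal(r$verdict, "converged")
  expect_lt(r$topRMSD, 2.0)
  expect_lt(r$designRMSD, 1.5)
})

test_that("the pairwise score proxy is calibrated near the selection
           threshold for a six-unit ladder", {
  fx <- planted()
  docks <- memo("plantedDocks", {
    pp <- chainSuperhelix(fx$protein)
    ds <- gridDock(fx$protein, fx$peptide, proteinParams = pp)
    lapply(ds, function(d)
      findHashMatches(d, fx$protein, fx$peptide, list(fx$table)))
  })
  best <- filterDocksByMatches(docks, 6)[[1]]
  cx <- peptideComplex(installMatches(fx), fx$peptide)
  s <- scoreComplex(cx, best@matches)
  expect_lt(s, -20)
  expect_gt(s, -70)
  # peptide strain proxy is small for a near-ideal-basin peptide
  expect_lt(peptideResidueScore(fx$peptide, smallRama()), 0.9)
})
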