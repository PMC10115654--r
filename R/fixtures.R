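# Planted-ladder fixtures: a repeat peptide with a known, hash-stored
# bidentate geometry realised at every repeat unit, and the single-residue-
# per-unit "protein" implied by the stored inverse rotamer. Used to
# exercise the full match -> dock -> hash -> refine pipeline against a
# known answer.

#' Construct a planted bidentate-ladder fixture
#'
#' Samples bidentate placements by Monte Carlo, selects the best-scoring
#' one, builds a repeat peptide whose every residue carries the sampled
#' backbone torsions, and places one side-chain-carrying protein residue
#' per repeat unit from a chosen inverse rotamer, so that the stored
#' interaction is realised exactly at every unit.
#'
#' @param nUnits peptide repeat units (default 6).
#' @param class interaction class (default AMIDE_BB_SAME).
#' @param resType protein residue type (default GLN).
#' @param rngSeed seed for the Monte Carlo sampling.
#' @param nSteps MC steps used to collect placements.
#' @param criteria an [hbondCriteria()].
#' @param placements optional precomputed [mcSampleBidentate()] output.
#' @return list with \code{peptide}, \code{protein} (both aligned so the
#'   planted pose is the identity dock), \code{placement} (the planted MC
#'   placement), \code{table} (a hash table containing the placement), and
#'   \code{targetResidues} (peptide residues carrying the interaction).
#' @export
plantedLadderFixture <- function(nUnits = 6, class = "AMIDE_BB_SAME",
                                 resType = "GLN", rngSeed = 42,
                                 nSteps = 400, criteria = hbondCriteria(),
                                 placements = NULL) {
  if (is.null(placements))
    placements <- mcSampleBidentate(class, criteria, nSteps, rngSeed)
  if (!length(placements))
    stop("no accepted placements; increase nSteps")
  scores <- vapply(placements, `[[`, numeric(1), "score")
  p <- placements[[which.min(scores)]]
  n <- 3L * nUnits
  tor <- data.frame(phi = rep(p$phi, n), psi = rep(p$psi, n), omega = 180)
  pep <- buildBackbone(tor, rep(c("PRO", "LEU", "PRO"), nUnits),
                       unitLength = 3L, nUnits = as.integer(nUnits),
                       chainId = "B")
  targetRes <- 3L * seq_len(nUnits) - 1L
  # one protein residue per unit from a fixed inverse rotamer
  rots <- inverseRotamers(p$relXform, resType, class = class)
  if (!length(rots)) stop("no clash-free inverse rotamer for the plant")
  rot <- rots[[1L]]
  rows <- list()
  for (u in seq_len(nUnits)) {
    fr <- residueFrame(pep, targetRes[u])
    place <- function(x) applyTransform(fr, x)
    N <- place(rot$atoms$N); CA <- place(rot$atoms$CA)
    C <- place(rot$atoms$C); CB <- place(rot$atoms$CB)
    O <- placeAtom(N, CA, C, 1.231, 120.8, -47 + 180)
    rows[[u]] <- data.frame(resno = u, resname = resType,
                            atom = c("N", "CA", "C", "O", "CB"),
                            x = c(N[1], CA[1], C[1], O[1], CB[1]),
                            y = c(N[2], CA[2], C[2], O[2], CB[2]),
                            z = c(N[3], CA[3], C[3], O[3], CB[3]))
  }
  prot <- new("BackboneChain", atoms = do.call(rbind, rows),
              unitLength = 1L, nUnits = as.integer(nUnits), chainId = "A")
  # align the complex on the protein's superhelical axis
  protParams <- chainSuperhelix(prot)
  protA <- alignAxisToZ(prot, protParams)
  xf <- attr(protA, "alignTransform")
  pepA <- transformChain(pep, xf)
  tab <- hashTableFromPlacements(list(p), class, seed = rngSeed,
                                 nSteps = nSteps)
  list(peptide = pepA, protein = protA, placement = p, table = tab,
       targetResidues = targetRes, rotamer = rot)
}
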