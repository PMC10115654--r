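# Parametric generator of helical-repeat (DHR-like) scaffolds that realise
# prescribed superhelical parameters. Repeat units are helix-loop-helix-loop
# with ideal alpha-helix torsions; the loop torsions are solved numerically
# so that the unit-to-unit screw transform hits the target rise/twist/radius.

#' Generate a helical-repeat scaffold realising target superhelix parameters
#'
#' Builds an idealised helix-loop-helix-loop repeat protein whose
#' unit-to-unit transform realises the target parameters within
#' (0.1 A rise, 1 degree twist, 0.5 A radius). Loop torsions are optimised
#' numerically from Ramachandran-plausible random starts; helix torsions are
#' ideal alpha values (-57, -47).
#'
#' @param helixLen helix length in residues (18 to 30).
#' @param loopLen loop length (3 or 4).
#' @param nUnits number of repeat units (>= 2).
#' @param target a [SuperhelixParams-class]; |twist| must be >= 1 degree.
#' @param rngSeed integer seed for the random restarts.
#' @param nStarts number of random restarts (default 20).
#' @param maxitPerStart optimiser iteration budget per start.
#' @return A [BackboneChain-class] with \code{unitLength} =
#'   2 * (helixLen + loopLen) and attribute \code{achieved} (the realised
#'   [SuperhelixParams-class]).
#' @export
generateDHRFixture <- function(helixLen = 20, loopLen = 3, nUnits = 4,
                               target, rngSeed = 1, nStarts = 20,
                               maxitPerStart = 400) {
  stopifnot(helixLen >= 18, helixLen <= 30, loopLen %in% c(3L, 4L),
            nUnits >= 2)
  if (abs(target@twist) < 1)
    stop("target twist below 1 degree: superhelical axis undefined")
  set.seed(rngSeed)
  unitLen <- 2L * (helixLen + loopLen)
  nLoopTor <- 2L * 2L * loopLen      # (phi, psi) x loopLen x 2 loops

  unitTorsions <- function(x) {
    lp <- matrix(x, ncol = 2)        # rows: loop residues, cols: phi, psi
    phi <- c(rep(-57, helixLen), lp[seq_len(loopLen), 1],
             rep(-57, helixLen), lp[loopLen + seq_len(loopLen), 1])
    psi <- c(rep(-47, helixLen), lp[seq_len(loopLen), 2],
             rep(-47, helixLen), lp[loopLen + seq_len(loopLen), 2])
    data.frame(phi = phi, psi = psi, omega = 180)
  }
  buildUnits <- function(x, n) {
    ut <- unitTorsions(x)
    tor <- ut[rep(seq_len(unitLen), n), ]
    buildBackbone(tor, "ALA", unitLength = unitLen, nUnits = as.integer(n))
  }
  measure <- function(x) {
    ut <- unitTorsions(x)
    xyz <- buildBackboneCoords(rep(ut$phi, 2), rep(ut$psi, 2))
    u1 <- xyz[seq_len(3L * unitLen), ]
    u2 <- xyz[3L * unitLen + seq_len(3L * unitLen), ]
    fit <- superpose(u1, u2)
    tryCatch(screwDecompose(fit$transform, colMeans(u1), angleTol = 0.5),
             error = function(e) NULL)
  }
  angDiff <- function(a, b) {
    d <- (a - b) %% 360
    min(d, 360 - d)
  }
  cost <- function(x) {
    p <- measure(x)
    if (is.null(p)) return(1e6)
    ((p@rise - target@rise) / 0.02)^2 +
      (angDiff(p@twist, target@twist) / 0.2)^2 +
      ((p@radius - target@radius) / 0.1)^2
  }
  tolOk <- function(p) {
    !is.null(p) && abs(p@rise - target@rise) <= 0.1 &&
      angDiff(p@twist, target@twist) <= 1 &&
      abs(p@radius - target@radius) <= 0.5
  }

  best <- NULL; bestCost <- Inf
  for (s in seq_len(nStarts)) {
    # loop torsions started in broadly allowed regions (PPII/beta/alpha mix)
    x0 <- cbind(stats::runif(2 * loopLen, -150, -50),
                stats::runif(2 * loopLen, -60, 170))
    x0 <- as.numeric(x0)
    fit <- stats::optim(x0, cost, method = "Nelder-Mead",
                        control = list(maxit = maxitPerStart,
                                       reltol = 1e-10))
    fit <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                        control = list(maxit = maxitPerStart,
                                       reltol = 1e-12))
    if (fit$value < bestCost) { bestCost <- fit$value; best <- fit$par }
    if (tolOk(measure(best))) break
  }
  achieved <- measure(best)
  if (!tolOk(achieved)) {
    stop(sprintf(paste0("generation failure: best achieved (rise %.3f, ",
                        "twist %.2f, radius %.2f) misses target (%.3f, ",
                        "%.2f, %.2f) beyond tolerance"),
                 achieved@rise, achieved@twist, achieved@radius,
                 target@rise, target@twist, target@radius))
  }
  ch <- buildUnits(best, nUnits)
  ch@chainId <- "A"
  attr(ch, "achieved") <- achieved
  attr(ch, "loopTorsions") <- best
  ch
}

#' Superhelix-parameter ranges used to curate repeat-protein scaffolds
#'
#' The geometric filter applied to candidate repeat-protein backbones:
#' twist between 0.6 and 1.0 radians, radius between 0 and 13 Angstrom and
#' rise between 0 and 10 Angstrom per repeat unit.
#'
#' @param params a [SuperhelixParams-class].
#' @param twistRange radians, default c(0.6, 1.0) on |twist|.
#' @param radiusRange Angstrom, default c(0, 13).
#' @param riseRange Angstrom, default c(0, 10).
#' @return logical: does the scaffold pass the geometric filter?
#' @export
dhrGeometryFilter <- function(params, twistRange = c(0.6, 1.0),
                              radiusRange = c(0, 13), riseRange = c(0, 10)) {
  tw <- abs(params@twist) * pi / 180
  tw >= twistRange[1] && tw <= twistRange[2] &&
    params@radius >= radiusRange[1] && params@radius <= radiusRange[2] &&
    params@rise >= riseRange[1] && params@rise <= riseRange[2]
}
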