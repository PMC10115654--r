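# Ramachandran density model: mixture of wrapped bivariate Gaussians over
# the favoured basins, per residue class. Used both to sample backbone
# torsions and as the acceptance filter during repeat-peptide sampling
# (pairs below a basin-density quantile are rejected and redrawn).

#' Ramachandran mixture model
#'
#' A mixture of wrapped bivariate Gaussians over the favoured basins
#' (alpha, beta, polyproline II, and left-handed alpha) per residue class:
#' \code{generic}, \code{proline}, \code{prepro} (pre-proline) and
#' \code{glycine}. The acceptance threshold is expressed as a log-density
#' quantile: a (phi, psi) pair is accepted when its log density is at or
#' above the \code{quantile}-quantile of density over draws from the model
#' itself (default 0.05, i.e. reject the lowest 5 percent of basin mass).
#'
#' @param quantile rejection quantile in (0, 1), default 0.05.
#' @param nCalib number of draws used to calibrate the threshold.
#' @param calibSeed RNG seed for threshold calibration.
#' @return object of class \code{RamaModel} with per-class components and
#'   thresholds.
#' @export
ramaModel <- function(quantile = 0.05, nCalib = 4000, calibSeed = 20260101) {
  basin <- function(phi, psi, sdPhi, sdPsi, w)
    list(mu = c(phi, psi), sd = c(sdPhi, sdPsi), w = w)
  classes <- list(
    generic = list(
      basin(-63, -43, 12, 12, 0.35),     # alpha
      basin(-120, 130, 20, 18, 0.30),    # beta
      basin(-75, 145, 14, 14, 0.30),     # PPII
      basin(60, 45, 12, 12, 0.05)        # alpha-L
    ),
    proline = list(
      basin(-62, -35, 10, 12, 0.35),     # alpha (restricted)
      basin(-65, 150, 10, 14, 0.65)      # PPII/beta merged; no phi>0 basin
    ),
    prepro = list(
      basin(-63, -43, 12, 12, 0.15),
      basin(-120, 130, 18, 16, 0.40),
      basin(-75, 145, 12, 12, 0.45)
    ),
    glycine = list(
      basin(-63, -43, 14, 14, 0.25),
      basin(-120, 130, 22, 20, 0.20),
      basin(-75, 145, 16, 16, 0.20),
      basin(63, 43, 14, 14, 0.25),
      basin(85, -5, 14, 14, 0.10)
    )
  )
  m <- list(classes = classes, quantile = quantile)
  class(m) <- "RamaModel"
  # calibrate per-class thresholds on draws from the model itself
  thr <- numeric(0)
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(calibSeed)
  for (cl in names(classes)) {
    ld <- vapply(seq_len(nCalib), function(i) {
      p <- ramaSampleRaw(m, cl)
      ramaLogDensity(m, p[1], p[2], cl)
    }, numeric(1))
    thr[cl] <- unname(stats::quantile(ld, quantile))
  }
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  m$threshold <- thr
  m
}

# wrapped normal density (sum over +-360 images; 1 image each side suffices
# at the basin widths used)
wrappedDnorm <- function(x, mu, sd) {
  stats::dnorm(x, mu, sd) + stats::dnorm(x, mu - 360, sd) +
    stats::dnorm(x, mu + 360, sd)
}

#' Ramachandran log density
#'
#' @param model a [ramaModel()].
#' @param phi,psi torsions in degrees (vectorised).
#' @param class one of "generic", "proline", "prepro", "glycine".
#' @return log density over the torus (degrees^-2 scale).
#' @export
ramaLogDensity <- function(model, phi, psi, class = "generic") {
  comps <- model$classes[[class]]
  if (is.null(comps)) stop("unknown residue class: ", class)
  dens <- 0
  for (b in comps)
    dens <- dens + b$w * wrappedDnorm(phi, b$mu[1], b$sd[1]) *
      wrappedDnorm(psi, b$mu[2], b$sd[2])
  log(dens)
}

# one raw draw (no threshold filter)
ramaSampleRaw <- function(model, class = "generic") {
  comps <- model$classes[[class]]
  w <- vapply(comps, `[[`, numeric(1), "w")
  b <- comps[[sample.int(length(comps), 1, prob = w)]]
  normTorsion(c(stats::rnorm(1, b$mu[1], b$sd[1]),
                stats::rnorm(1, b$mu[2], b$sd[2])))
}

#' Does a torsion pair pass the Ramachandran acceptance threshold?
#' @param model a [ramaModel()].
#' @param phi,psi torsions in degrees.
#' @param class residue class.
#' @return logical.
#' @export
ramaAccept <- function(model, phi, psi, class = "generic") {
  ramaLogDensity(model, phi, psi, class) >= model$threshold[[class]]
}

#' Sample one accepted (phi, psi) pair
#'
#' Draws from the basin mixture and redraws until the pair passes the
#' acceptance threshold.
#'
#' @param model a [ramaModel()].
#' @param class residue class.
#' @param maxTries rejection cap.
#' @return numeric length-2 c(phi, psi).
#' @export
ramaSamplePair <- function(model, class = "generic", maxTries = 10000) {
  for (i in seq_len(maxTries)) {
    p <- ramaSampleRaw(model, class)
    if (ramaAccept(model, p[1], p[2], class)) return(p)
  }
  stop("sampling failure: ", maxTries, " consecutive Ramachandran rejections")
}

.ramaCache <- new.env(parent = emptyenv())

#' Package default Ramachandran model (memoised)
#' @return the default [ramaModel()], built once per session.
#' @export
defaultRamaModel <- function() {
  if (is.null(.ramaCache$model)) .ramaCache$model <- ramaModel()
  .ramaCache$model
}

#' Residue classes for a sequence of 3-letter names
#'
#' Proline residues are class \code{proline}; residues immediately before a
#' proline are \code{prepro}; glycine is \code{glycine}; all others
#' \code{generic}.
#'
#' @param resnames character vector of 3-letter codes.
#' @return character vector of class labels.
#' @export
ramaClasses <- function(resnames) {
  n <- length(resnames)
  cls <- rep("generic", n)
  cls[resnames == "GLY"] <- "glycine"
  pre <- which(resnames == "PRO") - 1L
  pre <- pre[pre >= 1L]
  cls[pre] <- "prepro"
  cls[resnames == "PRO"] <- "proline"
  cls
}
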