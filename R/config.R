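# Declarative run configuration: every tunable default in one list,
# round-trippable through YAML, with unknown keys rejected.

#' Default run configuration
#'
#' All tunable defaults of the pipeline in one declarative list, with a
#' provenance block (package version, timestamp placeholder, seed).
#'
#' @param seed global seed recorded in the provenance block.
#' @return nested list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L) {
  structure(list(
    match = list(maxDeltaRise = 0.2, maxDeltaTwist = 5, minDeltaRadius = 4,
                 kMax = 3, signedTwist = FALSE),
    dock = list(stepT = 1.0, stepR = 10, pairCutoff = 10),
    hash = list(transBin = 1.0, transRange = 16, rotBin = 15, torBin = 10),
    hbond = list(dMin = 2.6, dMax = 3.4, dhaMin = 140, habMin = 90,
                 dIdeal = 2.9),
    interface = list(designableRange = 9, minimizeRange = 11,
                     burialCutoff = 5, dotDensity = 8),
    selection = list(ddg = -35.0, sc = 0.65, unsatBB = 2, unsatSC = 4,
                     pepRes = 0.9),
    scan = list(minUnits = 2),
    ssm = list(pseudocount = 0.5, minCount = 5),
    provenance = list(
      version = tryCatch(as.character(utils::packageVersion("superdock")),
                         error = function(e) "dev"),
      seed = as.integer(seed))
  ), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param seed seed for the provenance block of the base config.
#' @return a [runConfig()] list.
#' @export
readRunConfig <- function(path, seed = 1L) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("readRunConfig requires the yaml package")
  base <- runConfig(seed)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(base))
      stop("unknown config section: ", sec)
    for (k in names(user[[sec]])) {
      if (!k %in% names(base[[sec]]))
        stop("unknown config key: ", sec, ".", k)
      base[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  base
}
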