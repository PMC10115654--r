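#' @import methods
NULL

#' Rigid-body transform
#'
#' A proper rigid transform in 3-space: an orthonormal rotation matrix with
#' determinant +1 and a translation vector in Angstrom. Transforms act on
#' column points as \code{R x + t}.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation numeric length-3 vector (Angstrom).
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
      return("rotation must be a 3x3 numeric matrix")
    if (length(object@translation) != 3L)
      return("translation must have length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      return("rotation is not orthonormal (tolerance 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
      return("rotation determinant is not +1 (improper rotation)")
    TRUE
  })

#' Superhelical parameters of a repeating structure
#'
#' Every repeating polymeric structure traces a superhelix characterised by
#' the axial translation per repeat unit (rise), the rotation about the axis
#' per repeat unit (twist, signed, right-handed positive about
#' \code{axisDirection}), and the distance of the repeat-unit centroid from
#' the axis (radius). The axis is stored as a point and a unit direction;
#' the direction is chosen so that rise >= 0.
#'
#' @slot rise numeric, Angstrom per repeat unit.
#' @slot twist numeric, degrees per repeat unit in (-180, 180].
#' @slot radius numeric, Angstrom, >= 0.
#' @slot axisPoint numeric length-3, a point on the axis.
#' @slot axisDirection numeric length-3 unit vector.
#' @exportClass SuperhelixParams
setClass("SuperhelixParams",
  representation(rise = "numeric", twist = "numeric", radius = "numeric",
                 axisPoint = "numeric", axisDirection = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axisDirection^2)) - 1) > 1e-8)
      return("axisDirection must be a unit vector (tolerance 1e-8)")
    if (object@radius < 0) return("radius must be >= 0")
    if (object@twist <= -180 || object@twist > 180)
      return("twist must lie in (-180, 180]")
    TRUE
  })

#' Backbone chain container
#'
#' Residue-wise backbone atoms of one chain, with repeat-unit bookkeeping.
#' Atoms are held in a long-format data frame with columns \code{resno}
#' (1-based residue index), \code{resname} (3-letter code), \code{atom}
#' (N, CA, C, O, CB, or side-chain atom names for installed side chains),
#' and \code{x}, \code{y}, \code{z} (Angstrom).
#'
#' @slot atoms data.frame as described above.
#' @slot unitLength integer, residues per repeat unit (0 = non-repeating).
#' @slot nUnits integer, number of repeat units.
#' @slot chainId single character chain identifier.
#' @exportClass BackboneChain
setClass("BackboneChain",
  representation(atoms = "data.frame", unitLength = "integer",
                 nUnits = "integer", chainId = "character"),
  prototype(unitLength = 0L, nUnits = 0L, chainId = "A"),
  validity = function(object) {
    need <- c("resno", "resname", "atom", "x", "y", "z")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms must have columns", paste(need, collapse = ", ")))
    n <- length(unique(object@atoms$resno))
    if (object@unitLength > 0L && object@unitLength * object@nUnits > n)
      return("unitLength * nUnits exceeds chain length")
    TRUE
  })

#' Geometric hash table of privileged interactions
#'
#' Associative table from binned interaction-geometry keys (64-bit
#' representable integers held exactly in doubles) to lists of entries, each
#' entry recording the side-chain residue identity, its chi angles, the
#' interaction class and the geometric score at sample time. Provenance
#' metadata (class, binning config, seed, number of MC steps) travels with
#' the table and is checked at query time.
#'
#' @slot env environment mapping key strings to lists of entries.
#' @slot metadata list with elements class, config, seed, nSteps.
#' @exportClass InteractionHashTable
setClass("InteractionHashTable",
  representation(env = "environment", metadata = "list"))

#' A rigid placement of a peptide on a protein
#'
#' One candidate dock from the two-degree-of-freedom grid search: rotation
#' about and translation along the shared superhelical (z) axis, the
#' resulting rigid transform applied to the peptide, the hash-matched
#' bidentate interactions, and the clash count (0 for surviving docks).
#'
#' @slot rotDeg rotation about z in degrees.
#' @slot transA translation along z in Angstrom.
#' @slot transform the [RigidTransform-class] applied to the peptide.
#' @slot matches data.frame of matched interactions (one row each).
#' @slot clashes integer clash count.
#' @slot refined logical, whether [refineDock()] has been applied.
#' @slot score numeric, summed geometric score of the matches.
#' @exportClass Dock
setClass("Dock",
  representation(rotDeg = "numeric", transA = "numeric",
                 transform = "RigidTransform", matches = "data.frame",
                 clashes = "integer", refined = "logical", score = "numeric"),
  prototype(refined = FALSE, score = NA_real_))

#' Protein-peptide complex
#'
#' A two-chain complex: the repeat protein (chain A) and the docked peptide
#' (chain B), each a [BackboneChain-class].
#'
#' @slot protein the protein [BackboneChain-class].
#' @slot peptide the peptide [BackboneChain-class].
#' @exportClass PeptideComplex
setClass("PeptideComplex",
  representation(protein = "BackboneChain", peptide = "BackboneChain"))
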