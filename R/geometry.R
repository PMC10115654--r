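# Rigid-body algebra, Kabsch superposition, screw-axis decomposition.

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 (Angstrom). Default zero.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity transform
#' @return The identity [RigidTransform-class].
#' @export
identityTransform <- function() rigidTransform()

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first, then
#' \code{a}: (a o b)(x) = a(b(x)).
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param t a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% t@translation))
}

#' Apply a rigid transform to points
#'
#' @param t a [RigidTransform-class].
#' @param x numeric matrix n x 3 (or length-3 vector) of coordinates.
#' @return Transformed coordinates, same shape as input.
#' @export
applyTransform <- function(t, x) {
  if (is.null(dim(x))) {
    as.numeric(t@rotation %*% x) + t@translation
  } else {
    sweep(x %*% t(t@rotation), 2, t@translation, "+")
  }
}

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

rotationAngle <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric length-3, need not be unit length.
#' @param angleDeg rotation angle in degrees (right-handed about axis).
#' @return 3x3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimising the RMSD between
#' \code{applyTransform(t, moving)} and \code{fixed}.
#'
#' @param moving,fixed n x 3 coordinate matrices, equal n >= 3,
#'   not all collinear.
#' @return list with \code{transform} (a [RigidTransform-class]) and
#'   \code{rmsd} (post-fit RMSD, Angstrom).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("point sets must have equal cardinality")
  if (nrow(moving) < 3L)
    stop("degenerate geometry: fewer than 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  # collinearity check: rank of centred coordinates < 2
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-9 && svd(B, nu = 0, nv = 0)$d[2] < 1e-9)
    stop("degenerate geometry: collinear input")
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  moved <- sweep(A %*% t(R), 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(transform = rigidTransform(R, t), rmsd = rmsd)
}

#' Backbone RMSD between two coordinate sets without refitting
#' @param a,b n x 3 matrices in a common frame.
#' @return RMSD in Angstrom.
#' @export
coordRMSD <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Screw-axis decomposition of a rigid transform
#'
#' Decomposes a rigid transform into superhelical parameters: the rise
#' (translation component along the screw axis), the signed twist about the
#' axis (right-handed positive; axis direction flipped so rise >= 0), and
#' the radius of a reference point (typically the repeat-unit centroid)
#' from the axis.
#'
#' @param t a [RigidTransform-class]; its rotation angle must be at least
#'   \code{angleTol} for the axis to be defined.
#' @param referencePoint numeric length-3: point whose distance from the
#'   axis is reported as the radius.
#' @param angleTol minimum rotation angle in degrees (default 1).
#' @return A [SuperhelixParams-class].
#' @export
screwDecompose <- function(t, referencePoint = c(0, 0, 0), angleTol = 1) {
  R <- t@rotation; tr <- t@translation
  ang <- rotationAngle(R)
  if (ang < angleTol)
    stop("undefined axis: rotation angle below tolerance (pure translation has no finite superhelix)")
  # axis: eigenvector of R for eigenvalue 1 (robust near 180 deg)
  ev <- eigen(R)
  i1 <- which.min(abs(ev$values - 1))
  u <- Re(ev$vectors[, i1])
  u <- u / sqrt(sum(u^2))
  # signed angle about u
  a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  theta <- atan2(sum(a * u), (sum(diag(R)) - 1) / 2) * 180 / pi
  rise <- sum(tr * u)
  if (rise < 0) { u <- -u; theta <- -theta; rise <- -rise }
  # axis point: solve (I - R) p = t_perp restricted to plane normal to u
  tPerp <- tr - sum(tr * u) * u
  A <- rbind(diag(3) - R, u)
  p <- qr.solve(A, c(tPerp, 0))
  radius <- distToAxis(referencePoint, p, u)
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  new("SuperhelixParams", rise = rise, twist = theta, radius = radius,
      axisPoint = as.numeric(p), axisDirection = as.numeric(u))
}

distToAxis <- function(x, p, u) {
  v <- x - p
  sqrt(sum((v - sum(v * u) * u)^2))
}

#' Build the rigid transform realised by superhelical parameters
#'
#' Inverse of [screwDecompose()]: a rotation of \code{twist} degrees about
#' the axis combined with a translation of \code{rise} along it.
#'
#' @param params a [SuperhelixParams-class].
#' @return A [RigidTransform-class].
#' @export
buildTransform <- function(params) {
  u <- params@axisDirection; p <- params@axisPoint
  R <- rotationAboutAxis(u, params@twist)
  t <- p - as.numeric(R %*% p) + params@rise * u
  rigidTransform(R, t)
}

setMethod("show", "SuperhelixParams", function(object) {
  cat(sprintf("SuperhelixParams: rise %.3f A, twist %.2f deg, radius %.3f A\n",
              object@rise, object@twist, object@radius))
  cat(sprintf("  axis point (%.3f, %.3f, %.3f), direction (%.3f, %.3f, %.3f)\n",
              object@axisPoint[1], object@axisPoint[2], object@axisPoint[3],
              object@axisDirection[1], object@axisDirection[2],
              object@axisDirection[3]))
})

#' Superhelical parameters of a repeating backbone chain
#'
#' Superposes every repeat unit onto its successor, screw-decomposes the
#' averaged unit-to-unit transform, and reports the maximum deviation
#' across consecutive pairs as a regularity diagnostic.
#'
#' The per-pair transforms are averaged in the Lie-algebra sense by
#' chaining: the transform of unit 1 onto unit 2 is used as the canonical
#' transform, and the reported diagnostic is the maximum over pairs of the
#' displacement it would mispredict (Angstrom, plus degrees of rotation
#' mismatch folded in at 1 A/10 deg).
#'
#' @param chain a [BackboneChain-class] with at least 2 repeat units.
#' @param angleTol passed to [screwDecompose()].
#' @return A [SuperhelixParams-class] with attribute \code{regularity}
#'   (max deviation across pairs; 0 for exactly repeating chains).
#' @export
chainSuperhelix <- function(chain, angleTol = 1) {
  k <- chain@unitLength; n <- chain@nUnits
  if (k < 1L || n < 2L)
    stop("chain must have >= 2 repeat units")
  nres <- length(unique(chain@atoms$resno))
  if (k * n > nres)
    stop("non-integer repeat structure: unit_length x n_units exceeds chain length")
  units <- lapply(seq_len(n), function(i) unitBackboneCoords(chain, i))
  fits <- lapply(seq_len(n - 1L), function(i) superpose(units[[i]], units[[i + 1L]]))
  trans <- lapply(fits, `[[`, "transform")
  # average rotation via quaternion-free chordal mean, translation arithmetic
  Rbar <- Reduce(`+`, lapply(trans, slot, "rotation")) / (n - 1L)
  sv <- svd(Rbar)
  d <- sign(det(sv$u %*% t(sv$v)))
  Ravg <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tavg <- Reduce(`+`, lapply(trans, slot, "translation")) / (n - 1L)
  Tavg <- rigidTransform(Ravg, tavg)
  dev <- vapply(seq_along(trans), function(i) {
    pred <- applyTransform(Tavg, units[[i]])
    coordRMSD(pred, units[[i + 1L]])
  }, numeric(1))
  centroid <- colMeans(units[[1L]])
  params <- screwDecompose(Tavg, centroid, angleTol = angleTol)
  attr(params, "regularity") <- max(dev)
  params
}

# backbone N, CA, C, O coordinates of repeat unit i (unit centroid atom set)
unitBackboneCoords <- function(chain, i) {
  k <- chain@unitLength
  res <- sort(unique(chain@atoms$resno))
  sel <- res[((i - 1L) * k + 1L):(i * k)]
  at <- chain@atoms
  at <- at[at$resno %in% sel & at$atom %in% c("N", "CA", "C", "O"), ]
  at <- at[order(match(at$resno, sel), match(at$atom, c("N", "CA", "C", "O"))), ]
  as.matrix(at[, c("x", "y", "z")])
}

#' Rigidly move a backbone chain
#' @param chain a [BackboneChain-class].
#' @param t a [RigidTransform-class].
#' @return The transformed [BackboneChain-class].
#' @export
transformChain <- function(chain, t) {
  xyz <- as.matrix(chain@atoms[, c("x", "y", "z")])
  xyz <- applyTransform(t, xyz)
  chain@atoms$x <- xyz[, 1]; chain@atoms$y <- xyz[, 2]; chain@atoms$z <- xyz[, 3]
  chain
}

#' Align a chain's superhelical axis to the z axis
#'
#' Rigidly moves the chain so that its superhelical axis coincides with z
#' (axis point projected to the origin plane, direction +z). Internal
#' geometry is unchanged.
#'
#' @param chain a [BackboneChain-class].
#' @param params optional [SuperhelixParams-class] already derived from the
#'   chain; computed via [chainSuperhelix()] when missing.
#' @return The aligned [BackboneChain-class].
#' @export
alignAxisToZ <- function(chain, params = NULL) {
  if (is.null(params)) params <- chainSuperhelix(chain)
  u <- params@axisDirection; p <- params@axisPoint
  z <- c(0, 0, 1)
  v <- c(u[2] * z[3] - u[3] * z[2], u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(u * z)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotationAboutAxis(c(1, 0, 0), 180)
  } else {
    rotationAboutAxis(v, atan2(s, cth) * 180 / pi)
  }
  # after rotation, translate so the axis passes through the origin
  pr <- as.numeric(R %*% p)
  t <- c(-pr[1], -pr[2], 0)
  xf <- rigidTransform(R, t)
  out <- transformChain(chain, xf)
  attr(out, "alignTransform") <- xf
  out
}

#' Align a chain to z for docking, robust to near-zero twist
#'
#' Uses the superhelical screw axis when the per-unit twist is large
#' enough to condition it (at least \code{twistThreshold} degrees);
#' otherwise the chain is nearly straight and the axis is taken as the
#' least-squares line through its repeat-unit centroids, oriented from the
#' N- to the C-terminal unit.
#'
#' @param chain a repeat [BackboneChain-class].
#' @param twistThreshold degrees, default 5.
#' @return the aligned [BackboneChain-class].
#' @export
alignForDocking <- function(chain, twistThreshold = 5) {
  p <- tryCatch(chainSuperhelix(chain, angleTol = 0.1),
                error = function(e) NULL)
  if (!is.null(p) && abs(p@twist) >= twistThreshold)
    return(alignAxisToZ(chain, p))
  cen <- t(vapply(seq_len(chain@nUnits), function(i)
    colMeans(unitBackboneCoords(chain, i)), numeric(3)))
  mid <- colMeans(cen)
  X <- sweep(cen, 2, mid)
  u <- svd(X)$v[, 1]
  if (sum((cen[nrow(cen), ] - cen[1, ]) * u) < 0) u <- -u
  z <- c(0, 0, 1)
  v <- c(u[2] * z[3] - u[3] * z[2], u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(u * z)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotationAboutAxis(c(1, 0, 0), 180)
  } else rotationAboutAxis(v, atan2(s, cth) * 180 / pi)
  pr <- as.numeric(R %*% mid)
  out <- transformChain(chain, rigidTransform(R, c(-pr[1], -pr[2], 0)))
  attr(out, "alignTransform") <- rigidTransform(R, c(-pr[1], -pr[2], 0))
  out
}
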