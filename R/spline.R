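#' Fit a cubic spline through ordered vertebral centres
#'
#' Fits a piecewise-cubic curve per coordinate against the vertebra
#' ordinal p (1, 2, 3, ... cranial to caudal by default). With
#' `smoothing = NULL` (the default) the fit interpolates the centres
#' exactly; a numeric `smoothing` is passed to [stats::smooth.spline()] as
#' its `spar` argument, trading residual size against wiggliness when the
#' landmarks are noisy.
#'
#' @param centres ordered matrix of 3D points (n x 3, mm), n >= 4.
#' @param smoothing `NULL` for the interpolating fit, or a `spar` value.
#' @param knots optional numeric parameter values, strictly increasing;
#'   defaults to `1:n`.
#' @return a [SplineCurve-class].
#' @examples
#' p <- seq(-2, 2, by = 0.5)
#' curve <- fitSmoothingSpline(cbind(p, p^2, 0))
#' curvatureAt(curve, 5)  # apex of y = x^2: 2 mm^-1
#' @export
fitSmoothingSpline <- function(centres, smoothing = NULL, knots = NULL) {
  m <- .asPoints(centres, minPoints = 2L)
  if (nrow(m) < 4L) stop("insufficient points: a cubic fit needs at least 4")
  p <- if (is.null(knots)) seq_len(nrow(m)) else as.numeric(knots)
  if (length(p) != nrow(m)) stop("knots must match the number of points")
  if (anyDuplicated(p)) stop("invalid parameterization: duplicate ordinals")
  if (is.unsorted(p, strictly = TRUE))
    stop("invalid parameterization: ordinals must be strictly increasing")
  fits <- lapply(seq_len(3L), function(j) {
    if (is.null(smoothing)) {
      list(kind = "interp", fn = splinefun(p, m[, j], method = "fmm"))
    } else {
      list(kind = "smooth", obj = smooth.spline(p, m[, j], spar = smoothing))
    }
  })
  fitted <- vapply(fits, function(f) {
    if (f$kind == "interp") f$fn(p) else predict(f$obj, p)$y
  }, numeric(length(p)))
  new("SplineCurve", knots = p, fits = fits,
      smoothing = if (is.null(smoothing)) NA_real_ else smoothing,
      residuals = m - fitted)
}

#' Evaluate a fitted curve or its derivatives
#'
#' @param curve a [SplineCurve-class].
#' @param p numeric parameter values within the knot range.
#' @param deriv 0 (coordinates), 1 or 2 (derivatives w.r.t. p).
#' @return matrix `length(p)` x 3.
#' @export
evalCurve <- function(curve, p, deriv = 0L) {
  stopifnot(is(curve, "SplineCurve"), deriv %in% 0:3)
  rng <- range(curve@knots)
  if (any(p < rng[1] - 1e-9) || any(p > rng[2] + 1e-9))
    stop("parameter p outside the knot range of the curve")
  out <- vapply(curve@fits, function(f) {
    if (f$kind == "interp") f$fn(p, deriv = deriv)
    else predict(f$obj, p, deriv = deriv)$y
  }, numeric(length(p)))
  if (length(p) == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' Geometric curvature along a fitted vertebral line
#'
#' Geometric curvature (GC) is the reciprocal of the radius of the
#' osculating circle of the fitted curve, computed from the first and
#' second parametric derivatives; it is invariant under
#' re-parameterization, so its unit is mm^-1 regardless of the
#' dimensionless knot spacing. `method = "planar"` (the default for spine
#' work) evaluates the sagittal-plane specialization
#' |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2) on the x-y projection;
#' `method = "3d"` uses the full cross-product form |C' x C''| / |C'|^3,
#' appropriate for rib curves that leave the sagittal plane.
#'
#' @param curve a [SplineCurve-class].
#' @param p parameter values (vertebra ordinals) to evaluate at.
#' @param method `"planar"` or `"3d"`.
#' @return non-negative curvature values, mm^-1.
#' @seealso [signedCurvatureAt()] for the signed sagittal convention.
#' @export
curvatureAt <- function(curve, p, method = c("planar", "3d")) {
  method <- match.arg(method)
  d1 <- evalCurve(curve, p, 1L)
  d2 <- evalCurve(curve, p, 2L)
  if (method == "planar") {
    speed2 <- d1[, 1]^2 + d1[, 2]^2
    if (any(speed2 < 1e-24)) stop("degenerate tangent at requested parameter")
    abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / speed2^1.5
  } else {
    speed2 <- rowSums(d1^2)
    if (any(speed2 < 1e-24)) stop("degenerate tangent at requested parameter")
    cr <- .cross3(d1, d2)
    sqrt(rowSums(cr^2)) / speed2^1.5
  }
}

#' Signed sagittal curvature
#'
#' Planar curvature of the x-y (sagittal) projection keeping the sign of
#' x'y'' - y'x''. With +x anterior and +y cranial, and the curve traversed
#' cranial to caudal, positive values bend the spine posteriorly
#' (kyphotic) and negative values anteriorly (lordotic).
#'
#' @inheritParams curvatureAt
#' @return signed curvature values, mm^-1.
#' @export
signedCurvatureAt <- function(curve, p) {
  d1 <- evalCurve(curve, p, 1L)
  d2 <- evalCurve(curve, p, 2L)
  speed2 <- d1[, 1]^2 + d1[, 2]^2
  if (any(speed2 < 1e-24)) stop("degenerate tangent at requested parameter")
  (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / speed2^1.5
}

#' Residuals of a spline fit at its knots
#'
#' @param curve a [SplineCurve-class].
#' @return n x 3 matrix of (input - fitted) residuals in mm.
#' @export
splineResiduals <- function(curve) {
  stopifnot(is(curve, "SplineCurve"))
  curve@residuals
}
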