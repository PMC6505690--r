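## Polyline primitives. A 3D polyline is a plain numeric matrix with one
## point per row; two columns are promoted to three with z = 0.

.asPoints <- function(points, minPoints = 2L) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) == 2L) m <- cbind(m, 0)
  if (ncol(m) != 3L) stop("points must have 2 or 3 coordinate columns")
  if (!all(is.finite(m))) stop("non-finite coordinates in polyline")
  if (nrow(m) < minPoints) stop(sprintf("polyline needs at least %d points", minPoints))
  seg <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive polyline points must be distinct")
  m
}

#' Arc length of a polyline
#'
#' Sum of Euclidean segment lengths; the curved length L_C of a rib or any
#' landmark polyline.
#'
#' @param poly numeric matrix of ordered points (n x 3, or n x 2 taken as
#'   z = 0), mm.
#' @return length in mm; always >= [chordLength()].
#' @examples
#' arcLength(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))  # 2
#' @export
arcLength <- function(poly) {
  m <- .asPoints(poly)
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

#' Chord length of a polyline
#'
#' Euclidean distance between the first and last points; the endpoint
#' distance L_S used by the inflection count metric.
#'
#' @inheritParams arcLength
#' @return length in mm (0 for a closed loop).
#' @export
chordLength <- function(poly) {
  m <- .asPoints(poly)
  sqrt(sum((m[nrow(m), ] - m[1L, ])^2))
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Linear interpolation along the cumulative arc length; endpoints are
#' preserved exactly. Used to put rib centerlines on a common resolution
#' before discrete Frenet analysis.
#'
#' @inheritParams arcLength
#' @param n number of output points (>= 2).
#' @return an n x 3 matrix.
#' @export
resampleUniform <- function(poly, n) {
  m <- .asPoints(poly)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("invalid count: n must be >= 2")
  n <- as.integer(n)
  seg <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  out <- vapply(seq_len(3L), function(j) approx(s, m[, j], xout = target)$y,
                numeric(n))
  out[1L, ] <- m[1L, ]
  out[n, ] <- m[nrow(m), ]
  out
}

#' Project 3D points onto a named anatomical plane
#'
#' Orthogonal projection in the package frame (+x anterior, +y cranial,
#' +z left): the sagittal plane drops z, the frontal plane drops x and the
#' axial plane drops y.
#'
#' @param points n x 3 matrix (mm).
#' @param plane one of `"sagittal"`, `"frontal"`, `"axial"`.
#' @return an n x 2 matrix of in-plane coordinates.
#' @export
projectToPlane <- function(points, plane = c("sagittal", "frontal", "axial")) {
  plane <- match.arg(plane)
  m <- as.matrix(points)
  if (ncol(m) != 3L) stop("points must be n x 3")
  keep <- switch(plane, sagittal = c(1L, 2L), frontal = c(2L, 3L),
                 axial = c(1L, 3L))
  m[, keep, drop = FALSE]
}

## unit rows of a matrix (rows with ~zero norm flagged NA)
.unitRows <- function(m, tol = 1e-300) {
  n <- sqrt(rowSums(m^2))
  out <- m / n
  out[n < tol, ] <- NA_real_
  out
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
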