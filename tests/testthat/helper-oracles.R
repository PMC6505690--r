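# Analytic fixtures and independent oracles used across the suite.

# points on a circular arc of radius R in the x-y plane
circleArc <- function(R, centre = c(0, 0), theta0 = 0, span = 1.5 * pi,
                      n = 100) {
  th <- theta0 + seq(0, span, length.out = n)
  cbind(centre[1] + R * cos(th), centre[2] + R * sin(th), 0)
}

# one full sine arch y = sin(x) over [0, x1], densely sampled
sineCurve <- function(x1 = 4 * pi, n = 500) {
  x <- seq(0, x1, length.out = n)
  cbind(x, sin(x), 0)
}

# circular helix: constant curvature, smoothly rotating normal
helixCurve <- function(a = 1, b = 0.3, t1 = 4 * pi, n = 400) {
  t <- seq(0, t1, length.out = n)
  cbind(a * cos(t), a * sin(t), b * t)
}

# quadrature oracle for the arc length of y = sin(x) over [0, x1]
sineArcLengthOracle <- function(x1 = 4 * pi) {
  stats::integrate(function(t) sqrt(1 + cos(t)^2), 0, x1,
                   rel.tol = 1e-10)$value
}

# 28 standard labels (C1..C14, T1..T7, L1..L7)
allLabels <- function() {
  c(paste0("C", 1:14), paste0("T", 1:7), paste0("L", 1:7))
}

# build a Spine from bare centres (28 x 3), with parallel horizontal
# endplates bracketing each centre -- enough structure for curvature,
# height and alignment tests
spineFromCentres <- function(centres, id = "synthetic", stage = 9,
                             group = "control") {
  labs <- allLabels()
  stopifnot(nrow(centres) == length(labs))
  v <- data.frame(label = labs,
                  region = rep(c("C", "T", "L"), c(14, 7, 7)),
                  ord = seq_along(labs),
                  cx = centres[, 1], cy = centres[, 2], cz = centres[, 3],
                  stringsAsFactors = FALSE)
  v$sx1 <- v$cx - 0.1; v$sy1 <- v$cy + 0.15; v$sz1 <- v$cz
  v$sx2 <- v$cx + 0.1; v$sy2 <- v$cy + 0.15; v$sz2 <- v$cz
  v$ix1 <- v$cx - 0.1; v$iy1 <- v$cy - 0.15; v$iz1 <- v$cz
  v$ix2 <- v$cx + 0.1; v$iy2 <- v$cy - 0.15; v$iz2 <- v$cz
  v$fusedWithNext <- FALSE
  Spine(id, stage, group, v)
}

# dense finite-difference curvature of the generating sagittal template
# of a noise-free control configuration, evaluated at ordinal u
generatingCurvatureOracle <- function(config, u, h = 1e-4) {
  n <- sum(config@vertebraCounts)
  A0 <- config@baselineAmp
  delta <- config@targetHeightMm / 20
  xf <- function(t) A0 * sin(2 * pi * (t - 1) / (n - 1))
  yf <- function(t) -(t - 1) * delta
  chord <- sqrt((xf(n) - xf(8))^2 + (yf(n) - yf(8))^2)
  fac <- config@targetHeightMm / chord
  vapply(u, function(t) {
    x1 <- (xf(t + h) - xf(t - h)) / (2 * h)
    x2 <- (xf(t + h) - 2 * xf(t) + xf(t - h)) / h^2
    y1 <- (yf(t + h) - yf(t - h)) / (2 * h)
    abs(x1 * 0 - y1 * x2) / (x1^2 + y1^2)^1.5 / fac
  }, numeric(1))
}

fifthLeftRib <- function(specimen) {
  Filter(function(r) r@side == "left" && r@index == 5L, ribs(specimen))[[1L]]
}
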