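## angle in degrees between two 2D directions, ignoring orientation
.dirAngleDeg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  acos(pmin(1, abs(sum(u * v)) / (nu * nv))) * 180 / pi
}

#' Endplate wedge angle of a vertebra
#'
#' Angle between the lines drawn along the superior and inferior endplate
#' surfaces, measured from their direction vectors after projection into
#' the measurement plane (absolute cosine, so the result lies in
#' [0, 90] degrees and is well defined for parallel endplates). The two
#' endplates are passed as 2 x 3 matrices of their endpoint coordinates.
#'
#' @param superior,inferior 2 x 3 matrices (mm), one endplate endpoint
#'   per row.
#' @param basis optional 3 x 2 matrix whose columns span the local
#'   measurement plane; by default the sagittal plane (drop z) is used.
#' @return angle in degrees, in [0, 90].
#' @examples
#' sup <- rbind(c(-1, 0.5, 0), c(1, 0.5, 0))
#' inf <- rbind(c(-1, -0.5, 0), c(1, -0.5, 0))
#' wedgeAngle(sup, inf)  # parallel endplates: 0
#' @export
wedgeAngle <- function(superior, inferior, basis = NULL) {
  sup <- as.matrix(superior); inf <- as.matrix(inferior)
  if (ncol(sup) == 2L) sup <- cbind(sup, 0)
  if (ncol(inf) == 2L) inf <- cbind(inf, 0)
  if (nrow(sup) != 2L || nrow(inf) != 2L)
    stop("each endplate needs exactly two endpoint rows")
  ds <- sup[2L, ] - sup[1L, ]
  di <- inf[2L, ] - inf[1L, ]
  if (sqrt(sum(ds^2)) < 1e-9 || sqrt(sum(di^2)) < 1e-9)
    stop("degenerate endplate: coincident endpoints")
  if (is.null(basis)) {
    u2 <- ds[1:2]; v2 <- di[1:2]
  } else {
    u2 <- as.numeric(crossprod(basis, ds))
    v2 <- as.numeric(crossprod(basis, di))
  }
  ang <- .dirAngleDeg(u2, v2)
  if (is.na(ang)) stop("degenerate endplate: no in-plane component")
  ang
}

## local sagittal basis at vertebra i: plane spanned by the local spine
## tangent and the anterior axis, mimicking the manual rotation of cropped
## spinal segments into their own sagittal plane.
.localBasis <- function(centres, i) {
  n <- nrow(centres)
  a <- centres[max(1L, i - 1L), ]
  b <- centres[min(n, i + 1L), ]
  t <- b - a
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12) return(NULL)
  t <- t / nt
  ant <- c(1, 0, 0)
  e1 <- ant - sum(ant * t) * t
  ne1 <- sqrt(sum(e1^2))
  if (ne1 < 1e-9) return(NULL)
  cbind(e1 / ne1, t)
}

#' Classify wedged and fused vertebrae
#'
#' Measures every vertebra's endplate wedge angle (in its local sagittal
#' plane by default) and calls a vertebra wedged when the angle is
#' strictly greater than `threshold` (default 10 degrees, reflecting
#' normal variability in vertebral shape). A vertebra is called fused
#' when its `fusedWithNext` annotation is set or when the axial gap
#' between its inferior endplate midpoint and the next vertebra's
#' superior endplate midpoint is <= 0 (overlapping endplates); both
#' members of a fused pair are counted as fused. Vertebrae whose
#' endplates are degenerate are reported as unmeasured.
#'
#' @param x a [Spine-class] or [Specimen-class].
#' @param threshold wedge threshold in degrees; strict inequality, so an
#'   angle of exactly `threshold` is not wedged.
#' @param frame `"local"` projects endplates into each vertebra's local
#'   sagittal plane (tangent + anterior axis); `"sagittal"` uses the
#'   global x-y plane.
#' @param ... passed through between methods.
#' @return a [WedgeReport-class].
#' @export
setMethod("classifyVertebrae", "Spine", function(x, threshold = 10,
                                                 frame = c("local", "sagittal"),
                                                 ...) {
  frame <- match.arg(frame)
  v <- x@vertebrae
  n <- nrow(v)
  centres <- as.matrix(v[, c("cx", "cy", "cz")])
  angle <- rep(NA_real_, n)
  measured <- rep(TRUE, n)
  for (i in seq_len(n)) {
    sup <- rbind(c(v$sx1[i], v$sy1[i], v$sz1[i]), c(v$sx2[i], v$sy2[i], v$sz2[i]))
    inf <- rbind(c(v$ix1[i], v$iy1[i], v$iz1[i]), c(v$ix2[i], v$iy2[i], v$iz2[i]))
    basis <- if (frame == "local") .localBasis(centres, i) else NULL
    ang <- tryCatch(wedgeAngle(sup, inf, basis = basis), error = function(e) NA_real_)
    if (is.na(ang)) measured[i] <- FALSE
    angle[i] <- ang
  }
  fused <- rep(FALSE, n)
  supMid <- cbind((v$sx1 + v$sx2) / 2, (v$sy1 + v$sy2) / 2, (v$sz1 + v$sz2) / 2)
  infMid <- cbind((v$ix1 + v$ix2) / 2, (v$iy1 + v$iy2) / 2, (v$iz1 + v$iz2) / 2)
  for (i in seq_len(n - 1L)) {
    annot <- isTRUE(v$fusedWithNext[i])
    axis <- centres[i + 1L, ] - centres[i, ]
    na <- sqrt(sum(axis^2))
    geom <- FALSE
    if (na > 1e-12) {
      gap <- sum((supMid[i + 1L, ] - infMid[i, ]) * axis) / na
      geom <- gap <= 0
    }
    if (annot || geom) fused[i] <- fused[i + 1L] <- TRUE
  }
  ## strict inequality with a small numerical guard: an angle planted at
  ## exactly the threshold must not flip wedged through rounding alone
  records <- data.frame(label = v$label, angle_deg = angle,
                        wedged = measured & !is.na(angle) &
                          angle - threshold > 1e-9,
                        fused = fused, measured = measured,
                        stringsAsFactors = FALSE)
  new("WedgeReport", specimenID = x@specimenID, stage = x@stage,
      group = x@group, records = records, threshold = threshold)
})

#' @rdname classifyVertebrae
setMethod("classifyVertebrae", "Specimen", function(x, ...)
  classifyVertebrae(x@spine, ...))

#' Cohort summary of abnormal-vertebra counts
#'
#' Mean and sample SD (n - 1 denominator) of the per-specimen numbers of
#' wedged, fused and abnormal (wedged or fused) vertebrae, grouped by
#' (group, stage). SDs are `NA` for singleton groups.
#'
#' @param reports list of [WedgeReport-class] objects.
#' @return data.frame with one row per (group, stage).
#' @export
cohortAbnormalSummary <- function(reports) {
  if (is(reports, "WedgeReport")) reports <- list(reports)
  if (!length(reports)) stop("empty cohort")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(group = r@group, stage = r@stage, n_wedged = nWedged(r),
               n_fused = nFused(r), n_abnormal = nAbnormal(r),
               stringsAsFactors = FALSE)))
  keys <- unique(tab[, c("group", "stage")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- tab[tab$group == keys$group[k] & tab$stage == keys$stage[k], ]
    data.frame(group = keys$group[k], stage = keys$stage[k], n = nrow(sub),
               mean_wedged = mean(sub$n_wedged),
               sd_wedged = if (nrow(sub) > 1) sd(sub$n_wedged) else NA_real_,
               mean_fused = mean(sub$n_fused),
               sd_fused = if (nrow(sub) > 1) sd(sub$n_fused) else NA_real_,
               mean_abnormal = mean(sub$n_abnormal),
               sd_abnormal = if (nrow(sub) > 1) sd(sub$n_abnormal) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
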