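.windowLabels <- function(regionMap, from = "C8", to = "L7") {
  labs <- unlist(lapply(names(regionMap), function(r)
    paste0(r, seq_len(regionMap[[r]]))), use.names = FALSE)
  labs[seq(match(from, labs), match(to, labs))]
}

#' Per-vertebra geometric curvature profile
#'
#' Fits a cubic spline through all available vertebral-body centres
#' (parameterized by vertebra ordinal) and evaluates sagittal geometric
#' curvature at each vertebra of the analysis window, C8 to L7. Both the
#' absolute GC (as plotted in group comparisons) and the signed sagittal
#' curvature (positive kyphotic, negative lordotic) are reported.
#' Vertebrae missing from the landmark table inside the window are
#' reported as `NA`.
#'
#' @param x a [Spine-class] or [Specimen-class].
#' @param smoothing spline smoothing setting, see [fitSmoothingSpline()].
#' @param window character of length 2, first and last label of the
#'   analysis window.
#' @param ... passed through between methods.
#' @return a [CurvatureProfile-class].
#' @export
setMethod("computeGCProfile", "Spine", function(x, smoothing = NULL,
                                                window = c("C8", "L7"), ...) {
  v <- x@vertebrae
  if (nrow(v) < 4L) stop("insufficient points: need at least 4 vertebrae")
  curve <- fitSmoothingSpline(as.matrix(v[, c("cx", "cy", "cz")]),
                              smoothing = smoothing, knots = v$ord)
  labs <- .windowLabels(x@regionMap, window[1], window[2])
  idx <- match(labs, v$label)
  present <- !is.na(idx)
  if (!all(present))
    warning(sprintf("vertebrae missing inside the analysis window: %s",
                    paste(labs[!present], collapse = ", ")))
  pAll <- v$ord[idx[present]]
  gcs <- signedCurvatureAt(curve, pAll)
  prof <- data.frame(label = labs, p = NA_real_, gc = NA_real_,
                     gc_signed = NA_real_, stringsAsFactors = FALSE)
  prof$p[present] <- pAll
  prof$gc[present] <- abs(gcs)
  prof$gc_signed[present] <- gcs
  new("CurvatureProfile", specimenID = x@specimenID, stage = x@stage,
      group = x@group, profile = prof, curve = curve)
})

#' @rdname computeGCProfile
setMethod("computeGCProfile", "Specimen", function(x, ...)
  computeGCProfile(x@spine, ...))

#' Spine height
#'
#' Straight-line distance between the centres of C8 and L7 after
#' projection onto the sagittal plane.
#'
#' @param x a [Spine-class] or [Specimen-class].
#' @param ... ignored.
#' @return height in mm.
#' @export
setMethod("spineHeight", "Spine", function(x, ...) {
  v <- x@vertebrae
  i8 <- match("C8", v$label)
  i28 <- match("L7", v$label)
  if (is.na(i8) || is.na(i28)) stop("window endpoints absent: need C8 and L7")
  a <- c(v$cx[i8], v$cy[i8])
  b <- c(v$cx[i28], v$cy[i28])
  sqrt(sum((a - b)^2))
})

#' @rdname spineHeight
setMethod("spineHeight", "Specimen", function(x, ...) spineHeight(x@spine))

#' Align sagittal outline traces at T1
#'
#' Translates each spine's centre trace so that the centre of thoracic
#' vertebra 1 sits at the origin; no rotation or scaling is applied, so
#' the overlay preserves each specimen's own curvature. Spines lacking T1
#' are dropped with a warning.
#'
#' @param spines list of [Spine-class] or [Specimen-class] objects.
#' @return named list of n x 3 matrices of aligned centres.
#' @export
alignOutlines <- function(spines) {
  if (is(spines, "Spine") || is(spines, "Specimen")) spines <- list(spines)
  out <- list()
  for (sp in spines) {
    if (is(sp, "Specimen")) sp <- sp@spine
    v <- sp@vertebrae
    it <- match("T1", v$label)
    if (is.na(it)) {
      warning(sprintf("specimen '%s' has no T1; excluded from alignment",
                      sp@specimenID))
      next
    }
    ctr <- as.matrix(v[, c("cx", "cy", "cz")])
    ctr <- sweep(ctr, 2L, ctr[it, ])
    rownames(ctr) <- v$label
    out[[sp@specimenID]] <- ctr
  }
  out
}

#' Stack curvature profiles into one long table
#'
#' @param profiles list of [CurvatureProfile-class] objects.
#' @return data.frame with columns `specimen_id`, `group`, `stage`,
#'   `label`, `p`, `gc`, `gc_signed` -- the input expected by
#'   [perLocationComparison()].
#' @export
profilesTable <- function(profiles) {
  if (is(profiles, "CurvatureProfile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, as.data.frame))
}
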