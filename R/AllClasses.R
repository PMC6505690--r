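#' Fitted vertebral-line spline
#'
#' A piecewise-cubic curve fitted through an ordered sequence of 3D
#' vertebral-body centres, parameterized by vertebra ordinal `p`. The
#' object carries one univariate fit per coordinate and supports
#' evaluation of the curve and of its first and second derivatives with
#' respect to `p`, which is all that geometric curvature needs.
#'
#' @slot knots numeric, the ordinal parameter value of each input point.
#' @slot fits list of three per-coordinate fits (either interpolating
#'   spline functions or `smooth.spline` objects).
#' @slot smoothing numeric; `NA_real_` for the interpolating fit,
#'   otherwise the `spar` smoothing setting used.
#' @slot residuals numeric matrix of fit residuals at the knots (mm).
#' @seealso [fitSmoothingSpline()], [evalCurve()], [curvatureAt()]
#' @export
setClass("SplineCurve",
  representation(
    knots = "numeric",
    fits = "list",
    smoothing = "numeric",
    residuals = "matrix"
  )
)

setValidity("SplineCurve", function(object) {
  if (length(object@fits) != 3L) return("need one fit per coordinate (x, y, z)")
  if (length(object@knots) < 4L) return("a cubic fit needs at least 4 knots")
  if (is.unsorted(object@knots, strictly = TRUE))
    return("knots must be strictly increasing")
  TRUE
})

#' Spine landmark object
#'
#' One specimen's vertebral column: an ordered (cranial to caudal) table of
#' vertebral-body landmarks plus stage and treatment metadata. Each
#' vertebra carries its centre and the two endpoints of its superior and
#' inferior endplate lines, all in mm, in a right-handed frame with
#' +x anterior, +y cranial, +z left.
#'
#' The default regional plan is the chick axial formula used throughout:
#' 14 cervical, 7 thoracic and 7 lumbar vertebrae (labels C1..C14, T1..T7,
#' L1..L7). Curvature and height analyses use the window C8-L7.
#'
#' @slot specimenID character identifier.
#' @slot stage integer embryonic day (5-9).
#' @slot group character treatment group (`"control"`, `"Im3"`..`"Im6"`).
#' @slot vertebrae data.frame with columns `label`, `region`, `ord`,
#'   centre `cx,cy,cz`, superior endplate endpoints `sx1..sz2`, inferior
#'   endplate endpoints `ix1..iz2`, and logical `fusedWithNext`.
#' @slot regionMap named integer vector of vertebra counts per region.
#' @export
setClass("Spine",
  representation(
    specimenID = "character",
    stage = "integer",
    group = "character",
    vertebrae = "data.frame",
    regionMap = "integer"
  ),
  prototype(regionMap = c(C = 14L, T = 7L, L = 7L))
)

.spineCols <- c(
  "label", "region", "ord", "cx", "cy", "cz",
  "sx1", "sy1", "sz1", "sx2", "sy2", "sz2",
  "ix1", "iy1", "iz1", "ix2", "iy2", "iz2", "fusedWithNext"
)

setValidity("Spine", function(object) {
  v <- object@vertebrae
  miss <- setdiff(.spineCols, names(v))
  if (length(miss)) return(paste("missing vertebra columns:", paste(miss, collapse = ", ")))
  if (nrow(v) < 1L) return("spine has no vertebrae")
  if (anyDuplicated(v$label)) return("duplicate vertebra labels")
  if (is.unsorted(v$ord, strictly = TRUE)) return("vertebra ordinals must increase cranial to caudal")
  num <- as.matrix(v[, c("cx", "cy", "cz", "sx1", "sy1", "sz1", "sx2", "sy2", "sz2",
                         "ix1", "iy1", "iz1", "ix2", "iy2", "iz2")])
  if (!all(is.finite(num))) return("non-finite landmark coordinates")
  supLen <- sqrt((v$sx1 - v$sx2)^2 + (v$sy1 - v$sy2)^2 + (v$sz1 - v$sz2)^2)
  infLen <- sqrt((v$ix1 - v$ix2)^2 + (v$iy1 - v$iy2)^2 + (v$iz1 - v$iz2)^2)
  if (any(supLen <= 0) || any(infLen <= 0)) return("coincident endplate endpoints")
  TRUE
})

#' Rib centerline object
#'
#' One vertebral (dorsal) rib: side, thoracic index, presence flag and, if
#' present, its centerline polyline (an n x 3 matrix in mm). Absent ribs
#' carry an empty centerline. `fusedWith` optionally names another rib
#' (e.g. `"left4"`) annotated as fused to this one.
#'
#' @slot side `"left"` or `"right"`.
#' @slot index integer 1-7, the thoracic vertebra of attachment.
#' @slot present logical.
#' @slot centerline numeric matrix (n x 3, mm); 0 rows when absent.
#' @slot fusedWith character, `NA` when not annotated.
#' @export
setClass("Rib",
  representation(
    side = "character",
    index = "integer",
    present = "logical",
    centerline = "matrix",
    fusedWith = "character"
  ),
  prototype(fusedWith = NA_character_)
)

setValidity("Rib", function(object) {
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  if (object@index < 1L || object@index > 7L) return("rib index must be in 1..7")
  if (object@present) {
    if (nrow(object@centerline) < 2L) return("present rib needs a centerline with >= 2 points")
    if (ncol(object@centerline) != 3L) return("centerline must be n x 3")
  }
  TRUE
})

#' Specimen: spine plus ribs
#'
#' The unit of all measurement: one embryo's [Spine] together with its
#' list of [Rib] objects.
#'
#' @slot spine a `Spine`.
#' @slot ribs list of `Rib` objects.
#' @export
setClass("Specimen",
  representation(spine = "Spine", ribs = "list")
)

setValidity("Specimen", function(object) {
  if (!all(vapply(object@ribs, is, logical(1), class2 = "Rib")))
    return("all ribs must be Rib objects")
  TRUE
})

#' Per-vertebra wedge and fusion report
#'
#' Result of [classifyVertebrae()]: one record per vertebra with its
#' endplate wedge angle and wedged/fused calls, plus specimen metadata.
#' Counts are available via [nWedged()], [nFused()] and [nAbnormal()]
#' (abnormal = wedged or fused).
#'
#' @slot specimenID,group character; @slot stage integer.
#' @slot records data.frame: `label`, `angle_deg`, `wedged`, `fused`,
#'   `measured` (FALSE when an endplate was degenerate).
#' @slot threshold numeric wedge threshold in degrees.
#' @export
setClass("WedgeReport",
  representation(
    specimenID = "character",
    stage = "integer",
    group = "character",
    records = "data.frame",
    threshold = "numeric"
  )
)

#' Per-vertebra geometric curvature profile
#'
#' Result of [computeGCProfile()]: absolute and signed sagittal geometric
#' curvature (mm^-1) at each vertebra of the analysis window, plus the
#' fitted [SplineCurve].
#'
#' @slot specimenID,group character; @slot stage integer.
#' @slot profile data.frame: `label`, `p`, `gc`, `gc_signed`.
#' @slot curve the `SplineCurve` the profile was evaluated on.
#' @export
setClass("CurvatureProfile",
  representation(
    specimenID = "character",
    stage = "integer",
    group = "character",
    profile = "data.frame",
    curve = "SplineCurve"
  )
)

#' Synthetic-specimen generator configuration
#'
#' Stage- and group-specific parameters driving synthetic specimen
#' creation; see [defaultConfig()] for the calibrated defaults.
#'
#' @slot stage integer embryonic day; @slot group character group label.
#' @slot targetHeightMm numeric C8-L7 chord target (mm); `heightSd` its
#'   between-specimen SD.
#' @slot vertebraCounts named integer, vertebrae per region.
#' @slot baselineAmp numeric amplitude (mm) of the gentle sagittal
#'   baseline template.
#' @slot deformities data.frame of Gaussian curvature bumps: `label`
#'   (centre vertebra), `amp` (mm), `width` (vertebrae), `sign`
#'   (`"kyphotic"`/`"lordotic"`).
#' @slot wedgePlan data.frame `label`, `angle_deg` of planted wedges;
#'   `wedgeMean`, `wedgeSd` the cohort-level wedge-count calibration.
#' @slot fusionPlan character labels fused with their caudal neighbour.
#' @slot ribPlan data.frame per (side, index): `present`, `targetLc`
#'   (mm), `wavAmp` (mm), `wavLambda` (mm).
#' @slot ribLcSd numeric between-specimen SD of fifth-left rib length.
#' @slot absentNum,absentDen integers: in a cohort, specimen i is planted
#'   with absent ribs iff `((i-1) mod absentDen) < absentNum`.
#' @slot absentPerSpecimen integer ribs removed in an affected specimen.
#' @slot noiseSd numeric i.i.d. Gaussian landmark noise SD (mm).
#' @slot seed integer default seed.
#' @export
setClass("GeneratorConfig",
  representation(
    stage = "integer",
    group = "character",
    targetHeightMm = "numeric",
    heightSd = "numeric",
    vertebraCounts = "integer",
    baselineAmp = "numeric",
    deformities = "data.frame",
    wedgePlan = "data.frame",
    wedgeMean = "numeric",
    wedgeSd = "numeric",
    fusionPlan = "character",
    ribPlan = "data.frame",
    ribLcSd = "numeric",
    absentNum = "integer",
    absentDen = "integer",
    absentPerSpecimen = "integer",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  if (object@targetHeightMm <= 0) return("target height must be positive")
  if (object@noiseSd < 0) return("noise SD must be >= 0")
  if (nrow(object@wedgePlan) && any(object@wedgePlan$angle_deg <= 0))
    return("planted wedge angles must be positive")
  lc <- object@ribPlan$targetLc
  if (length(lc) && any(!is.na(lc) & lc <= 0))
    return("rib target lengths must be positive")
  if (object@absentNum > object@absentDen) return("absentNum cannot exceed absentDen")
  TRUE
})

## ---- constructors ----------------------------------------------------

#' Construct a Spine
#'
#' @param specimenID character id.
#' @param stage integer embryonic day.
#' @param group character treatment group.
#' @param vertebrae data.frame of per-vertebra landmarks (see [Spine-class]).
#' @param regionMap named integer vector of per-region vertebra counts.
#' @return a [Spine-class] object.
#' @export
Spine <- function(specimenID, stage, group, vertebrae,
                  regionMap = c(C = 14L, T = 7L, L = 7L)) {
  new("Spine", specimenID = as.character(specimenID), stage = as.integer(stage),
      group = as.character(group), vertebrae = vertebrae,
      regionMap = regionMap)
}

#' Construct a Rib
#'
#' @param side `"left"` or `"right"`.
#' @param index thoracic index, 1-7.
#' @param centerline n x 3 matrix (mm) or `NULL` for an absent rib.
#' @param present logical; defaults to whether a centerline was given.
#' @param fusedWith optional id of a rib annotated as fused to this one.
#' @return a [Rib-class] object.
#' @export
Rib <- function(side, index, centerline = NULL,
                present = !is.null(centerline), fusedWith = NA_character_) {
  force(present)
  if (is.null(centerline)) centerline <- matrix(numeric(0), ncol = 3)
  else centerline <- .asPoints(centerline)
  new("Rib", side = side, index = as.integer(index), present = present,
      centerline = centerline, fusedWith = fusedWith)
}

#' Construct a Specimen
#'
#' @param spine a [Spine-class].
#' @param ribs list of [Rib-class] objects.
#' @return a [Specimen-class] object.
#' @export
Specimen <- function(spine, ribs = list()) {
  new("Specimen", spine = spine, ribs = ribs)
}

## ---- accessors -------------------------------------------------------

#' @rdname accessors
setMethod("specimenID", "Spine", function(x) x@specimenID)
#' @rdname accessors
setMethod("specimenID", "Specimen", function(x) x@spine@specimenID)
#' @rdname accessors
setMethod("specimenID", "WedgeReport", function(x) x@specimenID)
#' @rdname accessors
setMethod("specimenID", "CurvatureProfile", function(x) x@specimenID)

#' @rdname accessors
setMethod("embryonicDay", "Spine", function(x) x@stage)
#' @rdname accessors
setMethod("embryonicDay", "Specimen", function(x) x@spine@stage)
#' @rdname accessors
setMethod("embryonicDay", "GeneratorConfig", function(x) x@stage)

#' @rdname accessors
setMethod("treatmentGroup", "Spine", function(x) x@group)
#' @rdname accessors
setMethod("treatmentGroup", "Specimen", function(x) x@spine@group)
#' @rdname accessors
setMethod("treatmentGroup", "GeneratorConfig", function(x) x@group)

#' @rdname accessors
setMethod("vertebrae", "Spine", function(x) x@vertebrae)
#' @rdname accessors
setMethod("vertebrae", "Specimen", function(x) x@spine@vertebrae)

#' @rdname accessors
setMethod("ribs", "Specimen", function(x) x@ribs)

#' @rdname wedge-accessors
setMethod("nWedged", "WedgeReport", function(x) sum(x@records$wedged, na.rm = TRUE))
#' @rdname wedge-accessors
setMethod("nFused", "WedgeReport", function(x) sum(x@records$fused, na.rm = TRUE))
#' @rdname wedge-accessors
setMethod("nAbnormal", "WedgeReport", function(x)
  sum(x@records$wedged | x@records$fused, na.rm = TRUE))
#' @rdname wedge-accessors
setMethod("wedgeRecords", "WedgeReport", function(x) x@records)

#' Vertebral centres of a spine
#'
#' @param spine a [Spine-class] or [Specimen-class].
#' @param labels optional character vector restricting to given labels.
#' @return numeric matrix (n x 3) of centres, mm, cranial to caudal.
#' @export
spineCentres <- function(spine, labels = NULL) {
  if (is(spine, "Specimen")) spine <- spine@spine
  v <- spine@vertebrae
  if (!is.null(labels)) v <- v[v$label %in% labels, , drop = FALSE]
  m <- as.matrix(v[, c("cx", "cy", "cz")])
  rownames(m) <- v$label
  m
}

#' Extract the profile table of a CurvatureProfile
#'
#' @param x a [CurvatureProfile-class] (or a `WedgeReport`).
#' @param ... ignored.
#' @return data.frame with specimen metadata columns prepended.
#' @export
setMethod("as.data.frame", "CurvatureProfile", function(x, ...) {
  cbind(specimen_id = x@specimenID, group = x@group, stage = x@stage,
        x@profile, stringsAsFactors = FALSE)
})

#' @rdname as.data.frame-CurvatureProfile-method
#' @export
setMethod("as.data.frame", "WedgeReport", function(x, ...) {
  cbind(specimen_id = x@specimenID, group = x@group, stage = x@stage,
        x@records, stringsAsFactors = FALSE)
})

## ---- show methods ----------------------------------------------------

setMethod("show", "Spine", function(object) {
  v <- object@vertebrae
  cat(sprintf("Spine '%s' (%s, E%d): %d vertebrae [%s..%s]\n",
              object@specimenID, object@group, object@stage, nrow(v),
              v$label[1], v$label[nrow(v)]))
})

setMethod("show", "Specimen", function(object) {
  show(object@spine)
  pres <- vapply(object@ribs, slot, logical(1), name = "present")
  cat(sprintf("  ribs: %d planned, %d present\n", length(pres), sum(pres)))
})

setMethod("show", "Rib", function(object) {
  cat(sprintf("Rib %s%d: %s (%d centerline points)\n", object@side,
              object@index, if (object@present) "present" else "absent",
              nrow(object@centerline)))
})

setMethod("show", "WedgeReport", function(object) {
  cat(sprintf("WedgeReport '%s' (%s, E%d): %d wedged, %d fused, %d abnormal (threshold %g deg)\n",
              object@specimenID, object@group, object@stage,
              nWedged(object), nFused(object), nAbnormal(object),
              object@threshold))
})

setMethod("show", "CurvatureProfile", function(object) {
  cat(sprintf("CurvatureProfile '%s' (%s, E%d): %d vertebrae, max |GC| %.3g mm^-1\n",
              object@specimenID, object@group, object@stage,
              nrow(object@profile), max(object@profile$gc, na.rm = TRUE)))
})

setMethod("show", "SplineCurve", function(object) {
  cat(sprintf("SplineCurve: %d knots over p in [%g, %g], %s fit\n",
              length(object@knots), min(object@knots), max(object@knots),
              if (is.na(object@smoothing)) "interpolating" else
                sprintf("smoothing (spar = %g)", object@smoothing)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig E%d %s: height %.2f mm, %d planted wedges, %d fusions, %d/%d absent-rib specimens, noise SD %g mm\n",
              object@stage, object@group, object@targetHeightMm,
              nrow(object@wedgePlan), length(object@fusionPlan),
              object@absentNum, object@absentDen, object@noiseSd))
})
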