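#' @import methods
#' @importFrom stats approx aov lm pf pt qtukey ptukey rnorm runif sd
#'   smooth.spline splinefun t.test TukeyHSD predict var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname computeGCProfile
#' @export
setGeneric("computeGCProfile", function(x, ...) standardGeneric("computeGCProfile"))

#' @rdname spineHeight
#' @export
setGeneric("spineHeight", function(x, ...) standardGeneric("spineHeight"))

#' @rdname classifyVertebrae
#' @export
setGeneric("classifyVertebrae", function(x, ...) standardGeneric("classifyVertebrae"))

#' Accessors for specimen-level objects
#'
#' `specimenID()`, `embryonicDay()` and `treatmentGroup()` return the
#' identity, stage (embryonic day, integer) and treatment group of a
#' [Spine], [Specimen] or derived report. `vertebrae()` returns the
#' per-vertebra landmark table of a spine; `ribs()` the list of [Rib]
#' objects of a specimen.
#'
#' @param x a `Spine`, `Specimen`, `WedgeReport` or `CurvatureProfile`.
#' @return See details; scalar metadata or the underlying table/list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specimenID", function(x) standardGeneric("specimenID"))

#' @rdname accessors
#' @export
setGeneric("embryonicDay", function(x) standardGeneric("embryonicDay"))

#' @rdname accessors
#' @export
setGeneric("treatmentGroup", function(x) standardGeneric("treatmentGroup"))

#' @rdname accessors
#' @export
setGeneric("vertebrae", function(x) standardGeneric("vertebrae"))

#' @rdname accessors
#' @export
setGeneric("ribs", function(x) standardGeneric("ribs"))

#' Wedge-report accessors
#'
#' Counts of wedged, fused and abnormal (wedged or fused) vertebrae in a
#' [WedgeReport], and the per-vertebra record table.
#'
#' @param x a `WedgeReport`.
#' @return `nWedged()`, `nFused()`, `nAbnormal()` return a single integer;
#'   `wedgeRecords()` a data frame with one row per vertebra (columns
#'   `label`, `angle_deg`, `wedged`, `fused`, `measured`).
#' @name wedge-accessors
NULL

#' @rdname wedge-accessors
#' @export
setGeneric("nWedged", function(x) standardGeneric("nWedged"))

#' @rdname wedge-accessors
#' @export
setGeneric("nFused", function(x) standardGeneric("nFused"))

#' @rdname wedge-accessors
#' @export
setGeneric("nAbnormal", function(x) standardGeneric("nAbnormal"))

#' @rdname wedge-accessors
#' @export
setGeneric("wedgeRecords", function(x) standardGeneric("wedgeRecords"))
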