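.schemaVersion <- "1.0"

.numOrStop <- function(x, path) {
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (any(is.na(v)))
    stop("validation error at ", path, ": non-numeric coordinate")
  v
}

#' Write a specimen to a JSON document
#'
#' Serialises a [Specimen-class] (or bare [Spine-class]) to the specimen
#' JSON schema: metadata, a `units` field fixed to `"mm"`, per-vertebra
#' centres and endplate endpoint pairs, and per-rib centerlines. The
#' document round-trips losslessly through [readSpecimen()].
#'
#' @param specimen a `Specimen` or `Spine`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpecimen <- function(specimen, path) {
  if (is(specimen, "Spine")) specimen <- Specimen(specimen)
  stopifnot(is(specimen, "Specimen"))
  sp <- specimen@spine
  v <- sp@vertebrae
  vert <- lapply(seq_len(nrow(v)), function(i) list(
    label = v$label[i], region = v$region[i], ord = v$ord[i],
    centre = c(v$cx[i], v$cy[i], v$cz[i]),
    superior_endplate = list(c(v$sx1[i], v$sy1[i], v$sz1[i]),
                             c(v$sx2[i], v$sy2[i], v$sz2[i])),
    inferior_endplate = list(c(v$ix1[i], v$iy1[i], v$iz1[i]),
                             c(v$ix2[i], v$iy2[i], v$iz2[i])),
    fused_with_next = isTRUE(v$fusedWithNext[i])))
  ribsDoc <- lapply(specimen@ribs, function(r) list(
    side = r@side, index = r@index, present = r@present,
    fused_with = if (is.na(r@fusedWith)) NULL else r@fusedWith,
    centerline = if (r@present) unname(apply(r@centerline, 1L, c,
                                             simplify = FALSE)) else list()))
  doc <- list(schema_version = .schemaVersion,
              specimen_id = sp@specimenID,
              stage = sp@stage, group = sp@group, units = "mm",
              region_map = as.list(sp@regionMap),
              vertebrae = vert, ribs = ribsDoc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a specimen from a JSON document
#'
#' Parses and validates a specimen document written by [writeSpecimen()].
#' Validation errors name the offending path; a missing `ribs` block
#' yields a specimen with zero ribs and a warning; an unknown
#' `schema_version` is refused.
#'
#' @param path file path.
#' @return a [Specimen-class].
#' @export
readSpecimen <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema_version) || doc$schema_version != .schemaVersion)
    stop("unsupported version: schema_version must be ", .schemaVersion)
  for (fld in c("specimen_id", "stage", "group", "units", "vertebrae"))
    if (is.null(doc[[fld]])) stop("validation error at $", fld, ": missing")
  if (doc$units != "mm") stop("validation error at $units: must be 'mm'")
  nv <- length(doc$vertebrae)
  rows <- vector("list", nv)
  for (i in seq_len(nv)) {
    vd <- doc$vertebrae[[i]]
    where <- sprintf("$vertebrae[%d]", i)
    if (is.null(vd$label)) stop("validation error at ", where, ".label: missing")
    ctr <- .numOrStop(vd$centre, paste0(where, ".centre"))
    sup <- .numOrStop(vd$superior_endplate, paste0(where, ".superior_endplate"))
    inf <- .numOrStop(vd$inferior_endplate, paste0(where, ".inferior_endplate"))
    if (length(ctr) != 3L || length(sup) != 6L || length(inf) != 6L)
      stop("validation error at ", where, ": wrong coordinate arity")
    rows[[i]] <- data.frame(
      label = vd$label, region = vd$region %||% sub("[0-9]+$", "", vd$label),
      ord = vd$ord %||% i,
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      sx1 = sup[1], sy1 = sup[2], sz1 = sup[3],
      sx2 = sup[4], sy2 = sup[5], sz2 = sup[6],
      ix1 = inf[1], iy1 = inf[2], iz1 = inf[3],
      ix2 = inf[4], iy2 = inf[5], iz2 = inf[6],
      fusedWithNext = isTRUE(vd$fused_with_next), stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, rows)
  regionMap <- if (!is.null(doc$region_map))
    vapply(doc$region_map, as.integer, integer(1)) else c(C = 14L, T = 7L, L = 7L)
  spine <- Spine(doc$specimen_id, doc$stage, doc$group, v, regionMap = regionMap)
  if (is.null(doc$ribs)) {
    warning("specimen document has no ribs block; returning zero ribs")
    return(Specimen(spine))
  }
  ribsList <- lapply(seq_along(doc$ribs), function(k) {
    rd <- doc$ribs[[k]]
    where <- sprintf("$ribs[%d]", k)
    if (is.null(rd$side) || is.null(rd$index))
      stop("validation error at ", where, ": missing side/index")
    if (isTRUE(rd$present)) {
      pts <- matrix(.numOrStop(rd$centerline, paste0(where, ".centerline")),
                    ncol = 3L, byrow = TRUE)
      Rib(rd$side, rd$index, centerline = pts,
          fusedWith = rd$fused_with %||% NA_character_)
    } else {
      Rib(rd$side, rd$index, fusedWith = rd$fused_with %||% NA_character_)
    }
  })
  Specimen(spine, ribsList)
}

#' Write polyline landmarks as CSV
#'
#' Long-format CSV (`specimen_id`, `structure`, `ordinal`, `x_mm`,
#' `y_mm`, `z_mm`; UTF-8, dot decimal) for a named list of polylines.
#'
#' @param polylines named list of n x 3 matrices.
#' @param specimenID id recorded in the first column.
#' @param path output path.
#' @return `path` invisibly.
#' @export
writePolylinesCSV <- function(polylines, specimenID, path) {
  rows <- lapply(names(polylines), function(nm) {
    m <- .asPoints(polylines[[nm]])
    data.frame(specimen_id = specimenID, structure = nm,
               ordinal = seq_len(nrow(m)),
               x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePolylinesCSV
#' @export
readPolylinesCSV <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "structure", "ordinal", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing polyline columns: ", paste(miss, collapse = ", "))
  split_keys <- interaction(tab$specimen_id, tab$structure, drop = TRUE)
  lapply(split(tab, split_keys), function(d) {
    d <- d[order(d$ordinal), ]
    as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
  })
}
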