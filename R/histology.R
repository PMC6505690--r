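## Histology joint-status tables: one row per (specimen, region, joint
## type) with counts of fused vs. total joints visible across sections.

.jointRegions <- c("cervical", "thoracic", "lumbar")
.jointTypes <- c("vertebral_body", "spinous_process")

#' Validate a joint-status table
#'
#' @param table data.frame with columns `specimen_id`, `region`,
#'   `joint_type`, `n_fused`, `n_total`.
#' @return the table, invisibly, after checks.
#' @export
validateJointTable <- function(table) {
  need <- c("specimen_id", "region", "joint_type", "n_fused", "n_total")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing joint-table columns: ", paste(miss, collapse = ", "))
  if (!all(table$region %in% .jointRegions))
    stop("region must be one of: ", paste(.jointRegions, collapse = ", "))
  if (!all(table$joint_type %in% .jointTypes))
    stop("joint_type must be one of: ", paste(.jointTypes, collapse = ", "))
  if (any(table$n_total < 1)) stop("n_total must be >= 1")
  if (any(table$n_fused < 0) || any(table$n_fused > table$n_total))
    stop("need 0 <= n_fused <= n_total")
  invisible(table)
}

#' Proportion of fused joints in a region
#'
#' The ratio between the number of fused (or partially segmented) joints
#' and the total number of joints visible in a region over all histology
#' sections. Rows matching the query are pooled additively (sum of fused
#' over sum of total), so per-section rows and pre-pooled rows give the
#' same answer. No statistics are attached: these proportions come from
#' very few specimens and are meant for dot-plot style display.
#'
#' @param table a joint-status table (see [validateJointTable()]).
#' @param region `"cervical"`, `"thoracic"` or `"lumbar"`.
#' @param jointType `"vertebral_body"` or `"spinous_process"`.
#' @param specimenID optional; restrict to one specimen.
#' @return proportion in [0, 1].
#' @examples
#' tab <- data.frame(specimen_id = "s1", region = "cervical",
#'                   joint_type = "vertebral_body", n_fused = 3, n_total = 10)
#' fusedProportion(tab, "cervical", "vertebral_body")  # 0.3
#' @export
fusedProportion <- function(table, region, jointType, specimenID = NULL) {
  validateJointTable(table)
  region <- match.arg(region, .jointRegions)
  jointType <- match.arg(jointType, .jointTypes)
  sub <- table[table$region == region & table$joint_type == jointType, , drop = FALSE]
  if (!is.null(specimenID)) sub <- sub[sub$specimen_id %in% specimenID, , drop = FALSE]
  if (!nrow(sub)) stop("region/type not scored: ", region, "/", jointType)
  sum(sub$n_fused) / sum(sub$n_total)
}

#' Fused-joint proportions for every scored combination
#'
#' @param table a joint-status table.
#' @param bySpecimen pool across specimens (`FALSE`, default) or report
#'   per specimen.
#' @return data.frame of proportions per (region, joint_type) and,
#'   optionally, specimen.
#' @export
fusedProportionTable <- function(table, bySpecimen = TRUE) {
  validateJointTable(table)
  keyCols <- if (bySpecimen) c("specimen_id", "region", "joint_type") else
    c("region", "joint_type")
  keys <- unique(table[, keyCols, drop = FALSE])
  keys$proportion <- vapply(seq_len(nrow(keys)), function(k) {
    fusedProportion(table, keys$region[k], keys$joint_type[k],
                    specimenID = if (bySpecimen) keys$specimen_id[k] else NULL)
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}

#' Read / write joint-status tables as CSV
#'
#' Plain UTF-8 CSV with a header row, comma separator and dot decimal,
#' mirroring the joint-status schema.
#'
#' @param path file path.
#' @return `readJointStatusCSV` returns a validated data.frame.
#' @export
readJointStatusCSV <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validateJointTable(tab)
  tab
}

#' @rdname readJointStatusCSV
#' @param table table to write.
#' @export
writeJointStatusCSV <- function(table, path) {
  validateJointTable(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
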