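#' Run the full measurement pipeline over a cohort
#'
#' Measures every specimen (curvature profile, wedge/fusion report, rib
#' metrics and census), summarises cohorts, optionally runs per-vertebra
#' group comparisons, and writes all result tables as CSV. The run is
#' deterministic given its inputs: re-running on the same specimens
#' produces byte-identical CSVs.
#'
#' Written files (in `outDir`): `profiles.csv`, `wedge_reports.csv`,
#' `rib_metrics.csv`, `rib_census.csv`, `abnormal_summary.csv`,
#' `rib_summary.csv`, `comparisons.csv` (when a design is given),
#' `errors.csv` (when some specimens failed) and `run_log.txt`.
#'
#' @param specimens a list of [Specimen-class] objects, or a directory
#'   containing specimen JSON documents (read with [readSpecimen()]).
#' @param outDir output directory, created if needed; `NULL` to skip
#'   writing.
#' @param design `NULL`, `"critical_timings"` or `"ontogenetic"`; when
#'   given, [perLocationComparison()] is run on the stacked profiles.
#' @param smoothing spline smoothing passed to [computeGCProfile()].
#' @return (invisibly) a list with elements `profiles`, `wedges`,
#'   `ribMetrics`, `census`, `abnormalSummary`, `ribSummary`,
#'   `comparisons`, `errors`.
#' @export
runPipeline <- function(specimens, outDir = NULL, design = NULL,
                        smoothing = NULL) {
  if (is.character(specimens) && length(specimens) == 1L) {
    paths <- sort(list.files(specimens, pattern = "\\.json$", full.names = TRUE))
    if (!length(paths)) stop("no specimen JSON documents found in ", specimens)
    specimens <- lapply(paths, readSpecimen)
  }
  if (is(specimens, "Specimen")) specimens <- list(specimens)

  profs <- list(); wedges <- list(); ribTabs <- list(); censusTabs <- list()
  reports <- list(); errs <- list()
  for (sp in specimens) {
    sid <- specimenID(sp)
    res <- tryCatch({
      pr <- computeGCProfile(sp, smoothing = smoothing)
      wr <- classifyVertebrae(sp)
      rowsRib <- lapply(ribs(sp), function(r) {
        base <- data.frame(specimen_id = sid, group = treatmentGroup(sp),
                           stage = embryonicDay(sp), side = r@side,
                           index = r@index, present = r@present,
                           stringsAsFactors = FALSE)
        if (r@present) cbind(base, ribMetrics(r))
        else cbind(base, data.frame(L_C_mm = NA_real_, L_S_mm = NA_real_,
                                    N = NA_integer_, ICM = NA_real_))
      })
      cen <- ribCensus(sp)
      list(pr = pr, wr = wr,
           rib = if (length(rowsRib)) do.call(rbind, rowsRib) else NULL,
           cen = data.frame(specimen_id = sid, group = treatmentGroup(sp),
                            stage = embryonicDay(sp),
                            has_absent = cen$hasAbsent,
                            n_fused_pairs = nrow(cen$fusedPairs),
                            stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(specimen_id = sid,
                                              error = conditionMessage(res),
                                              stringsAsFactors = FALSE)
      next
    }
    profs[[length(profs) + 1L]] <- res$pr
    reports[[length(reports) + 1L]] <- res$wr
    wedges[[length(wedges) + 1L]] <- as.data.frame(res$wr)
    if (!is.null(res$rib)) ribTabs[[length(ribTabs) + 1L]] <- res$rib
    censusTabs[[length(censusTabs) + 1L]] <- res$cen
  }
  if (!length(profs)) stop("all specimens failed to measure")

  out <- list(
    profiles = profilesTable(profs),
    wedges = do.call(rbind, wedges),
    ribMetrics = if (length(ribTabs)) do.call(rbind, ribTabs) else NULL,
    census = do.call(rbind, censusTabs),
    abnormalSummary = cohortAbnormalSummary(reports),
    ribSummary = tryCatch(cohortRibSummary(specimens), error = function(e) NULL),
    comparisons = NULL,
    errors = if (length(errs)) do.call(rbind, errs) else NULL)
  if (!is.null(design))
    out$comparisons <- perLocationComparison(out$profiles, design = design)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) if (!is.null(tab))
      write.csv(tab, file.path(outDir, name), row.names = FALSE)
    wr(out$profiles, "profiles.csv")
    wr(out$wedges, "wedge_reports.csv")
    wr(out$ribMetrics, "rib_metrics.csv")
    wr(out$census, "rib_census.csv")
    wr(out$abnormalSummary, "abnormal_summary.csv")
    wr(out$ribSummary, "rib_summary.csv")
    wr(out$comparisons, "comparisons.csv")
    wr(out$errors, "errors.csv")
    log <- c(sprintf("spinemorph %s", as.character(utils::packageVersion("spinemorph"))),
             sprintf("specimens: %d measured, %d failed", length(profs), length(errs)),
             sprintf("design: %s", design %||% "none"),
             sprintf("smoothing: %s", if (is.null(smoothing)) "interpolating" else smoothing))
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  invisible(out)
}

#' Simulate a cohort and write it as specimen documents
#'
#' Convenience wrapper: [generateCohort()] then [writeSpecimen()] for
#' each specimen, plus a `manifest.csv` recording ids, group, stage and
#' the seed of every generator call for exact replay.
#'
#' @param config a [GeneratorConfig-class].
#' @param n cohort size.
#' @param baseSeed base seed.
#' @param outDir output directory.
#' @return (invisibly) the manifest data.frame.
#' @export
simulateCohortFiles <- function(config, n, baseSeed, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(config, n, baseSeed)
  man <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    sid <- specimenID(cohort[[i]])
    writeSpecimen(cohort[[i]], file.path(outDir, paste0(sid, ".json")))
    data.frame(specimen_id = sid, group = treatmentGroup(cohort[[i]]),
               stage = embryonicDay(cohort[[i]]),
               spine_seed = baseSeed + i - 1L,
               rib_seed = baseSeed + i - 1L + 1000003L,
               stringsAsFactors = FALSE)
  }))
  write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
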