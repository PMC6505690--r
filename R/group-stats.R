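.dropSmallGroups <- function(values, groups, minN = 2L) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < minN]
  if (length(small)) {
    warning("groups with fewer than 2 values excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  list(values = values, groups = factor(groups))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within mean squares, F
#' on k-1 and N-k degrees of freedom) fitted with [stats::aov()]. Groups
#' with fewer than two values are excluded with a warning. When the
#' between-group sum of squares is exactly zero the F statistic is 0 and
#' p = 1, including the fully degenerate all-constant case.
#'
#' @param values numeric response.
#' @param groups group labels, same length as `values`.
#' @return list with `statistic` (F), `p_value`, `df` (length 2) and the
#'   underlying `aov` fit (`NULL` in degenerate cases).
#' @export
oneWayAnova <- function(values, groups) {
  d <- .dropSmallGroups(values, groups)
  k <- nlevels(d$groups)
  if (k < 2L) stop("insufficient groups: need at least 2 groups with >= 2 values")
  gm <- tapply(d$values, d$groups, mean)
  ssb <- sum(tapply(d$values, d$groups, length) * (gm - mean(d$values))^2)
  ssw <- sum((d$values - gm[d$groups])^2)
  df <- c(k - 1L, length(d$values) - k)
  if (ssb <= .Machine$double.eps * max(1, sum(d$values^2)))
    return(list(statistic = 0, p_value = 1, df = df, fit = NULL))
  if (ssw == 0)
    return(list(statistic = Inf, p_value = 0, df = df, fit = NULL))
  fit <- aov(d$values ~ d$groups)
  s <- summary(fit)[[1L]]
  list(statistic = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
       df = df, fit = fit)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, adjusted with the
#' studentized-range distribution at family level alpha = 0.05
#' ([stats::TukeyHSD()]). With exactly two groups the adjusted p-value
#' equals the pooled-variance t-test p-value.
#'
#' @inheritParams oneWayAnova
#' @return data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukeyHsd <- function(values, groups) {
  d <- .dropSmallGroups(values, groups)
  if (nlevels(d$groups) < 2L)
    stop("insufficient groups: need at least 2 groups with >= 2 values")
  if (var(d$values) == 0) {
    lev <- levels(d$groups)
    pairs <- outer(lev, lev, paste, sep = "-")[lower.tri(matrix(0, length(lev), length(lev)))]
    return(data.frame(pair = pairs, diff = 0, lwr = 0, upr = 0, p_adj = 1,
                      stringsAsFactors = FALSE))
  }
  g <- d$groups
  fit <- aov(d$values ~ g)
  tk <- TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-tailed unpaired t-test
#'
#' Student two-sample t-test with pooled variance by default (set
#' `pooled = FALSE` for the Welch form). Degenerate zero-variance inputs
#' are resolved explicitly: equal means give p = 1, unequal means give
#' p = 0 with a warning.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param pooled use the pooled-variance (Student) statistic.
#' @return list with `statistic` (t), `p_value`, `df`.
#' @export
tTestUnpaired <- function(a, b, pooled = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1, df = df))
    warning("zero pooled variance with unequal means; p = 0")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0, df = df))
  }
  tt <- t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Per-vertebra group comparisons of curvature profiles
#'
#' Applies the study's statistical design to a long profile table (see
#' [profilesTable()]). For the critical-timings design each vertebral
#' location is compared across treatment groups at a common harvest stage
#' with a one-way ANOVA followed by Tukey post-hoc tests against the
#' control group. For the ontogenetic design each location is compared
#' between the immobilised group and its age-matched control with a
#' two-tailed unpaired (pooled-variance) t-test, stage by stage.
#' Significance is flagged at `alpha` with no correction across
#' locations, mirroring per-vertebra reporting. Locations observed in
#' fewer than half of either group's specimens are skipped with a
#' warning.
#'
#' @param profiles data.frame with columns `specimen_id`, `group`,
#'   `stage`, `label` and the response column `value`.
#' @param design `"critical_timings"` or `"ontogenetic"`.
#' @param value name of the response column (default `"gc"`).
#' @param control label of the control group.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `location`, `stage`, `test`, `statistic`,
#'   `p_value`, `significant`; for the ANOVA design the Tukey pairwise
#'   table is attached as attribute `"pairwise"`.
#' @export
perLocationComparison <- function(profiles,
                                  design = c("critical_timings", "ontogenetic"),
                                  value = "gc", control = "control",
                                  alpha = 0.05) {
  design <- match.arg(design)
  need <- c("specimen_id", "group", "stage", "label", value)
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profile table lacks columns: ", paste(miss, collapse = ", "))
  profiles <- profiles[!is.na(profiles[[value]]), , drop = FALSE]
  out <- list(); pairwise <- list()

  .groupSizes <- function(df) tapply(df$specimen_id, df$group,
                                     function(s) length(unique(s)))

  if (design == "critical_timings") {
    sizes <- .groupSizes(profiles)
    for (lab in unique(profiles$label)) {
      sub <- profiles[profiles$label == lab, ]
      nHere <- tapply(sub$specimen_id, factor(sub$group, names(sizes)),
                      function(s) length(unique(s)))
      nHere[is.na(nHere)] <- 0L
      if (any(nHere < sizes / 2)) {
        warning(sprintf("location %s observed in fewer than half of a group; skipped", lab))
        next
      }
      res <- tryCatch(oneWayAnova(sub[[value]], sub$group), error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- data.frame(
        location = lab, stage = NA_integer_, test = "anova_tukey",
        statistic = res$statistic, p_value = res$p_value,
        significant = res$p_value < alpha, stringsAsFactors = FALSE)
      tk <- tryCatch(tukeyHsd(sub[[value]], sub$group), error = function(e) NULL)
      if (!is.null(tk)) {
        tk <- tk[grepl(control, tk$pair, fixed = TRUE), , drop = FALSE]
        if (nrow(tk)) pairwise[[length(pairwise) + 1L]] <- cbind(location = lab, tk)
      }
    }
  } else {
    for (st in sort(unique(profiles$stage))) {
      atStage <- profiles[profiles$stage == st, ]
      gs <- setdiff(unique(atStage$group), control)
      for (g in gs) {
        sub <- atStage[atStage$group %in% c(control, g), ]
        sizes <- .groupSizes(sub)
        if (length(sizes) < 2L) next
        for (lab in unique(sub$label)) {
          here <- sub[sub$label == lab, ]
          nHere <- tapply(here$specimen_id, factor(here$group, names(sizes)),
                          function(s) length(unique(s)))
          nHere[is.na(nHere)] <- 0L
          if (any(nHere < sizes / 2)) {
            warning(sprintf("location %s (E%d) observed in fewer than half of a group; skipped",
                            lab, st))
            next
          }
          res <- tryCatch(
            tTestUnpaired(here[[value]][here$group == g],
                          here[[value]][here$group == control]),
            error = function(e) NULL)
          if (is.null(res)) next
          out[[length(out) + 1L]] <- data.frame(
            location = lab, stage = st, test = "t_test",
            statistic = res$statistic, p_value = res$p_value,
            significant = res$p_value < alpha, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(location = character(0), stage = integer(0), test = character(0),
               statistic = numeric(0), p_value = numeric(0),
               significant = logical(0))
  if (length(pairwise)) attr(res, "pairwise") <- do.call(rbind, pairwise)
  res
}
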