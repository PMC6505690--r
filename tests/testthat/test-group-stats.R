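test_that("one-way ANOVA matches hand computation", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- oneWayAnova(vals, grp)
  # SSB = 54 on 2 df, SSW = 6 on 6 df -> F = 27
  expect_equal(res$statistic, 27, tolerance = 1e-9)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res$p_value, 0.001, tolerance = 0.01)
})

test_that("degenerate ANOVA inputs resolve as documented", {
  res <- oneWayAnova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- oneWayAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)

  res <- oneWayAnova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, Inf)
  expect_equal(res$p_value, 0)

  expect_warning(res <- oneWayAnova(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluded")
  expect_error(suppressWarnings(oneWayAnova(c(1, 2, 9), c("a", "a", "c"))),
               "insufficient groups")
})

test_that("unpaired t-test matches hand computation and is symmetric", {
  res <- tTestUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(res$df, 4)

  sw <- tTestUnpaired(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$statistic, -res$statistic)
  expect_equal(sw$p_value, res$p_value)

  same <- tTestUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flat <- tTestUnpaired(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_warning(off <- tTestUnpaired(c(2, 2), c(3, 3)), "zero pooled variance")
  expect_equal(off$p_value, 0)
})

test_that("Tukey HSD is ordered and reduces to the pooled t at k = 2", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  tk <- tukeyHsd(vals, grp)
  expect_equal(nrow(tk), 3)
  expect_equal(tk$pair[which.min(tk$p_adj)], "c-a")  # extreme pair

  idGroups <- tukeyHsd(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(idGroups$p_adj, 1, tolerance = 1e-9)

  set.seed(21)
  for (k in 1:5) {
    a <- rnorm(6); b <- rnorm(5, mean = 0.8)
    tk2 <- tukeyHsd(c(a, b), rep(c("a", "b"), c(6, 5)))
    tt <- tTestUnpaired(a, b)
    expect_equal(tk2$p_adj, tt$p_value, tolerance = 1e-6)
  }
})

test_that("per-location comparisons find planted effects and only those", {
  # identical cohorts: nothing significant
  co1 <- generateCohort(defaultConfig(9, "control"), 6, 1)
  pa <- profilesTable(lapply(co1, computeGCProfile))
  pb <- pa
  pb$group <- "Im4"
  pb$specimen_id <- paste0(pb$specimen_id, "_b")
  cmp <- perLocationComparison(rbind(pa, pb), design = "ontogenetic")
  expect_equal(sum(cmp$significant), 0)

  # a 5-SD mean shift at one location with n = 6 per group is detected
  shifted <- pb
  sdL2 <- sd(pa$gc[pa$label == "L2"])
  shifted$gc[shifted$label == "L2"] <- shifted$gc[shifted$label == "L2"] + 5 * sdL2
  cmp <- perLocationComparison(rbind(pa, shifted), design = "ontogenetic")
  expect_true(cmp$significant[cmp$location == "L2"])

  # a planted thoracolumbar deformity concentrates significant locations
  # around its support
  ctl <- generateCohort(defaultConfig(9, "control"), 8, 1)
  im <- generateCohort(defaultConfig(9, "Im4"), 8, 100)
  prof <- rbind(profilesTable(lapply(ctl, computeGCProfile)),
                profilesTable(lapply(im, computeGCProfile)))
  cmp <- perLocationComparison(prof, design = "critical_timings")
  sigLabs <- cmp$location[cmp$significant]
  expect_gt(length(sigLabs), 0)
  planted <- defaultConfig(9, "Im4")@deformities$label
  support <- unlist(lapply(planted, function(lb) {
    i <- match(lb, allLabels())
    allLabels()[max(1, i - 3):min(28, i + 3)]
  }))
  expect_gt(mean(sigLabs %in% support), 0.5)
  expect_s3_class(attr(cmp, "pairwise"), "data.frame")
})

test_that("locations observed in under half a group are skipped", {
  co1 <- generateCohort(defaultConfig(9, "control"), 4, 1)
  pa <- profilesTable(lapply(co1, computeGCProfile))
  pb <- pa; pb$group <- "Im4"; pb$specimen_id <- paste0(pb$specimen_id, "_b")
  # remove L4 from 3 of 4 control specimens
  drop <- pa$label == "L4" & pa$specimen_id %in% unique(pa$specimen_id)[1:3]
  expect_warning(cmp <- perLocationComparison(rbind(pa[!drop, ], pb),
                                              design = "ontogenetic"),
                 "skipped")
  expect_false("L4" %in% cmp$location)
})

test_that("null cohorts give the nominal per-location false-positive rate", {
  # identical generating parameters in both arms; ~2000 locations
  cfg <- defaultConfig(9, "control")
  sig <- 0L; tot <- 0L
  for (k in 1:96) {
    a <- generateCohort(cfg, 6, 10000 + 13 * k)
    b <- generateCohort(cfg, 6, 500000 + 13 * k)
    pa <- profilesTable(lapply(a, computeGCProfile))
    pb <- profilesTable(lapply(b, computeGCProfile))
    pb$group <- "ImNull"
    cmp <- perLocationComparison(rbind(pa, pb), design = "ontogenetic")
    sig <- sig + sum(cmp$significant)
    tot <- tot + nrow(cmp)
  }
  expect_gte(tot, 2000)
  rate <- sig / tot
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
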