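test_that("inflection counts match analytic expectations", {
  straight <- cbind(seq(0, 2.7, length.out = 50), 0, 0)
  expect_equal(countInflections(straight), 0)

  # sine over two periods: signed curvature changes sign at pi, 2pi, 3pi
  expect_equal(countInflections(sineCurve(4 * pi)), 3)

  # a single period has one interior inflection
  expect_equal(countInflections(sineCurve(2 * pi)), 1)

  # circular helix: the normal rotates smoothly, no flips
  expect_equal(countInflections(helixCurve()), 0)

  # semicircle: a single smooth curve
  expect_equal(countInflections(circleArc(1, span = pi, n = 300)), 0)
})

test_that("rib metrics follow the ICM formula", {
  straight <- cbind(seq(0, 2.7, length.out = 30), 0, 0)
  m <- ribMetrics(straight)
  expect_equal(m$L_C_mm, 2.7)
  expect_equal(m$L_S_mm, 2.7)
  expect_equal(m$N, 0)
  expect_equal(m$ICM, 0)

  # sine over two periods against the quadrature oracle
  m <- ribMetrics(sineCurve(4 * pi))
  lcOracle <- sineArcLengthOracle(4 * pi)
  expect_equal(m$N, 3)
  expect_equal(m$ICM, 3 * lcOracle / (4 * pi), tolerance = 0.01)

  semi <- circleArc(1, span = pi, n = 300)
  m <- ribMetrics(semi)
  expect_equal(m$N, 0)
  expect_equal(m$ICM, 0)
  expect_equal(m$L_C_mm / m$L_S_mm, pi / 2, tolerance = 1e-4)
})

test_that("ICM is scale invariant and L_C scales linearly", {
  sine <- sineCurve(4 * pi)
  base <- ribMetrics(sine)
  for (s in c(0.37, 2.5, 11)) {
    scaled <- ribMetrics(sine * s)
    expect_equal(scaled$ICM, base$ICM, tolerance = 1e-6)
    expect_equal(scaled$L_C_mm, base$L_C_mm * s, tolerance = 1e-9)
  }
})

test_that("degenerate rib inputs raise the documented errors", {
  expect_error(ribMetrics(Rib("left", 5)), "rib absent")
  loop <- circleArc(1, span = 2 * pi, n = 200)
  loop[nrow(loop), ] <- loop[1, ]
  loop <- loop[-nrow(loop), ]
  loop <- rbind(loop, loop[1, ] + c(1e-9, 0, 0))
  expect_error(ribMetrics(loop), "degenerate chord")
})

test_that("inflection count is stable across resampling resolutions", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  for (amp in c(0.05, 0.1)) {
    cfg@ribPlan$wavAmp <- amp
    sp <- generateSpine(cfg, 2)
    r5 <- fifthLeftRib(Specimen(sp, generateRibs(cfg, sp, 2)))
    m100 <- ribMetrics(r5, n = 100)
    m400 <- ribMetrics(r5, n = 400)
    expect_equal(m100$N, m400$N)
    expect_equal(m100$ICM, m400$ICM, tolerance = 0.02)
  }
})

test_that("ICM is non-decreasing in the planted waviness amplitude", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  icm <- vapply(c(0, 0.02, 0.05, 0.1, 0.15, 0.2), function(a) {
    cfg@ribPlan$wavAmp <- a
    sp <- generateSpine(cfg, 3)
    ribMetrics(fifthLeftRib(Specimen(sp, generateRibs(cfg, sp, 3))))$ICM
  }, numeric(1))
  expect_equal(icm[1], 0)  # zero amplitude: single smooth arc
  expect_true(all(diff(icm) >= 0))
})

test_that("rib census flags absences and annotated or touching fusions", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  sp <- generateSpine(cfg, 1)
  full <- Specimen(sp, generateRibs(cfg, sp, 1))
  cen <- ribCensus(full)
  expect_false(cen$hasAbsent)
  expect_equal(nrow(cen$fusedPairs), 0)
  expect_equal(sum(cen$presence$present), 14)

  cfg2 <- cfg
  cfg2@ribPlan$present[cfg2@ribPlan$side == "left" & cfg2@ribPlan$index == 3] <- FALSE
  missing3 <- Specimen(sp, generateRibs(cfg2, sp, 1))
  expect_true(ribCensus(missing3)$hasAbsent)

  # two near-identical adjacent centerlines read as fused
  rbs <- generateRibs(cfg, sp, 1)
  i3 <- which(vapply(rbs, function(r) r@side == "left" && r@index == 3, logical(1)))
  i4 <- which(vapply(rbs, function(r) r@side == "left" && r@index == 4, logical(1)))
  touching <- rbs[[i3]]@centerline
  touching <- touching + matrix(c(0, 0.01, 0), nrow(touching), 3, byrow = TRUE)
  rbs[[i4]] <- Rib("left", 4, centerline = touching)
  cen <- ribCensus(Specimen(sp, rbs))
  expect_true(nrow(cen$fusedPairs) >= 1)
  expect_true(any(cen$fusedPairs[, 1] == "left3" & cen$fusedPairs[, 2] == "left4"))

  # annotated fusion without geometric contact
  rbs2 <- generateRibs(cfg, sp, 1)
  rbs2[[i4]]@fusedWith <- "left3"
  expect_true(nrow(ribCensus(Specimen(sp, rbs2))$fusedPairs) == 1)
})

test_that("cohort rib summaries exclude absent fifth ribs from means only", {
  co <- generateCohort(defaultConfig(9, "control"), 5, 1)
  s <- cohortRibSummary(co)
  expect_equal(s$n_rib_measured, 5)
  expect_equal(s$prop_absent, 0)
  expect_equal(s$mean_L_C, 2.7, tolerance = 0.02)

  # drop one fifth-left rib by hand: mean over the remaining four
  co2 <- co
  rb <- ribs(co2[[2]])
  k <- which(vapply(rb, function(r) r@side == "left" && r@index == 5, logical(1)))
  rb[[k]] <- Rib("left", 5)
  co2[[2]] <- Specimen(co2[[2]]@spine, rb)
  s2 <- cohortRibSummary(co2)
  expect_equal(s2$n_rib_measured, 4)
  expect_equal(s2$prop_absent, 0.2)
  expect_false(is.na(s2$mean_L_C))

  one <- cohortRibSummary(co[1])
  expect_true(is.na(one$sd_L_C))
  expect_error(cohortRibSummary(list()), "empty group")
})

test_that("rib spacing statistic reflects geometry and is finite", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  sp <- generateSpine(cfg, 1)
  spn <- Specimen(sp, generateRibs(cfg, sp, 1))
  expect_true(is.finite(ribSpacingStat(spn)))
  expect_gt(ribSpacingStat(spn), 0.1)
})
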