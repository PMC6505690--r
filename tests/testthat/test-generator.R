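test_that("default configurations encode the study groups", {
  ctl <- defaultConfig(9, "control")
  expect_equal(nrow(ctl@wedgePlan), 0)
  expect_equal(length(ctl@fusionPlan), 0)
  expect_equal(nrow(ctl@deformities), 0)
  expect_true(all(ctl@ribPlan$present))

  im4 <- defaultConfig(9, "Im4")
  expect_equal(nrow(im4@wedgePlan), 8)
  expect_true(all(im4@wedgePlan$angle_deg > 10))

  im5 <- defaultConfig(9, "Im5")
  lc5 <- im5@ribPlan$targetLc[im5@ribPlan$side == "left" & im5@ribPlan$index == 5]
  expect_equal(lc5, 1.7)
  expect_equal(im5@absentNum, 5L)
  expect_equal(im5@absentDen, 6L)

  expect_equal(defaultConfig("E7", "Im4")@stage, 7L)
  expect_error(defaultConfig(4, "control"), "unknown stage")
  expect_error(defaultConfig(9, "Im7"), "unknown group")
})

test_that("spine generation is deterministic and hits its targets exactly", {
  cfg <- defaultConfig(9, "control")
  a <- generateSpine(cfg, 7)
  b <- generateSpine(cfg, 7)
  expect_identical(vertebrae(a), vertebrae(b))
  c <- generateSpine(cfg, 8)
  expect_false(identical(vertebrae(a), vertebrae(c)))

  expect_equal(spineHeight(generateSpine(noiseFree(defaultConfig(6, "control")), 1)),
               6.2, tolerance = 1e-12)
  expect_equal(spineHeight(generateSpine(noiseFree(defaultConfig(9, "control")), 1)),
               10.9, tolerance = 1e-12)
  # immobilised height deficit at late stages
  expect_lt(defaultConfig(9, "Im4")@targetHeightMm, 10.9)

  bad <- defaultConfig(9, "control")
  bad@deformities <- data.frame(label = "Q9", amp = 0.3, width = 1.5,
                                sign = "kyphotic", stringsAsFactors = FALSE)
  expect_error(generateSpine(bad, 1), "invalid deformity location")
})

test_that("generated spines satisfy the landmark invariants", {
  for (grp in c("control", "Im3", "Im4")) {
    sp <- generateSpine(defaultConfig(9, grp), 3)
    v <- vertebrae(sp)
    expect_equal(nrow(v), 28)
    expect_false(anyDuplicated(v$label) > 0)
    # centre lies between the endplate midpoints along the spine axis
    supY <- (v$sy1 + v$sy2) / 2
    infY <- (v$iy1 + v$iy2) / 2
    expect_true(all(supY > v$cy - 1e-6))
    expect_true(all(infY < v$cy + 1e-6))
  }
})

test_that("generated ribs respect length, waviness and laterality", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  sp <- generateSpine(cfg, 1)
  rbs <- generateRibs(cfg, sp, 1)
  expect_length(rbs, 14)
  plan <- cfg@ribPlan
  for (k in seq_along(rbs)) {
    r <- rbs[[k]]
    expect_true(r@present)
    expect_equal(arcLength(r@centerline), plan$targetLc[k], tolerance = 0.005)
    zspan <- mean(r@centerline[, 3]) - vertebrae(sp)$cz[1]
    if (r@side == "left") expect_gt(zspan, 0) else expect_lt(zspan, 0)
  }
  # zero waviness amplitude gives a smooth arc with no inflections
  cfg0 <- cfg; cfg0@ribPlan$wavAmp <- 0
  r5 <- fifthLeftRib(Specimen(sp, generateRibs(cfg0, sp, 1)))
  expect_equal(countInflections(r5@centerline), 0)
  expect_equal(ribMetrics(r5)$ICM, 0)
  # ribs absent before E6
  early <- generateRibs(defaultConfig(5, "control"),
                        generateSpine(defaultConfig(5, "control"), 1), 1)
  expect_true(all(!vapply(early, slot, logical(1), name = "present")))
})

test_that("cohorts are reproducible and calibrated", {
  cfg <- defaultConfig(9, "control")
  co1 <- generateCohort(cfg, 4, 11)
  co2 <- generateCohort(cfg, 4, 11)
  expect_identical(lapply(co1, vertebrae), lapply(co2, vertebrae))
  expect_identical(lapply(co1, function(s) fifthLeftRib(s)@centerline),
                   lapply(co2, function(s) fifthLeftRib(s)@centerline))

  single <- generateCohort(cfg, 1, 5)
  expect_length(single, 1)

  # cohort means sit on the calibration targets
  co <- generateCohort(cfg, 10, 1)
  heights <- vapply(co, spineHeight, numeric(1))
  expect_equal(mean(heights), 10.9, tolerance = 0.05)
  expect_gt(sd(heights), 0.2)  # between-specimen spread is real

  lc <- vapply(co, function(s) ribMetrics(fifthLeftRib(s))$L_C_mm, numeric(1))
  expect_equal(mean(lc), 2.7, tolerance = 0.03)
  expect_equal(sd(lc), 0.36, tolerance = 0.1)

  co7 <- generateCohort(defaultConfig(7, "Im4"), 10, 1)
  wed <- vapply(co7, function(s) nWedged(classifyVertebrae(s)), numeric(1))
  expect_equal(mean(wed), 2.8, tolerance = 0.15)
  expect_gt(sd(wed), 0.8)
})

test_that("absent-rib planting follows the deterministic seed-order rule", {
  co6 <- generateCohort(defaultConfig(9, "Im5"), 6, 1)
  flags <- vapply(co6, function(s) ribCensus(s)$hasAbsent, logical(1))
  expect_equal(sum(flags), 5)
  expect_false(flags[6])  # the sixth specimen is the intact one

  # fifth left rib is never removed (kept measurable across the cohort)
  for (s in co6) expect_true(fifthLeftRib(s)@present)

  # controls never lose ribs
  ctl <- generateCohort(defaultConfig(9, "control"), 6, 1)
  expect_false(any(vapply(ctl, function(s) ribCensus(s)$hasAbsent, logical(1))))
})
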