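test_that("wedge angle matches analytic endplate configurations", {
  mk <- function(dir, at = c(0, 0, 0)) rbind(at - dir, at + dir)
  flat <- c(1, 0, 0)
  expect_equal(wedgeAngle(mk(flat, c(0, 0.5, 0)), mk(flat, c(0, -0.5, 0))), 0)
  for (th in c(15, 37, 90)) {
    tilted <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
    expect_equal(wedgeAngle(mk(tilted, c(0, 0.5, 0)), mk(flat, c(0, -0.5, 0))),
                 th, tolerance = 1e-9)
  }
  # orientation of the endpoint pair does not matter (absolute cosine)
  rev15 <- mk(-c(cos(15 * pi / 180), sin(15 * pi / 180), 0), c(0, 0.5, 0))
  expect_equal(wedgeAngle(rev15, mk(flat, c(0, -0.5, 0))), 15, tolerance = 1e-9)
  expect_error(wedgeAngle(rbind(c(0, 0, 0), c(0, 0, 0)), mk(flat)),
               "degenerate endplate")
})

test_that("wedged means strictly greater than the 10-degree threshold", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  cfg@wedgePlan <- data.frame(label = "T3", angle_deg = 10,
                              stringsAsFactors = FALSE)
  rep10 <- classifyVertebrae(generateSpine(cfg, 1))
  expect_equal(nWedged(rep10), 0)
  rec <- wedgeRecords(rep10)
  expect_equal(rec$angle_deg[rec$label == "T3"], 10, tolerance = 1e-6)

  cfg@wedgePlan$angle_deg <- 10.05
  expect_equal(nWedged(classifyVertebrae(generateSpine(cfg, 1))), 1)
})

test_that("planted wedges are recovered exactly without noise", {
  cfg <- noiseFree(defaultConfig(9, "Im4"))
  wr <- classifyVertebrae(generateSpine(cfg, 1))
  expect_equal(nWedged(wr), 8)
  rec <- wedgeRecords(wr)
  expect_setequal(rec$label[rec$wedged], cfg@wedgePlan$label)
  # planted angles are read back to numerical precision
  got <- rec$angle_deg[match(cfg@wedgePlan$label, rec$label)]
  expect_equal(got, cfg@wedgePlan$angle_deg, tolerance = 1e-6)

  ctl <- classifyVertebrae(generateSpine(noiseFree(defaultConfig(9, "control")), 1))
  expect_equal(nWedged(ctl), 0)
  expect_equal(nFused(ctl), 0)
  expect_equal(nAbnormal(ctl), 0)
})

test_that("wedge recovery stays accurate under landmark noise", {
  cfg <- defaultConfig(9, "Im4")
  cfg@noiseSd <- 0.01
  cfg@wedgePlan <- data.frame(label = cfg@wedgePlan$label,
                              angle_deg = rep(16, 8),
                              stringsAsFactors = FALSE)
  f1 <- vapply(1:20, function(s) {
    rec <- wedgeRecords(classifyVertebrae(generateSpine(cfg, s)))
    called <- rec$label[rec$wedged]
    tp <- sum(called %in% cfg@wedgePlan$label)
    fp <- length(called) - tp
    fn <- nrow(cfg@wedgePlan) - tp
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("wedged count is non-increasing in the threshold", {
  cfg <- defaultConfig(9, "Im4")
  sp <- generateSpine(cfg, 5)
  counts <- vapply(c(5, 10, 14, 17, 25), function(th)
    nWedged(classifyVertebrae(sp, threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fusion is detected from overlapping endplates and annotation", {
  cfg <- noiseFree(defaultConfig(9, "Im3"))  # one planted cervical fusion pair
  wr <- classifyVertebrae(generateSpine(cfg, 1))
  expect_equal(nFused(wr), 2)  # both members of the pair
  rec <- wedgeRecords(wr)
  expect_setequal(rec$label[rec$fused], c("C13", "C14"))
  expect_equal(nAbnormal(wr), nWedged(wr) + 2)

  # annotation alone (no geometric overlap) also marks the pair
  sp <- generateSpine(noiseFree(defaultConfig(9, "control")), 1)
  v <- vertebrae(sp)
  v$fusedWithNext[v$label == "L2"] <- TRUE
  wr2 <- classifyVertebrae(Spine("x", 9, "control", v))
  rec2 <- wedgeRecords(wr2)
  expect_setequal(rec2$label[rec2$fused], c("L2", "L3"))
})

test_that("cohort abnormal summaries use sample SDs", {
  cfg <- noiseFree(defaultConfig(9, "control"))
  mkRep <- function(k, id) {
    c2 <- cfg
    c2@wedgePlan <- data.frame(label = paste0("T", seq_len(k) + 1),
                               angle_deg = rep(15, k), stringsAsFactors = FALSE)
    classifyVertebrae(generateSpine(c2, 1, id = id))
  }
  two <- cohortAbnormalSummary(list(mkRep(2, "a"), mkRep(4, "b")))
  expect_equal(two$mean_wedged, 3)
  expect_equal(two$sd_wedged, sqrt(2))

  one <- cohortAbnormalSummary(list(mkRep(2, "a")))
  expect_true(is.na(one$sd_wedged))

  same <- cohortAbnormalSummary(list(mkRep(3, "a"), mkRep(3, "b"), mkRep(3, "c")))
  expect_equal(same$sd_wedged, 0)
  expect_error(cohortAbnormalSummary(list()), "empty cohort")
})
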