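test_that("the calibration filter reproduces the worked coefficient set", {
  # pool {-0.10, 0.20, 0.50, 0.80}: the negative goes, the mean +/- 2 SD
  # pass (mean 0.5, SD 0.3 -> bounds [-0.1, 1.1]) removes nothing
  cal <- calibrateFromCoeffs(c(-0.10, 0.20, 0.50, 0.80))
  expect_equal(sort(retainedCoeffs(cal)), c(0.20, 0.50, 0.80))
  expect_equal(baselineR(cal), 0.20)
  expect_equal(maxR(cal), 0.80)
  expect_equal(cal@nRemovedNegative, 1L)
  expect_equal(cal@nRemovedOutlier, 0L)
})

test_that("an all-negative pool raises a calibration failure", {
  expect_error(calibrateFromCoeffs(c(-0.4, -0.1, -0.05)),
               class = "calibrationFailure")
  expect_error(calibrateFromCoeffs(c(0.5, 0.5, 0.5)),
               class = "calibrationFailure")  # baseline == max
})

test_that("the outlier pass removes extreme coefficients", {
  # 12 tight values plus one far outlier: SD of the 13 is ~0.26, so only
  # 0.99 is beyond mean + 2 SD
  pool <- c(rep(c(0.10, 0.12, 0.14), 4), 0.99)
  cal <- calibrateFromCoeffs(pool)
  expect_equal(cal@nRemovedOutlier, 1L)
  expect_lt(maxR(cal), 0.99)
})

test_that("calibration filtering is idempotent (single-pass convention)", {
  set.seed(11)
  for (i in 1:20) {
    pool <- runif(40, -0.3, 1)
    cal <- tryCatch(calibrateFromCoeffs(pool),
                    calibrationFailure = function(e) NULL)
    if (is.null(cal)) next
    again <- calibrateFromCoeffs(retainedCoeffs(cal))
    expect_equal(sort(retainedCoeffs(again)), sort(retainedCoeffs(cal)))
    expect_equal(again@nRemovedNegative + again@nRemovedOutlier, 0L)
  }
})

test_that("localizer task blocks contribute 11 windows each (66 pooled)", {
  loc <- makeLocalizerDesign()
  ts <- simulateRun(loc, SimParams(couplingRegulate = 0.9, seed = 21))
  cal <- calibrate(ts, loc, windowLen = 20L)
  # noisy run: no degenerate windows, so retained + removed = (30-20+1)*6
  expect_equal(length(retainedCoeffs(cal)) + cal@nRemovedNegative +
                 cal@nRemovedOutlier, 66L)
})

test_that("windows never straddle a task-block boundary", {
  # make REST samples constant so any window touching REST would be
  # degenerate or wildly different; within-task windows must all be defined
  loc <- makeLocalizerDesign()
  ts <- simulateRun(loc, SimParams(couplingRegulate = 0.9, seed = 22))
  m <- boldMatrix(ts)
  labs <- labelsPerTr(loc)
  m[labs == "REST", ] <- 0
  tsMasked <- RoiTimeSeries(m, design = loc)
  cal <- calibrate(tsMasked, loc, windowLen = 20L)
  calRef <- calibrate(ts, loc, windowLen = 20L)
  # zeroing REST cannot change task-only windows
  expect_equal(sort(retainedCoeffs(cal)), sort(retainedCoeffs(calRef)))
})

test_that("calibrated ranges are plausible for responder localizers", {
  res <- t(vapply(1:50, function(s) {
    p <- simulateParticipant("responder", seed = s)
    cal <- calibrate(p$localizer, makeLocalizerDesign())
    c(baselineR(cal), maxR(cal))
  }, numeric(2)))
  expect_gte(mean(res[, 1L] >= 0 & res[, 1L] <= 0.54), 0.8)
  expect_gte(mean(res[, 2L] >= 0.38 & res[, 2L] <= 0.99), 0.8)
})

test_that("the fallback calibration supplies the group-mean range with a warning", {
  expect_warning(cal <- fallbackCalibration(), "group-default")
  expect_equal(baselineR(cal), 0.17)
  expect_equal(maxR(cal), 0.81)
})

test_that("calibration results round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  cal <- calibrateFromCoeffs(c(0.2, 0.35, 0.5, 0.81))
  writeCalibration(cal, p)
  cal2 <- readCalibration(p)
  expect_equal(retainedCoeffs(cal2), retainedCoeffs(cal))
  expect_equal(baselineR(cal2), baselineR(cal))
  expect_equal(maxR(cal2), maxR(cal))
  writeLines("{\"baseline_r\": 0.1}", p)
  expect_error(readCalibration(p), "missing field")
})
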