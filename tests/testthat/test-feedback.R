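test_that("gauge scaling matches the published boundary behaviour", {
  calib <- meanCalib()  # baseline 0.17, max 0.81
  expect_identical(scaleToLines(0.95, calib), 10L)  # scaled 12.19, clamped
  expect_identical(scaleToLines(0.05, calib), 0L)   # scaled -1.875, clamped
  expect_identical(scaleToLines(0.49, calib), 5L)   # 0.32/0.64 * 10 = 5.0
  expect_identical(scaleToLines(NA_real_, calib), 0L)
  expect_error(scaleToLines(0.5, calibrateFromCoeffs(c(0.3, 0.3, 0.31))),
               NA)
  badCal <- new("CalibrationResult", retainedCoeffs = c(0.2, 0.4),
                baselineR = 0.4, maxR = 0.4, nRemovedNegative = 0L,
                nRemovedOutlier = 0L)
  expect_error(scaleToLines(0.5, badCal), "degenerate")
})

test_that("gauge lines are non-decreasing in the raw correlation", {
  calib <- meanCalib()
  grid <- seq(-1, 1, by = 0.001)
  lines <- scaleToLines(grid, calib)
  expect_true(all(diff(lines) >= 0))
  expect_true(all(lines >= 0L & lines <= 10L))
})

test_that("the streaming engine warms up for 19 samples then matches the batch window", {
  nf <- makeNfDesign()
  ts <- simulateRun(nf, SimParams(seed = 31))
  m <- boldMatrix(ts)
  calib <- meanCalib()

  state <- newFeedbackState(calib, nf, windowLen = 20L)
  frames <- vector("list", 25L)
  for (i in 1:25) {
    out <- feedbackStep(state, m[i, ])
    state <- out$state
    frames[[i]] <- out$frame
  }
  fr <- do.call(rbind, frames)
  expect_true(all(fr$warmup[1:19]))
  expect_true(all(fr$lines[1:19] == 0L))
  expect_false(any(fr$warmup[20:25]))

  w <- windowValues(windowedPartialCorr(ts, 20L))
  expect_identical(fr$rawR[20:25], w[1:6])

  expect_error(feedbackStep(state, c(1, NA, 3)), "non-missing")
})

test_that("batch replay emits one frame per TR with the display rules applied", {
  nf <- makeNfDesign()
  ts <- simulateRun(nf, SimParams(seed = 32))
  trace <- runFeedback(ts, nf, meanCalib())
  fr <- frames(trace)
  expect_equal(nrow(fr), 420L)
  labs <- labelsPerTr(nf)
  expect_true(all(!fr$shown[labs == "REST"]))
  expect_true(all(fr$shown[labs == "REGULATE"]))
  expect_equal(provenance(trace), "veridical")

  expect_error(runFeedback(RoiTimeSeries(boldMatrix(ts)[1:100, ], trS = 1),
                           nf, meanCalib()),
               "does not match")
})

test_that("a noise-free fully coupled run pins the gauge at 10", {
  nf <- makeNfDesign()
  p <- SimParams(taskAmp = 0, couplingRest = 1, couplingRegulate = 1,
                 globalAmp = 0, noiseSd = 0, driftPerMin = 0, seed = 1)
  fr <- frames(runFeedback(simulateRun(nf, p), nf, meanCalib()))
  sel <- fr$shown & !fr$warmup
  expect_true(all(fr$lines[sel] == 10L))
})

test_that("yoked traces replay the source display exactly and refuse re-yoking", {
  nf <- makeNfDesign()
  src <- runFeedback(simulateRun(nf, SimParams(seed = 33)), nf, meanCalib(),
                     runId = "eg_run1")
  sham <- yokedTrace(src, runId = "cg_run1")
  expect_identical(frames(sham)$lines, frames(src)$lines)
  expect_identical(frames(sham)$shown, frames(src)$shown)
  expect_equal(length(sham), 420L)
  expect_equal(provenance(sham), "yoked:eg_run1")
  expect_error(yokedTrace(sham), "second-generation")
})

test_that("responders earn more gauge lines than non-responders at matched seeds", {
  loc <- makeLocalizerDesign(); nf <- makeNfDesign()
  meanLines <- function(scenario, s) {
    p <- simulateParticipant(scenario, seed = s)
    cal <- calibrate(p$localizer, loc)
    mean(vapply(p$nfRuns, function(run) {
      fr <- frames(runFeedback(run, nf, cal))
      mean(fr$lines[fr$shown & !fr$warmup])
    }, numeric(1)))
  }
  wins <- vapply(1:50, function(s)
    meanLines("responder", s) > meanLines("non_responder", s), logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("feedback traces round-trip through the text format", {
  nf <- makeNfDesign()
  trace <- runFeedback(simulateRun(nf, SimParams(seed = 34)), nf,
                       meanCalib(), runId = "rt1")
  p <- withr::local_tempfile(fileext = ".tsv")
  writeFeedbackTrace(trace, p)
  t2 <- readFeedbackTrace(p)
  expect_identical(frames(t2)$lines, frames(trace)$lines)
  expect_identical(frames(t2)$shown, frames(trace)$shown)
  expect_identical(frames(t2)$warmup, frames(trace)$warmup)
  expect_equal(frames(t2)$rawR, frames(trace)$rawR, tolerance = 1e-9)
  expect_equal(runId(t2), "rt1")
  expect_equal(provenance(t2), provenance(trace))
})
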