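test_that("gamma HRF kernel has the stated mean lag, mode and normalization", {
  # shape k = (mean/sd)^2 = 4, scale = sd^2/mean = 1.5; mean = k * scale
  k <- 4; theta <- 1.5
  expect_equal(k * theta, 6)

  fine <- gammaHrf(6, 3, 0.1)
  # mode of the underlying gamma at (k - 1) * theta = 4.5 s
  expect_lt(abs((which.max(fine) - 1L) * 0.1 - 4.5), 0.1 + 1e-9)

  for (kern in list(gammaHrf(6, 3, 1), fine, gammaHrf(5, 2, 0.5))) {
    expect_true(all(kern >= 0))
    expect_equal(max(kern), 1)
  }
  expect_error(gammaHrf(-6, 3, 1), "positive")
  expect_error(gammaHrf(6, 0, 1), "positive")
})

test_that("simulation is bit-identical under a fixed seed", {
  nf <- makeNfDesign()
  p <- SimParams(seed = 42)
  expect_identical(boldMatrix(simulateRun(nf, p)),
                   boldMatrix(simulateRun(nf, p)))
  expect_false(identical(boldMatrix(simulateRun(nf, SimParams(seed = 43))),
                         boldMatrix(simulateRun(nf, p))))
})

test_that("a noise-free fully coupled run has identical targets and unit windowed r", {
  nf <- makeNfDesign()
  p <- SimParams(taskAmp = 0, couplingRest = 1, couplingRegulate = 1,
                 globalAmp = 0, noiseSd = 0, driftPerMin = 0, seed = 1)
  m <- boldMatrix(simulateRun(nf, p))
  expect_equal(m[, "dlpfc"], m[, "acc"], tolerance = 1e-12)
  w <- windowValues(windowedPartialCorr(simulateRun(nf, p)))
  expect_true(all(abs(w - 1) < 1e-9))
})

test_that("windowed partial correlation is centred on zero for pure noise", {
  nf <- makeNfDesign()
  means <- vapply(1:200, function(s) {
    p <- SimParams(taskAmp = 0, globalAmp = 0, couplingRest = 0,
                   couplingRegulate = 0, driftPerMin = 0, seed = s)
    mean(windowValues(windowedPartialCorr(simulateRun(nf, p))), na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("the partial-vs-raw correlation gap grows with the global amplitude", {
  nf <- makeNfDesign()
  gap <- vapply(c(0.4, 0.8, 1.2), function(ga) {
    mean(vapply(1:30, function(s) {
      ts <- simulateRun(nf, SimParams(taskAmp = 0, globalAmp = ga,
                                      couplingRest = 0, couplingRegulate = 0,
                                      seed = s))
      m <- boldMatrix(ts)
      w <- windowValues(windowedPartialCorr(ts))
      raw <- vapply(seq_along(w), function(st)
        cor(m[st:(st + 19L), 1L], m[st:(st + 19L), 2L]), numeric(1))
      mean(raw) - mean(w, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("participant scenarios emit one localizer and four nf runs with the right coupling schedules", {
  resp <- simulateParticipant("responder", seed = 7)
  expect_length(resp$nfRuns, 4L)
  expect_equal(nSamples(resp$localizer), 360L)
  expect_true(all(vapply(resp$nfRuns, nSamples, integer(1)) == 420L))

  coupOf <- function(run)
    S4Vectors::metadata(run)$provenance$params$couplingRegulate
  respCoup <- vapply(resp$nfRuns, coupOf, numeric(1))
  expect_gt(respCoup[4L], respCoup[1L])
  expect_true(all(diff(respCoup[1:3]) > 0))

  nonr <- simulateParticipant("non_responder", seed = 7)
  nonrCoup <- vapply(nonr$nfRuns, coupOf, numeric(1))
  expect_true(all(nonrCoup == nonrCoup[1L]))

  expect_error(simulateParticipant("sleeper", seed = 1), "scenario")
})
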