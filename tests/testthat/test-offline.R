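test_that("NF-signal percent change is relative to the localizer reference", {
  calib <- calibrateFromCoeffs(c(0.4, 0.6))  # reference mean 0.5
  expect_equal(nfSignalTimecourse(list(makeConstantTrace(0.5)),
                                  calib)$percentChange, 0)
  tc <- nfSignalTimecourse(list(makeConstantTrace(0.6, "r1"),
                                makeConstantTrace(0.45, "r2")), calib)
  expect_equal(tc$percentChange, c(20, -10))
  expect_equal(tc$runId, c("r1", "r2"))
  expect_equal(tc$localizerRefR, c(0.5, 0.5))

  # a run with no defined post-warmup REGULATE coefficients is an error
  expect_error(nfSignalTimecourse(list(makeConstantTrace(NA_real_)), calib),
               "no defined")
})

test_that("responder percent change rises over runs 1-3 and the shape allows a run-4 dip", {
  loc <- makeLocalizerDesign(); nf <- makeNfDesign()
  pc <- t(vapply(1:30, function(s) {
    p <- simulateParticipant("responder", seed = s)
    cal <- calibrate(p$localizer, loc)
    traces <- lapply(seq_along(p$nfRuns), function(r)
      runFeedback(p$nfRuns[[r]], nf, cal, runId = paste0("run", r)))
    nfSignalTimecourse(traces, cal)$percentChange
  }, numeric(4)))
  avg <- colMeans(pc)
  expect_true(all(diff(avg[1:3]) > 0))
  expect_lt(avg[4L], avg[3L])
})

test_that("block regressors are causal, HRF-lagged and run-length", {
  nf <- makeNfDesign()
  reg <- buildRegressor(nf, "REGULATE", gammaHrf(6, 3, 1))
  expect_length(reg, 420L)
  # nothing before the first REGULATE onset at 25 s
  expect_true(all(abs(reg[1:25]) < 1e-9))
  # half-peak time of the first response lags onset by a few seconds
  firstBlock <- reg[26:70]
  halfUp <- which(firstBlock >= 0.5 * max(firstBlock))[1L]
  expect_gte(halfUp, 3); expect_lte(halfUp, 8)
  expect_error(buildRegressor(nf, "TASK"), "not present")
})

test_that("OLS recovers exact coefficients without noise and matches the normal equations with it", {
  set.seed(71)
  X <- cbind(intercept = 1, a = rnorm(60), b = rnorm(60))
  b <- c(2, -1.5, 0.25)
  fit <- glmFit(as.numeric(X %*% b), X)
  expect_lt(max(abs(fit$coefficients$beta - b)), 1e-10)

  for (i in 1:200) {
    n <- sample(20:80, 1L)
    X <- cbind(1, matrix(rnorm(n * 3L), ncol = 3L))
    colnames(X) <- c("intercept", "a", "b", "c")
    y <- X %*% rnorm(4L) + rnorm(n)
    fit <- glmFit(y, X)
    expect_lt(max(abs(fit$coefficients$beta -
                        normalEquationsBeta(y, X))), 1e-8)
  }
})

test_that("rank-deficient design matrices are rejected with the collinear column named", {
  set.seed(72)
  x <- rnorm(30)
  X <- cbind(intercept = 1, a = x, dup = x)
  expect_error(glmFit(rnorm(30), X), "dup")
  expect_error(glmFit(rnorm(30), X), class = "rankDeficient")
})

test_that("the PPI interaction beta vanishes for a noise-free unmodulated run", {
  nf <- makeNfDesign()
  p <- SimParams(taskAmp = 0, couplingRest = 0.5, couplingRegulate = 0.5,
                 globalAmp = 0.8, noiseSd = 0, driftPerMin = 0.2, seed = 5)
  res <- ppiFirstLevel(simulateRun(nf, p), nf)
  expect_lt(abs(res@coefficients["interaction", "beta"]), 1e-8)
  expect_gt(res@residualDf, 0)

  # constant seed is rejected
  flat <- SimParams(taskAmp = 0, couplingRest = 0, couplingRegulate = 0,
                    globalAmp = 0, noiseSd = 0, driftPerMin = 0, seed = 1)
  expect_error(ppiFirstLevel(simulateRun(nf, flat), nf), "constant seed")
})

test_that("the mean PPI interaction beta is monotone in the coupling modulation", {
  nf <- makeNfDesign()
  means <- vapply(c(0.3, 0.9, 1.5), function(cp) {
    mean(vapply(1:50, function(s) {
      ts <- simulateRun(nf, SimParams(couplingRegulate = cp, seed = s))
      ppiFirstLevel(ts, nf)@coefficients["interaction", "beta"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("run contrasts propagate variance and demand matching designs", {
  nf <- makeNfDesign()
  r1 <- ppiFirstLevel(simulateRun(nf, SimParams(seed = 81)), nf)
  self <- runContrast(r1, r1)
  expect_equal(self$estimate, 0)
  expect_equal(self$se, sqrt(2) * r1@coefficients["interaction", "se"])

  alt <- BlockDesign(rep(c("REST", "REGULATE"), 6L), rep(c(30, 40), 6L))
  other <- ppiFirstLevel(simulateRun(alt, SimParams(seed = 81)), alt)
  expect_error(runContrast(r1, other), "different designs")
})

test_that("run 1 vs 4 contrasts separate responders from non-responders on average", {
  nf <- makeNfDesign()
  est <- function(scenario, s) {
    p <- simulateParticipant(scenario, seed = s)
    runContrast(ppiFirstLevel(p$nfRuns[[1L]], nf),
                ppiFirstLevel(p$nfRuns[[4L]], nf))$estimate
  }
  resp <- vapply(1:50, function(s) est("responder", s), numeric(1))
  nonr <- vapply(1:50, function(s) est("non_responder", s), numeric(1))
  expect_gt(mean(resp), 0)
  # non-responder mean contrast is statistically indistinguishable from 0
  expect_gt(stats::t.test(nonr)$p.value, 0.05)
})

test_that("PPI results round-trip through JSON", {
  nf <- makeNfDesign()
  res <- ppiFirstLevel(simulateRun(nf, SimParams(seed = 91)), nf)
  p <- withr::local_tempfile(fileext = ".json")
  writePpiResult(res, p)
  res2 <- readPpiResult(p)
  expect_equal(res2@coefficients, res@coefficients)
  expect_equal(res2@residualDf, res@residualDf)
  expect_equal(res2@designDigest, res@designDigest)
})
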