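# Shared fixtures built in code.

# The group-mean calibration range reported for the protocol.
meanCalib <- function() calibrateFromCoeffs(c(0.17, 0.81))

# Residual-regression oracle for the first-order partial correlation:
# correlate the residuals of x ~ z and y ~ z.
residualOracle <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Normal-equations oracle for OLS.
normalEquationsBeta <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# A FeedbackTrace with prescribed rawR values on shown frames, for
# exercising the NF-signal summary without a simulation.
makeConstantTrace <- function(rawShown, runId = "run") {
  design <- makeNfDesign()
  labs <- labelsPerTr(design)
  n <- length(labs)
  warmup <- seq_len(n) < 20L
  rawR <- ifelse(warmup, NA_real_, rawShown)
  calib <- meanCalib()
  scaled <- (rawR - baselineR(calib)) / (maxR(calib) - baselineR(calib)) * 10
  lines <- ifelse(is.na(rawR), 0L, scaleToLines(rawR, calib))
  new("FeedbackTrace",
      frames = S4Vectors::DataFrame(
        tIndex = seq_len(n) - 1L, rawR = rawR,
        scaled = ifelse(is.na(rawR), NA_real_, scaled),
        lines = lines, shown = labs == "REGULATE", warmup = warmup),
      runId = runId,
      calibrationRef = "test", designRef = "test",
      provenance = "veridical")
}

# Mean windowed partial correlation over post-warm-up REGULATE samples.
meanRegulateR <- function(ts, design, windowLen = 20L) {
  labs <- labelsPerTr(design)
  w <- windowValues(windowedPartialCorr(ts, windowLen))
  ends <- seq(windowLen, nSamples(design))
  mean(w[labs[ends] == "REGULATE"], na.rm = TRUE)
}
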