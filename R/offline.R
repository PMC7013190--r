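# Offline analyses: neurofeedback-signal time course across runs and a
# simplified single-subject first-level PPI model.

#' Neurofeedback-signal time course across runs
#'
#' For each run, the mean of the defined post-warm-up REGULATE-block
#' windowed partial correlations is expressed as a percentage change
#' relative to the localizer reference connectivity (the mean of the
#' calibration's retained localizer coefficients):
#' \code{100 * (meanRegulateR - localizerRefR) / localizerRefR}.
#'
#' @param traces list of \linkS4class{FeedbackTrace} objects, in run
#'   order.
#' @param calibLocalizer the localizer \linkS4class{CalibrationResult};
#'   its retained-coefficient mean is the reference.
#' @return data.frame with one row per run and columns \code{runId},
#'   \code{meanRegulateR}, \code{localizerRefR}, \code{percentChange}.
#' @examples
#' calib <- calibrateFromCoeffs(c(0.3, 0.5, 0.7))
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 11))
#' tr <- runFeedback(ts, makeNfDesign(), calib)
#' nfSignalTimecourse(list(tr), calib)
#' @export
nfSignalTimecourse <- function(traces, calibLocalizer) {
  stopifnot(is(calibLocalizer, "CalibrationResult"))
  refR <- mean(calibLocalizer@retainedCoeffs)
  if (refR == 0)
    nfStop("invalidArgument",
           "localizer reference connectivity is zero; percent change undefined")
  rows <- lapply(traces, function(tr) {
    stopifnot(is(tr, "FeedbackTrace"))
    fr <- tr@frames
    use <- fr$shown & !fr$warmup & !is.na(fr$rawR)
    if (!any(use))
      nfStop("invalidArgument", sprintf(
        "run %s has no defined post-warmup REGULATE coefficients", tr@runId))
    meanR <- mean(fr$rawR[use])
    data.frame(runId = tr@runId,
               meanRegulateR = meanR,
               localizerRefR = refR,
               percentChange = 100 * (meanR - refR) / refR,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build an HRF-convolved block regressor
#'
#' Boxcar of the labelled blocks (1 inside, 0 elsewhere) convolved with
#' the supplied HRF kernel and truncated to the run length.
#'
#' @param design a \linkS4class{BlockDesign}.
#' @param label block label to model (must occur in the design).
#' @param hrfKernel convolution kernel, e.g. \code{\link{gammaHrf}()}.
#' @return Numeric regressor of length \code{nSamples(design)}.
#' @examples
#' reg <- buildRegressor(makeNfDesign(), "REGULATE", gammaHrf())
#' length(reg)
#' @export
buildRegressor <- function(design, label, hrfKernel = gammaHrf(6, 3, trS(design))) {
  stopifnot(is(design, "BlockDesign"))
  labels <- labelsPerTr(design)
  if (!label %in% design@labels)
    nfStop("invalidArgument", paste("label not present in design:", label))
  boxcar <- as.numeric(labels == label)
  convolveCausal(boxcar, hrfKernel)
}

#' Ordinary least squares with t-statistics
#'
#' Plain OLS fit (no prewhitening or autocorrelation correction): betas,
#' residual-variance-based standard errors and t-statistics. Design
#' matrices that are not of full column rank are rejected with the
#' offending columns named.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with \code{nrow(X) == length(y)};
#'   column names are used in outputs and error messages.
#' @return List with \code{coefficients} (data.frame: beta, se, t),
#'   \code{residualDf}, \code{sigma2} and \code{conditionNumber}.
#' @examples
#' X <- cbind(intercept = 1, x = rnorm(50))
#' glmFit(X %*% c(2, 3) + rnorm(50), X)$coefficients
#' @export
glmFit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    nfStop("invalidArgument", "rows of X must match length of y")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    nfStop("rankDeficient", paste(
      "design matrix is rank deficient; collinear column(s):",
      paste(bad, collapse = ", ")))
  }
  n <- length(y); p <- ncol(X)
  df <- n - p
  if (df <= 0)
    nfStop("invalidArgument", "no residual degrees of freedom")
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- ifelse(se > 0, beta / se, NA_real_)
  sv <- svd(X, nu = 0, nv = 0)$d
  list(coefficients = data.frame(beta = as.numeric(beta),
                                 se = as.numeric(se),
                                 t = as.numeric(tstat),
                                 row.names = colnames(X)),
       residualDf = df,
       sigma2 = sigma2,
       conditionNumber = max(sv) / min(sv))
}

#' Simplified first-level PPI model of one neurofeedback run
#'
#' Fits the ACC time series on an intercept, the HRF-convolved REGULATE
#' regressor, the mean-centred DLPFC seed time series, and the
#' psychophysiological interaction: seed times the zero-centred
#' (+0.5 REGULATE / -0.5 REST) condition boxcar. The interaction
#' t-statistic tests whether seed-target coupling differs between
#' Regulate and Rest.
#'
#' @param ts \linkS4class{RoiTimeSeries} of the run.
#' @param design the run's \linkS4class{BlockDesign} (REGULATE blocks).
#' @return A \linkS4class{PpiResult}.
#' @examples
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 8))
#' ppiFirstLevel(ts, makeNfDesign())
#' @export
ppiFirstLevel <- function(ts, design) {
  stopifnot(is(design, "BlockDesign"))
  m <- boldMatrix(ts)
  if (nrow(m) != nSamples(design))
    nfStop("invalidArgument", "time series length does not match design")
  seed <- m[, "dlpfc"]
  if (sd(seed) == 0)
    nfStop("invalidArgument", "constant seed series: PPI undefined")
  seedC <- seed - mean(seed)
  psych <- ifelse(labelsPerTr(design) == "REGULATE", 0.5, -0.5)
  X <- cbind(intercept = 1,
             task = buildRegressor(design, "REGULATE",
                                   gammaHrf(6, 3, trS(design))),
             seed = seedC,
             interaction = seedC * psych)
  fit <- glmFit(m[, "acc"], X)
  new("PpiResult",
      coefficients = fit$coefficients,
      residualDf = fit$residualDf,
      conditionNumber = fit$conditionNumber,
      designDigest = designDigest(design))
}

setMethod("show", "PpiResult", function(object) {
  cat("PpiResult (df =", object@residualDf,
      ", condition number =", format(object@conditionNumber, digits = 4),
      ")\n")
  print(round(object@coefficients, 4))
})

#' Contrast the PPI interaction between two runs
#'
#' Difference of the seed-by-condition interaction betas (later minus
#' earlier run) with variance propagated under the independent-runs
#' assumption; the z-like statistic is the difference over its pooled
#' standard error.
#'
#' @param resultRun1,resultRun4 \linkS4class{PpiResult} fits of the two
#'   runs, from the same participant and design.
#' @return List with \code{estimate}, \code{se} and \code{statistic}.
#' @export
runContrast <- function(resultRun1, resultRun4) {
  stopifnot(is(resultRun1, "PpiResult"), is(resultRun4, "PpiResult"))
  if (!identical(resultRun1@designDigest, resultRun4@designDigest))
    nfStop("invalidArgument", "cannot contrast fits from different designs")
  b1 <- resultRun1@coefficients["interaction", ]
  b4 <- resultRun4@coefficients["interaction", ]
  est <- b4$beta - b1$beta
  se <- sqrt(b1$se^2 + b4$se^2)
  list(estimate = est, se = se,
       statistic = if (se > 0) est / se else NA_real_)
}

#' Write a PpiResult or run summary as JSON
#'
#' @param x a \linkS4class{PpiResult} or the data.frame returned by
#'   \code{\link{nfSignalTimecourse}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePpiResult <- function(x, path) {
  stopifnot(is(x, "PpiResult"))
  jsonlite::write_json(
    list(regressors = rownames(x@coefficients),
         beta = x@coefficients$beta,
         se = x@coefficients$se,
         t = x@coefficients$t,
         residual_df = x@residualDf,
         condition_number = x@conditionNumber,
         design_digest = x@designDigest),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePpiResult
#' @export
readPpiResult <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PpiResult",
      coefficients = data.frame(beta = j$beta, se = j$se, t = j$t,
                                row.names = j$regressors),
      residualDf = j$residual_df,
      conditionNumber = j$condition_number,
      designDigest = j$design_digest)
}
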