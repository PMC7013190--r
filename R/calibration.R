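# Localizer-based calibration of the feedback range: pool task-block
# windowed partial correlations, filter, and take min/max as
# ConnectivityBaseline / ConnectivityMax.

#' Calibrate the feedback range from a localizer run
#'
#' For every TASK block, all full sliding windows lying entirely within
#' the block are computed and their partial-correlation coefficients
#' pooled. Undefined windows are dropped, then coefficients below 0 are
#' removed, then a single mean +/- 2 SD pass removes outliers (sample SD
#' of the post-negative-removal set). The minimum and maximum of the
#' retained set become ConnectivityBaseline and ConnectivityMax.
#'
#' @param localizerTs \linkS4class{RoiTimeSeries} of the localizer run.
#' @param design the localizer \linkS4class{BlockDesign}; its TASK blocks
#'   must each span at least \code{windowLen} samples.
#' @param windowLen window length in samples.
#' @return A \linkS4class{CalibrationResult}.
#' @seealso \code{\link{fallbackCalibration}} for the group-default range
#'   used when calibration fails.
#' @examples
#' loc <- simulateRun(makeLocalizerDesign(),
#'                    SimParams(couplingRegulate = 0.9, seed = 5))
#' calibrate(loc, makeLocalizerDesign())
#' @export
calibrate <- function(localizerTs, design, windowLen = 20L) {
  stopifnot(is(design, "BlockDesign"))
  validObject(design)
  windowLen <- as.integer(windowLen)
  m <- boldMatrix(localizerTs)
  if (nrow(m) != nSamples(design))
    nfStop("invalidArgument", "time series length does not match design")

  taskIdx <- which(design@labels == "TASK")
  if (length(taskIdx) == 0L)
    nfStop("invalidArgument", "design has no TASK blocks")
  blockLens <- round(design@durations[taskIdx] / design@trS)
  if (any(blockLens < windowLen))
    nfStop("invalidArgument",
           "every TASK block must span at least windowLen samples")

  pooled <- unlist(lapply(taskIdx, function(b) {
    first <- round(design@onsets[b] / design@trS) + 1L
    len <- round(design@durations[b] / design@trS)
    starts <- first:(first + len - windowLen)
    vapply(starts, function(s) {
      idx <- s:(s + windowLen - 1L)
      partialCorrValue(m[idx, 1L], m[idx, 2L], m[idx, 3L])
    }, numeric(1L))
  }))

  calibrateFromCoeffs(pooled)
}

#' Filter pooled coefficients (the calibration filtering rule alone)
#'
#' Exposed separately for testing and for calibrating from externally
#' computed coefficient pools: drops \code{NA}, removes negatives, then
#' one mean +/- 2 SD outlier pass.
#'
#' @param coeffs numeric vector of pooled partial-correlation
#'   coefficients.
#' @return A \linkS4class{CalibrationResult}.
#' @examples
#' calibrateFromCoeffs(c(-0.10, 0.20, 0.50, 0.80))
#' @export
calibrateFromCoeffs <- function(coeffs) {
  coeffs <- coeffs[!is.na(coeffs)]
  nonNeg <- coeffs[coeffs >= 0]
  nNeg <- length(coeffs) - length(nonNeg)
  if (length(nonNeg) == 0L)
    nfStop("calibrationFailure", paste(
      "calibration failed: no non-negative coefficients retained;",
      "use fallbackCalibration() for the group-default range"))
  mu <- mean(nonNeg)
  sdv <- sd(nonNeg)
  keep <- if (length(nonNeg) > 1L && is.finite(sdv) && sdv > 0)
    abs(nonNeg - mu) <= 2 * sdv else rep(TRUE, length(nonNeg))
  retained <- nonNeg[keep]
  if (length(retained) == 0L || min(retained) == max(retained))
    nfStop("calibrationFailure", paste(
      "calibration failed: degenerate retained set (baseline equals max);",
      "use fallbackCalibration() for the group-default range"))
  new("CalibrationResult",
      retainedCoeffs = retained,
      baselineR = min(retained),
      maxR = max(retained),
      nRemovedNegative = as.integer(nNeg),
      nRemovedOutlier = as.integer(sum(!keep)))
}

#' Group-default calibration range
#'
#' Fallback used when a participant's own calibration fails (degenerate
#' or empty retained set): the sample-mean ConnectivityBaseline of 0.17
#' and ConnectivityMax of 0.81. A warning is raised so the substitution
#' is visible in logs.
#'
#' @return A \linkS4class{CalibrationResult} with the group-default range.
#' @export
fallbackCalibration <- function() {
  warning("using group-default calibration (baseline 0.17, max 0.81)",
          call. = FALSE)
  new("CalibrationResult",
      retainedCoeffs = c(0.17, 0.81),
      baselineR = 0.17, maxR = 0.81,
      nRemovedNegative = 0L, nRemovedOutlier = 0L)
}

#' @rdname CalibrationResult-class
#' @export
setMethod("baselineR", "CalibrationResult", function(x) x@baselineR)

#' @rdname CalibrationResult-class
#' @export
setMethod("maxR", "CalibrationResult", function(x) x@maxR)

#' @rdname CalibrationResult-class
#' @export
setMethod("retainedCoeffs", "CalibrationResult", function(x) x@retainedCoeffs)

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult:",
      sprintf("baseline %.3f, max %.3f (%d retained; %d negative, %d outlier removed)\n",
              object@baselineR, object@maxR, length(object@retainedCoeffs),
              object@nRemovedNegative, object@nRemovedOutlier))
})

#' Write / read a CalibrationResult as JSON
#'
#' @param calib a \linkS4class{CalibrationResult}.
#' @param path file path.
#' @return \code{readCalibration} returns a
#'   \linkS4class{CalibrationResult}; \code{writeCalibration} returns
#'   \code{path} invisibly.
#' @export
writeCalibration <- function(calib, path) {
  stopifnot(is(calib, "CalibrationResult"))
  jsonlite::write_json(
    list(retained_coeffs = calib@retainedCoeffs,
         baseline_r = calib@baselineR,
         max_r = calib@maxR,
         n_removed_negative = calib@nRemovedNegative,
         n_removed_outlier = calib@nRemovedOutlier),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("retained_coeffs", "baseline_r", "max_r"))
    if (is.null(j[[f]]))
      nfStop("parseError", sprintf("%s: missing field '%s'", path, f))
  new("CalibrationResult",
      retainedCoeffs = as.numeric(j$retained_coeffs),
      baselineR = as.numeric(j$baseline_r),
      maxR = as.numeric(j$max_r),
      nRemovedNegative = as.integer(j$n_removed_negative %||% 0L),
      nRemovedOutlier = as.integer(j$n_removed_outlier %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
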