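# First-order partial correlation and its sliding-window form: the core
# quantity rewarded by the feedback gauge.

# Internal: partial correlation of x and y given z via the
# pairwise-correlation formula. Returns NA for degenerate windows.
# A zero-variance nuisance z partials out nothing beyond the mean, so the
# residual-regression definition reduces to the plain Pearson r_xy; the
# same convention is used here. Zero variance in x or y, or a nuisance
# perfectly collinear with a target, leaves the coefficient undefined.
partialCorrValue <- function(x, y, z) {
  sx <- sd(x); sy <- sd(y); sz <- sd(z)
  if (sx == 0 || sy == 0 || !is.finite(sx) || !is.finite(sy))
    return(NA_real_)
  if (sz == 0 || !is.finite(sz)) {
    r <- cor(x, y)
    return(if (is.finite(r)) max(-1, min(1, r)) else NA_real_)
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (!is.finite(den2) || den2 <= 0)
    return(NA_real_)
  r <- (rxy - rxz * ryz) / sqrt(den2)
  if (!is.finite(r)) return(NA_real_)
  max(-1, min(1, r))
}

#' First-order partial correlation
#'
#' Correlation between \code{x} and \code{y} after removing the linear
#' influence of a nuisance signal \code{z}:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' with Pearson correlations on mean-centred vectors. A constant nuisance
#' partials out nothing beyond the mean, so the coefficient reduces to the
#' plain Pearson \eqn{r_{xy}}. Zero variance in \code{x} or \code{y}, or a
#' nuisance perfectly collinear with a target, leaves the coefficient
#' undefined: an error here, an \code{NA} marker inside windowed use.
#'
#' @param x,y,z equal-length numeric vectors (length >= 3).
#' @return Partial-correlation coefficient in \code{[-1, 1]}.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partialCorr(x, y, z)
#' @export
partialCorr <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    nfStop("invalidArgument", "x, y and z must have equal length")
  if (length(x) < 3L)
    nfStop("invalidArgument", "need at least 3 samples")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    nfStop("invalidArgument", "missing values are not allowed")
  r <- partialCorrValue(x, y, z)
  if (is.na(r))
    nfStop("degenerateInput",
           "partial correlation undefined: zero-variance target or nuisance collinear with a target")
  r
}

#' Sliding-window partial correlation of an ROI time series
#'
#' Computes the 20-sample (by default) sliding-window partial correlation
#' between the two target ROIs given the nuisance ROI, one coefficient
#' per window position at stride 1. At TR = 1 s the default window spans
#' 20 s; for other TRs use \code{round(20 / trS)} to preserve the
#' 20-second semantics. Degenerate windows yield \code{NA}.
#'
#' @param ts an \linkS4class{RoiTimeSeries} (or a TR-by-3 numeric matrix).
#' @param windowLen window length in samples (>= 3).
#' @return A \linkS4class{WindowedSeries} with
#'   \code{nSamples - windowLen + 1} values.
#' @examples
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 2))
#' w <- windowedPartialCorr(ts)
#' length(windowValues(w))  # 420 - 20 + 1
#' @export
windowedPartialCorr <- function(ts, windowLen = 20L) {
  m <- if (is(ts, "RoiTimeSeries")) boldMatrix(ts) else as.matrix(ts)
  windowLen <- as.integer(windowLen)
  if (windowLen < 3L)
    nfStop("invalidArgument", "windowLen must be at least 3")
  n <- nrow(m)
  if (n < windowLen)
    nfStop("invalidArgument",
           sprintf("series has %d samples, shorter than window %d",
                   n, windowLen))
  starts <- seq_len(n - windowLen + 1L)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + windowLen - 1L)
    partialCorrValue(m[idx, 1L], m[idx, 2L], m[idx, 3L])
  }, numeric(1L))
  new("WindowedSeries", values = vals, windowLen = windowLen,
      startIndices = as.integer(starts - 1L))
}

#' @rdname WindowedSeries-class
#' @export
setMethod("windowValues", "WindowedSeries", function(x) x@values)

#' @rdname WindowedSeries-class
#' @export
setMethod("windowStarts", "WindowedSeries", function(x) x@startIndices)

#' @describeIn WindowedSeries-class number of window positions.
#' @export
setMethod("length", "WindowedSeries", function(x) length(x@values))

setMethod("show", "WindowedSeries", function(object) {
  v <- object@values
  cat("WindowedSeries:", length(v), "windows of", object@windowLen,
      "samples;", sum(is.na(v)), "undefined\n")
  if (any(!is.na(v)))
    cat(sprintf("  range of defined values: [%.3f, %.3f]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' Write a WindowedSeries as tab-separated text
#'
#' Columns \code{start_index} (0-based) and \code{r}; undefined windows
#' are written as \code{NA}.
#'
#' @param ws a \linkS4class{WindowedSeries}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeWindowedSeries <- function(ws, path) {
  stopifnot(is(ws, "WindowedSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# window_len=", ws@windowLen), con)
  writeLines("start_index\tr", con)
  writeLines(paste(ws@startIndices,
                   ifelse(is.na(ws@values), "NA", fmtNum(ws@values)),
                   sep = "\t"), con)
  invisible(path)
}
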