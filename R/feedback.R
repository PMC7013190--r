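# Streaming per-TR feedback engine: gauge scaling, incremental window
# updates, batch replay and yoked sham playback.

#' Scale a partial correlation to gauge lines
#'
#' The gauge maps the windowed partial correlation onto 0-10 lines via
#' \deqn{lines = \frac{r - ConnectivityBaseline}
#'   {ConnectivityMax - ConnectivityBaseline} \times 10}
#' rounded to the next integer (implemented as round-half-away-from-zero,
#' isolated here so the convention is swappable), then clamped: values of
#' 10 or more display the maximum of 10 lines, values of 0 or less the
#' minimum of 0. An undefined \code{rawR} displays 0 lines.
#'
#' @param rawR partial-correlation value (may be \code{NA}).
#' @param calib a \linkS4class{CalibrationResult} with
#'   \code{maxR > baselineR}.
#' @return Integer line count in \code{0..10}.
#' @examples
#' calib <- calibrateFromCoeffs(c(0.17, 0.81))
#' scaleToLines(0.95, calib)  # clamps to 10
#' scaleToLines(0.05, calib)  # clamps to 0
#' scaleToLines(0.49, calib)  # exactly 5
#' @export
scaleToLines <- function(rawR, calib) {
  stopifnot(is(calib, "CalibrationResult"))
  if (calib@maxR <= calib@baselineR)
    nfStop("invalidArgument",
           "degenerate calibration: maxR must exceed baselineR")
  vapply(rawR, function(r) {
    if (is.na(r)) return(0L)
    scaled <- (r - calib@baselineR) / (calib@maxR - calib@baselineR) * 10
    as.integer(max(0, min(10, roundHalfAway(scaled))))
  }, integer(1L))
}

#' Streaming feedback state
#'
#' Creates the state object consumed by \code{\link{feedbackStep}}: the
#' calibration, the per-TR design labels, and a rolling buffer of the
#' last \code{windowLen} sample triples. Cost per step is independent of
#' run length.
#'
#' @param calib a \linkS4class{CalibrationResult}.
#' @param design the run's \linkS4class{BlockDesign}.
#' @param windowLen window length in samples.
#' @return A feedback state (opaque list).
#' @export
newFeedbackState <- function(calib, design, windowLen = 20L) {
  stopifnot(is(calib, "CalibrationResult"), is(design, "BlockDesign"))
  validObject(design)
  if (calib@maxR <= calib@baselineR)
    nfStop("invalidArgument",
           "degenerate calibration: maxR must exceed baselineR")
  list(calib = calib,
       labels = labelsPerTr(design),
       designDigest = designDigest(design),
       windowLen = as.integer(windowLen),
       buffer = matrix(numeric(0), nrow = 0L, ncol = 3L),
       t = 0L)
}

#' Advance the feedback engine by one TR
#'
#' Appends one sample triple (dlpfc, acc, nuisance) to the rolling
#' buffer and emits exactly one feedback frame. While the buffer is
#' below \code{windowLen} samples the frame is a warm-up frame with 0
#' lines; afterwards the raw value is the partial correlation over the
#' trailing window. The gauge is shown only during REGULATE blocks.
#'
#' @param state a state from \code{\link{newFeedbackState}} (or a
#'   previous step).
#' @param sampleTriple numeric length-3 vector: dlpfc, acc, nuisance.
#' @return List with elements \code{state} (updated) and \code{frame}
#'   (one-row data.frame: tIndex, rawR, scaled, lines, shown, warmup).
#' @examples
#' st <- newFeedbackState(calibrateFromCoeffs(c(0.17, 0.81)), makeNfDesign())
#' out <- feedbackStep(st, c(0.1, 0.2, 0.05))
#' out$frame
#' @export
feedbackStep <- function(state, sampleTriple) {
  if (length(sampleTriple) != 3L || anyNA(sampleTriple) ||
      !is.numeric(sampleTriple))
    nfStop("invalidArgument",
           "sampleTriple must be 3 non-missing numeric values")
  if (state$t >= length(state$labels))
    nfStop("invalidArgument", "run already complete: no further samples")

  buf <- rbind(state$buffer, as.numeric(sampleTriple))
  if (nrow(buf) > state$windowLen)
    buf <- buf[-1L, , drop = FALSE]
  state$buffer <- buf
  tIndex <- state$t
  state$t <- tIndex + 1L

  warmup <- nrow(buf) < state$windowLen
  rawR <- if (warmup) NA_real_ else
    partialCorrValue(buf[, 1L], buf[, 2L], buf[, 3L])
  scaled <- if (is.na(rawR)) NA_real_ else
    (rawR - state$calib@baselineR) /
      (state$calib@maxR - state$calib@baselineR) * 10
  lines <- if (warmup || is.na(rawR)) 0L else scaleToLines(rawR, state$calib)
  frame <- data.frame(
    tIndex = tIndex,
    rawR = rawR,
    scaled = scaled,
    lines = lines,
    shown = state$labels[tIndex + 1L] == "REGULATE",
    warmup = warmup)
  list(state = state, frame = frame)
}

#' Batch replay of the feedback engine over a full run
#'
#' Feeds every TR of the run through \code{\link{feedbackStep}} and
#' collects the frames into a veridical \linkS4class{FeedbackTrace}.
#' Frames are shown only during REGULATE blocks; warm-up and undefined
#' frames display 0 lines.
#'
#' @param ts \linkS4class{RoiTimeSeries} of the run.
#' @param design the run's \linkS4class{BlockDesign}.
#' @param calib a \linkS4class{CalibrationResult}.
#' @param windowLen window length in samples.
#' @param runId identifier recorded in the trace.
#' @return A \linkS4class{FeedbackTrace} with one frame per TR.
#' @examples
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 4))
#' calib <- calibrateFromCoeffs(c(0.17, 0.81))
#' tr <- runFeedback(ts, makeNfDesign(), calib)
#' head(frames(tr))
#' @export
runFeedback <- function(ts, design, calib, windowLen = 20L,
                        runId = "run") {
  m <- boldMatrix(ts)
  if (nrow(m) != nSamples(design))
    nfStop("invalidArgument", sprintf(
      "series length %d does not match design sample count %d",
      nrow(m), nSamples(design)))
  state <- newFeedbackState(calib, design, windowLen)
  frameList <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    out <- feedbackStep(state, m[i, ])
    state <- out$state
    frameList[[i]] <- out$frame
  }
  fr <- do.call(rbind, frameList)
  new("FeedbackTrace",
      frames = S4Vectors::DataFrame(fr),
      runId = runId,
      calibrationRef = sprintf("baseline=%s;max=%s",
                               fmtNum(calib@baselineR), fmtNum(calib@maxR)),
      designRef = designDigest(design),
      provenance = "veridical")
}

#' Yoked sham playback of a veridical trace
#'
#' Returns a trace whose displayed line and shown sequences are exactly
#' those of the source trace; the recipient's own brain data has no
#' influence. Provenance records the source run. Yoking an already
#' yoked trace (second-generation sham) is rejected.
#'
#' @param source a veridical \linkS4class{FeedbackTrace}.
#' @param runId identifier for the sham run.
#' @return A \linkS4class{FeedbackTrace} with provenance
#'   \code{"yoked:<source run id>"}.
#' @export
yokedTrace <- function(source, runId = paste0(source@runId, "_yoked")) {
  stopifnot(is(source, "FeedbackTrace"))
  if (source@provenance != "veridical")
    nfStop("invalidArgument",
           "cannot yoke a yoked trace (no second-generation sham)")
  new("FeedbackTrace",
      frames = source@frames,
      runId = runId,
      calibrationRef = source@calibrationRef,
      designRef = source@designRef,
      provenance = paste0("yoked:", source@runId))
}

#' @rdname FeedbackTrace-class
#' @export
setMethod("frames", "FeedbackTrace", function(x) x@frames)

#' @rdname FeedbackTrace-class
#' @export
setMethod("provenance", "FeedbackTrace", function(x) x@provenance)

#' @rdname FeedbackTrace-class
#' @export
setMethod("runId", "FeedbackTrace", function(x) x@runId)

#' @describeIn FeedbackTrace-class number of frames (TRs).
#' @export
setMethod("length", "FeedbackTrace", function(x) nrow(x@frames))

setMethod("show", "FeedbackTrace", function(object) {
  fr <- object@frames
  shownLines <- fr$lines[fr$shown & !fr$warmup]
  cat("FeedbackTrace:", nrow(fr), "frames,", object@provenance, "\n")
  cat(sprintf("  run %s; mean shown lines %.2f; %d warm-up frames\n",
              object@runId,
              if (length(shownLines)) mean(shownLines) else NA_real_,
              sum(fr$warmup)))
})

#' Write / read a FeedbackTrace as tab-separated text plus JSON sidecar
#'
#' The table has columns \code{t_index}, \code{raw_r}, \code{scaled},
#' \code{lines}, \code{shown}, \code{warmup}; the sidecar
#' (\code{<path>.json}) carries run id, calibration and design references
#' and provenance.
#'
#' @param trace a \linkS4class{FeedbackTrace}.
#' @param path file path for the table; the sidecar is \code{<path>.json}.
#' @return \code{readFeedbackTrace} returns a
#'   \linkS4class{FeedbackTrace}; \code{writeFeedbackTrace} returns
#'   \code{path} invisibly.
#' @export
writeFeedbackTrace <- function(trace, path) {
  stopifnot(is(trace, "FeedbackTrace"))
  fr <- as.data.frame(trace@frames)
  con <- file(path, "w")
  writeLines("t_index\traw_r\tscaled\tlines\tshown\twarmup", con)
  writeLines(paste(fr$tIndex,
                   ifelse(is.na(fr$rawR), "NA", fmtNum(fr$rawR)),
                   ifelse(is.na(fr$scaled), "NA", fmtNum(fr$scaled)),
                   fr$lines,
                   as.integer(fr$shown),
                   as.integer(fr$warmup),
                   sep = "\t"), con)
  close(con)
  jsonlite::write_json(
    list(run_id = trace@runId,
         calibration_ref = trace@calibrationRef,
         design_ref = trace@designRef,
         provenance = trace@provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFeedbackTrace
#' @export
readFeedbackTrace <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  need <- c("t_index", "raw_r", "scaled", "lines", "shown", "warmup")
  if (!identical(colnames(tab), need))
    nfStop("parseError", sprintf(
      "%s: line 1: expected columns %s", path, paste(need, collapse = ", ")))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    nfStop("parseError", sprintf("missing sidecar %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new("FeedbackTrace",
      frames = S4Vectors::DataFrame(
        tIndex = as.integer(tab$t_index),
        rawR = as.numeric(tab$raw_r),
        scaled = as.numeric(tab$scaled),
        lines = as.integer(tab$lines),
        shown = as.logical(tab$shown),
        warmup = as.logical(tab$warmup)),
      runId = as.character(meta$run_id),
      calibrationRef = as.character(meta$calibration_ref),
      designRef = as.character(meta$design_ref),
      provenance = as.character(meta$provenance))
}
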