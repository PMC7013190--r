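# On-disk formats (tab-separated tables with JSON sidecars), the
# participant manifest, the NIfTI ROI-mean adapter and the end-to-end
# pipeline driver.

#' Write / read an RoiTimeSeries as tab-separated text plus JSON sidecar
#'
#' The table has columns \code{t_index}, \code{dlpfc}, \code{acc},
#' \code{nuisance} at 10 significant digits; the sidecar
#' (\code{<path>.json}) carries the TR, the design (when attached) and
#' the provenance record, so the round trip reproduces the object within
#' serialization precision.
#'
#' @param ts an \linkS4class{RoiTimeSeries}.
#' @param path file path for the table; the sidecar is \code{<path>.json}.
#' @return \code{readRoiTimeSeries} returns an
#'   \linkS4class{RoiTimeSeries}; \code{writeRoiTimeSeries} returns
#'   \code{path} invisibly.
#' @examples
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 9))
#' p <- tempfile(fileext = ".tsv")
#' writeRoiTimeSeries(ts, p)
#' ts2 <- readRoiTimeSeries(p)
#' @export
writeRoiTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeSeries"))
  m <- boldMatrix(ts)
  con <- file(path, "w")
  writeLines("t_index\tdlpfc\tacc\tnuisance", con)
  writeLines(paste(seq_len(nrow(m)) - 1L,
                   fmtNum(m[, 1L]), fmtNum(m[, 2L]), fmtNum(m[, 3L]),
                   sep = "\t"), con)
  close(con)
  md <- S4Vectors::metadata(ts)
  sidecar <- list(tr_s = md$trS, provenance = md$provenance)
  if (!is.null(md$design)) {
    d <- md$design
    sidecar$design <- list(labels = d@labels, durations = d@durations,
                           tr_s = d@trS)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiTimeSeries
#' @export
readRoiTimeSeries <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !identical(lines[1L],
                                       "t_index\tdlpfc\tacc\tnuisance"))
    nfStop("parseError", sprintf(
      "%s: line 1: expected header 't_index dlpfc acc nuisance'", path))
  tab <- utils::read.delim(textConnection(lines), header = TRUE)
  if (ncol(tab) != 4L)
    nfStop("parseError", sprintf("%s: expected 4 columns, found %d",
                                 path, ncol(tab)))
  for (cn in c("dlpfc", "acc", "nuisance")) {
    tab[[cn]] <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(tab[[cn]]))
      nfStop("parseError", sprintf(
        "%s: line %d, column %s: missing or non-numeric value",
        path, 1L + which(is.na(tab[[cn]]))[1L], cn))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    nfStop("parseError", sprintf("missing sidecar %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  design <- NULL
  if (!is.null(meta$design))
    design <- BlockDesign(meta$design$labels, meta$design$durations,
                          trS = meta$design$tr_s)
  RoiTimeSeries(as.matrix(tab[, c("dlpfc", "acc", "nuisance")]),
                design = design, trS = meta$tr_s,
                provenance = as.list(meta$provenance))
}

#' ROI-mean time series from a 4-D NIfTI volume and three masks
#'
#' Adapter for acquired data: averages the BOLD signal of a 4-D NIfTI
#' volume within three binary ROI masks (dlpfc, acc, nuisance) and
#' returns the per-TR means as an \linkS4class{RoiTimeSeries}. Masks and
#' data must share grid dimensions. Requires the RNifti package.
#'
#' @param boldFile path to a 4-D NIfTI volume.
#' @param maskFiles character vector of three 3-D binary mask paths, in
#'   the order dlpfc, acc, nuisance.
#' @param trS repetition time in seconds.
#' @param design optional \linkS4class{BlockDesign} to attach.
#' @return An \linkS4class{RoiTimeSeries}.
#' @export
roiMeansFromNifti <- function(boldFile, maskFiles, trS, design = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    nfStop("invalidArgument", "roiMeansFromNifti requires the RNifti package")
  if (length(maskFiles) != 3L)
    nfStop("invalidArgument", "exactly three mask files are required")
  bold <- RNifti::readNifti(boldFile)
  dims <- dim(bold)
  if (length(dims) != 4L)
    nfStop("invalidArgument", "BOLD image must be 4-D")
  nT <- dims[4L]
  vox <- matrix(as.numeric(bold), ncol = nT)
  cols <- vapply(maskFiles, function(mf) {
    mask <- RNifti::readNifti(mf)
    if (!identical(dim(mask)[1:3], dims[1:3]))
      nfStop("invalidArgument", sprintf(
        "mask %s grid does not match BOLD grid", mf))
    sel <- as.logical(as.numeric(mask) != 0)
    if (!any(sel))
      nfStop("invalidArgument", sprintf("mask %s is empty", mf))
    colMeans(vox[sel, , drop = FALSE])
  }, numeric(nT))
  RoiTimeSeries(cols, design = design, trS = trS,
                provenance = list(source = boldFile, masks = maskFiles))
}

#' Construct a RunManifest
#'
#' @param participantId participant identifier.
#' @param group \code{"EG"} (veridical feedback) or \code{"CG"} (yoked
#'   sham; requires \code{yokeSource}).
#' @param paths named list of artifact paths.
#' @param seeds named list of seeds (top-level and derived).
#' @param yokeSource id of the yoke-source participant (CG only).
#' @return A \linkS4class{RunManifest}.
#' @export
RunManifest <- function(participantId, group, paths = list(),
                        seeds = list(), yokeSource = NA_character_) {
  yokeSource <- as.character(yokeSource)
  if (length(yokeSource) == 0L) yokeSource <- NA_character_
  new("RunManifest", participantId = as.character(participantId),
      group = group, yokeSource = yokeSource,
      paths = paths, seeds = seeds)
}

setMethod("show", "RunManifest", function(object) {
  cat("RunManifest:", object@participantId, sprintf("(%s)", object@group))
  if (!is.na(object@yokeSource))
    cat(" yoked to", object@yokeSource)
  cat("\n ", length(object@paths), "artifacts\n")
})

#' Write / read a RunManifest as JSON
#'
#' @param manifest a \linkS4class{RunManifest}.
#' @param path file path.
#' @return \code{readRunManifest} returns a validated
#'   \linkS4class{RunManifest}; \code{writeRunManifest} returns
#'   \code{path} invisibly.
#' @export
writeRunManifest <- function(manifest, path) {
  stopifnot(is(manifest, "RunManifest"))
  validObject(manifest)
  rec <- list(participant_id = manifest@participantId,
              group = manifest@group,
              paths = manifest@paths,
              seeds = manifest@seeds)
  if (!is.na(manifest@yokeSource))
    rec$yoke_source <- manifest@yokeSource
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunManifest
#' @export
readRunManifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ys <- j$yoke_source
  if (is.null(ys) || length(ys) == 0L) ys <- NA_character_
  m <- RunManifest(j$participant_id, j$group,
                   paths = as.list(j$paths), seeds = as.list(j$seeds),
                   yokeSource = ys)
  validObject(m)
  m
}

#' Run the full pipeline for one simulated participant
#'
#' Simulates a localizer and four neurofeedback runs, calibrates the
#' feedback range from the localizer, replays the feedback engine over
#' each run (veridically, or as yoked sham when \code{yokeFrom} names a
#' previous participant's output directory), computes the
#' neurofeedback-signal time course and the per-run PPI fits with the
#' run 1 vs run 4 contrast, and writes every artifact plus a
#' machine-readable \code{summary.json} and \code{manifest.json} under
#' \code{outDir}. Identical \code{(scenario, seed)} produce
#' byte-identical summaries.
#'
#' @param scenario \code{"responder"} or \code{"non_responder"}.
#' @param seed top-level integer seed for the participant.
#' @param outDir output directory (created if needed).
#' @param participantId identifier used in the manifest.
#' @param yokeFrom \code{NULL} for a veridical (EG) participant, or the
#'   output directory of a previous EG participant whose traces are
#'   replayed as sham (CG).
#' @param windowLen sliding-window length in samples.
#' @param verbose emit progress messages.
#' @return The summary list, invisibly.
#' @examples
#' \donttest{
#' out <- endToEnd("responder", seed = 1, outDir = tempfile())
#' out$nf_timecourse
#' }
#' @export
endToEnd <- function(scenario, seed, outDir,
                     participantId = sprintf("sub-%04d", seed),
                     yokeFrom = NULL, windowLen = 20L, verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      nfStop("pipelineError",
             sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("simulating participant ", participantId, " (", scenario, ")")
  sim <- stage("simulate", simulateParticipant(scenario, seed))
  locDesign <- makeLocalizerDesign()
  nfDesign <- makeNfDesign()

  pth <- function(f) file.path(outDir, f)
  writeRoiTimeSeries(sim$localizer, pth("localizer.tsv"))
  for (r in seq_len(4L))
    writeRoiTimeSeries(sim$nfRuns[[r]], pth(sprintf("nf_run%d.tsv", r)))

  say("calibrating from localizer")
  calib <- stage("calibrate",
                 tryCatch(calibrate(sim$localizer, locDesign, windowLen),
                          calibrationFailure = function(e) {
                            say("calibration failed; using fallback")
                            suppressWarnings(fallbackCalibration())
                          }))
  writeCalibration(calib, pth("calibration.json"))

  group <- if (is.null(yokeFrom)) "EG" else "CG"
  yokeSourceId <- NA_character_
  traces <- stage("feedback", lapply(seq_len(4L), function(r) {
    veridical <- runFeedback(sim$nfRuns[[r]], nfDesign, calib, windowLen,
                             runId = sprintf("%s_run%d", participantId, r))
    if (is.null(yokeFrom)) return(veridical)
    src <- readFeedbackTrace(file.path(yokeFrom,
                                       sprintf("trace_run%d.tsv", r)))
    yokedTrace(src, runId = sprintf("%s_run%d", participantId, r))
  }))
  if (group == "CG") {
    srcMan <- readRunManifest(file.path(yokeFrom, "manifest.json"))
    yokeSourceId <- srcMan@participantId
  }
  for (r in seq_len(4L))
    writeFeedbackTrace(traces[[r]], pth(sprintf("trace_run%d.tsv", r)))

  say("offline analyses")
  # The NF-signal time course is defined for veridical feedback only; a
  # CG participant's own windowed connectivity is still summarised from
  # veridical replays of their own data for diagnostics.
  ownTraces <- if (group == "EG") traces else
    stage("feedback", lapply(seq_len(4L), function(r)
      runFeedback(sim$nfRuns[[r]], nfDesign, calib, windowLen,
                  runId = sprintf("%s_run%d_own", participantId, r))))
  nfTc <- stage("nf-timecourse", nfSignalTimecourse(ownTraces, calib))
  jsonlite::write_json(nfTc, pth("nf_timecourse.json"), digits = NA,
                       dataframe = "rows")

  ppis <- stage("ppi", lapply(seq_len(4L), function(r)
    ppiFirstLevel(sim$nfRuns[[r]], nfDesign)))
  for (r in seq_len(4L))
    writePpiResult(ppis[[r]], pth(sprintf("ppi_run%d.json", r)))
  contrast <- stage("contrast", runContrast(ppis[[1L]], ppis[[4L]]))
  jsonlite::write_json(contrast, pth("contrast_run4_vs_run1.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- RunManifest(
    participantId, group,
    paths = list(
      localizer = "localizer.tsv",
      nf_runs = sprintf("nf_run%d.tsv", 1:4),
      calibration = "calibration.json",
      traces = sprintf("trace_run%d.tsv", 1:4),
      nf_timecourse = "nf_timecourse.json",
      ppi = sprintf("ppi_run%d.json", 1:4),
      contrast = "contrast_run4_vs_run1.json"),
    seeds = list(top = seed,
                 localizer = subSeed(seed, 100L),
                 nf_runs = vapply(1:4, function(r) subSeed(seed, 100L + r),
                                  integer(1L))),
    yokeSource = yokeSourceId)
  writeRunManifest(manifest, pth("manifest.json"))

  summary <- list(
    participant_id = participantId,
    group = group,
    scenario = scenario,
    seed = seed,
    calibration = list(baseline_r = baselineR(calib), max_r = maxR(calib)),
    nf_timecourse = nfTc,
    ppi_interaction_t = vapply(ppis, function(p)
      p@coefficients["interaction", "t"], numeric(1L)),
    contrast_run4_vs_run1 = contrast,
    mean_shown_lines = vapply(traces, function(tr) {
      fr <- frames(tr)
      mean(fr$lines[fr$shown & !fr$warmup])
    }, numeric(1L)))
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(summary)
}
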