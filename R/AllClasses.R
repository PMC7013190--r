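#' @import methods
#' @importFrom stats cor convolve dgamma qt pt rnorm sd setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' BlockDesign: an alternating block experimental design
#'
#' Ordered, contiguous, non-overlapping blocks labelled \code{REST} and one
#' active label (\code{TASK} for the localizer, \code{REGULATE} for
#' neurofeedback runs), sampled at a fixed TR. Labels must strictly
#' alternate between rest and the active condition.
#'
#' @slot labels character vector, one label per block.
#' @slot onsets numeric vector of block onsets in seconds.
#' @slot durations numeric vector of block durations in seconds.
#' @slot trS sampling interval (TR) in seconds.
#' @slot totalDurationS total run duration in seconds; an integer multiple
#'   of \code{trS} and equal to the sum of block durations.
#' @exportClass BlockDesign
setClass("BlockDesign",
  representation(
    labels = "character",
    onsets = "numeric",
    durations = "numeric",
    trS = "numeric",
    totalDurationS = "numeric"
  )
)

setValidity("BlockDesign", function(object) {
  msg <- character()
  nb <- length(object@labels)
  if (length(object@onsets) != nb || length(object@durations) != nb)
    msg <- c(msg, "labels, onsets and durations must have equal length")
  if (nb == 0L)
    msg <- c(msg, "design must contain at least one block")
  if (!all(object@labels %in% c("REST", "TASK", "REGULATE")))
    msg <- c(msg, "labels must be REST, TASK or REGULATE")
  if (length(object@trS) != 1L || object@trS <= 0)
    msg <- c(msg, "trS must be a single positive number")
  if (length(msg)) return(msg)
  if (nb > 1L) {
    if (any(diff(object@onsets) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    gaps <- object@onsets[-1L] -
      (object@onsets[-nb] + object@durations[-nb])
    if (any(abs(gaps) > 1e-9))
      msg <- c(msg, "blocks must be contiguous and non-overlapping")
    active <- object@labels != REST_LABEL
    if (any(active[-1L] == active[-nb]))
      msg <- c(msg, "labels must strictly alternate between rest and active")
  }
  if (abs(object@onsets[1L]) > 1e-9)
    msg <- c(msg, "first block must start at time 0")
  if (abs(sum(object@durations) - object@totalDurationS) > 1e-9)
    msg <- c(msg, "sum of block durations must equal totalDurationS")
  nSamp <- object@totalDurationS / object@trS
  if (abs(nSamp - round(nSamp)) > 1e-9)
    msg <- c(msg, "totalDurationS must be an integer multiple of trS")
  if (length(msg)) msg else TRUE
})

#' SimParams: parameters of the synthetic BOLD generator
#'
#' Controls the generative model for ROI-mean BOLD time series:
#' task-locked activation amplitude, the condition-dependent loading of a
#' shared latent component (which sets the target-target partial
#' correlation), a global component common to all three ROIs, AR(1) noise,
#' and slow linear drift. Identical \code{(params, design, seed)} always
#' yield bit-identical output.
#'
#' @slot taskAmp activation amplitude added to the target ROIs during
#'   active blocks (after HRF convolution), unitless.
#' @slot couplingRest,couplingRegulate shared-component loadings in
#'   \code{[0, 1.5]} applied during rest / active samples.
#' @slot globalAmp loading of the global (nuisance) component in all ROIs.
#' @slot noiseSd innovation standard deviation of the AR(1) noise; may be 0
#'   only for deliberately noise-free runs.
#' @slot ar1Phi AR(1) coefficient, in (-1, 1).
#' @slot driftPerMin linear drift slope, signal units per minute.
#' @slot seed integer RNG seed for the run.
#' @exportClass SimParams
setClass("SimParams",
  representation(
    taskAmp = "numeric",
    couplingRest = "numeric",
    couplingRegulate = "numeric",
    globalAmp = "numeric",
    noiseSd = "numeric",
    ar1Phi = "numeric",
    driftPerMin = "numeric",
    seed = "numeric"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  one <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("taskAmp", "couplingRest", "couplingRegulate", "globalAmp",
               "noiseSd", "ar1Phi", "driftPerMin", "seed"))
    if (!one(slot(object, nm)))
      msg <- c(msg, paste0(nm, " must be a single finite number"))
  if (length(msg)) return(msg)
  if (object@couplingRest < 0 || object@couplingRest > 1.5)
    msg <- c(msg, "couplingRest must lie in [0, 1.5]")
  if (object@couplingRegulate < 0 || object@couplingRegulate > 1.5)
    msg <- c(msg, "couplingRegulate must lie in [0, 1.5]")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (abs(object@ar1Phi) >= 1)
    msg <- c(msg, "ar1Phi must lie in (-1, 1)")
  if (length(msg)) msg else TRUE
})

#' RoiTimeSeries: ROI-mean BOLD signals for one run
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{bold} assay of
#' three rows (ROIs \code{dlpfc}, \code{acc}, \code{nuisance}) by one
#' column per TR. \code{colData} carries the 0-based TR index and, when a
#' design is attached, the per-TR block label; \code{metadata} records the
#' TR, the design and the provenance (simulation parameters and seed, or
#' the source file).
#'
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries", contains = "SummarizedExperiment")

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (!"bold" %in% SummarizedExperiment::assayNames(object))
    return("RoiTimeSeries requires a 'bold' assay")
  m <- SummarizedExperiment::assay(object, "bold")
  if (nrow(m) != 3L || !identical(rownames(m), c("dlpfc", "acc", "nuisance")))
    msg <- c(msg, "bold assay must have rows dlpfc, acc, nuisance")
  if (anyNA(m))
    msg <- c(msg, "bold assay must not contain missing values")
  md <- S4Vectors::metadata(object)
  if (is.null(md$trS) || !is.numeric(md$trS) || md$trS <= 0)
    msg <- c(msg, "metadata$trS must be a positive number")
  if (length(msg)) msg else TRUE
})

#' WindowedSeries: sliding-window partial-correlation coefficients
#'
#' One coefficient per window position (stride 1). Degenerate windows
#' (zero variance in a target channel, or a nuisance channel perfectly
#' collinear with a target) carry the undefined marker \code{NA}.
#'
#' @slot values numeric vector of coefficients in \code{[-1, 1]} or
#'   \code{NA}.
#' @slot windowLen window length in samples.
#' @slot startIndices 0-based index of each window's first sample.
#' @exportClass WindowedSeries
setClass("WindowedSeries",
  representation(
    values = "numeric",
    windowLen = "integer",
    startIndices = "integer"
  )
)

setValidity("WindowedSeries", function(object) {
  msg <- character()
  if (length(object@values) != length(object@startIndices))
    msg <- c(msg, "values and startIndices must have equal length")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (any(v < -1 - 1e-12) || any(v > 1 + 1e-12)))
    msg <- c(msg, "defined values must lie in [-1, 1]")
  if (object@windowLen < 3L)
    msg <- c(msg, "windowLen must be at least 3")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: localizer-derived feedback scaling range
#'
#' Retained localizer partial-correlation coefficients after removing
#' negatives and mean +/- 2 SD outliers, together with the minimum
#' (ConnectivityBaseline) and maximum (ConnectivityMax) used to scale the
#' gauge feedback.
#'
#' @slot retainedCoeffs retained coefficients, all in \code{[0, 1]}.
#' @slot baselineR minimum retained coefficient (ConnectivityBaseline).
#' @slot maxR maximum retained coefficient (ConnectivityMax).
#' @slot nRemovedNegative count of coefficients removed for being < 0.
#' @slot nRemovedOutlier count removed by the mean +/- 2 SD pass.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(
    retainedCoeffs = "numeric",
    baselineR = "numeric",
    maxR = "numeric",
    nRemovedNegative = "integer",
    nRemovedOutlier = "integer"
  )
)

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (length(object@retainedCoeffs) == 0L)
    msg <- c(msg, "retained set must be non-empty")
  if (any(object@retainedCoeffs < 0))
    msg <- c(msg, "retained coefficients must be non-negative")
  if (!(object@baselineR >= 0 && object@baselineR <= object@maxR &&
        object@maxR <= 1))
    msg <- c(msg, "must satisfy 0 <= baselineR <= maxR <= 1")
  if (length(msg)) msg else TRUE
})

#' FeedbackTrace: per-TR gauge feedback for one run
#'
#' One frame per TR with the raw windowed partial correlation, its scaled
#' value, the integer 0-10 gauge line count, whether the gauge was shown
#' (REGULATE blocks only) and whether the window was still warming up.
#' Provenance is \code{"veridical"} for feedback computed from the run's
#' own data, or \code{"yoked:<source run id>"} for sham playback.
#'
#' @slot frames a \link[S4Vectors]{DataFrame} with columns
#'   \code{tIndex}, \code{rawR}, \code{scaled}, \code{lines}, \code{shown},
#'   \code{warmup}.
#' @slot runId identifier of the run the trace belongs to.
#' @slot calibrationRef,designRef identifiers of the calibration and design.
#' @slot provenance \code{"veridical"} or \code{"yoked:<source_id>"}.
#' @exportClass FeedbackTrace
setClass("FeedbackTrace",
  representation(
    frames = "DataFrame",
    runId = "character",
    calibrationRef = "character",
    designRef = "character",
    provenance = "character"
  )
)

setValidity("FeedbackTrace", function(object) {
  msg <- character()
  need <- c("tIndex", "rawR", "scaled", "lines", "shown", "warmup")
  if (!all(need %in% colnames(object@frames)))
    return(paste("frames must have columns:", paste(need, collapse = ", ")))
  fr <- object@frames
  if (any(fr$lines < 0L | fr$lines > 10L))
    msg <- c(msg, "lines must lie in 0..10")
  bad <- (is.na(fr$rawR) | fr$warmup) & fr$lines != 0L
  if (any(bad))
    msg <- c(msg, "lines must be 0 when rawR is undefined or during warmup")
  if (!(identical(object@provenance, "veridical") ||
        startsWith(object@provenance, "yoked:")))
    msg <- c(msg, "provenance must be 'veridical' or 'yoked:<source_id>'")
  if (length(msg)) msg else TRUE
})

#' PpiResult: simplified first-level PPI model fit
#'
#' Ordinary-least-squares fit of the target (ACC) time series on an
#' intercept, the HRF-convolved REGULATE regressor, the mean-centred seed
#' (DLPFC) time series and the seed-by-condition interaction.
#'
#' @slot coefficients data.frame with one row per regressor and columns
#'   \code{beta}, \code{se}, \code{t}.
#' @slot residualDf residual degrees of freedom.
#' @slot conditionNumber condition number of the design matrix.
#' @slot designDigest compact design descriptor used to check that two
#'   fits being contrasted share the same design.
#' @exportClass PpiResult
setClass("PpiResult",
  representation(
    coefficients = "data.frame",
    residualDf = "numeric",
    conditionNumber = "numeric",
    designDigest = "character"
  )
)

setValidity("PpiResult", function(object) {
  if (object@residualDf <= 0)
    return("residual degrees of freedom must be positive")
  if (!all(c("beta", "se", "t") %in% colnames(object@coefficients)))
    return("coefficients must have columns beta, se, t")
  TRUE
})

#' RunManifest: bookkeeping record for one simulated participant
#'
#' Paths to the artifacts of one participant's study (localizer, four
#' neurofeedback runs, calibration, feedback traces) together with the
#' group assignment and the seed registry. Control-group (CG) manifests
#' must name the experimental-group participant whose feedback they were
#' yoked to; experimental-group (EG) manifests must not.
#'
#' @slot participantId participant identifier.
#' @slot group \code{"EG"} or \code{"CG"}.
#' @slot yokeSource id of the yoke source participant (CG only), else
#'   \code{NA}.
#' @slot paths named list of artifact paths.
#' @slot seeds named list: top-level seed and derived per-run sub-seeds.
#' @exportClass RunManifest
setClass("RunManifest",
  representation(
    participantId = "character",
    group = "character",
    yokeSource = "character",
    paths = "list",
    seeds = "list"
  )
)

setValidity("RunManifest", function(object) {
  msg <- character()
  if (!object@group %in% c("EG", "CG"))
    msg <- c(msg, "group must be EG or CG")
  if (object@group == "CG" && is.na(object@yokeSource))
    msg <- c(msg, "CG manifests must reference a yoke-source participant")
  if (object@group == "EG" && !is.na(object@yokeSource))
    msg <- c(msg, "EG manifests must not reference a yoke source")
  if (length(msg)) msg else TRUE
})
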