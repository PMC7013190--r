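# Synthetic ROI-mean BOLD generator: gamma HRF, condition-dependent
# coupling through a shared latent component, global component, AR(1)
# noise and linear drift.

#' Construct simulation parameters
#'
#' Defaults are the package's fixed simulation conditions: moderate task
#' activation (\code{taskAmp = 1}), a global component loading of 0.8,
#' unit-SD AR(1) innovations with coefficient 0.3, and a drift of 0.2
#' signal units per minute. The coupling loadings default to a resting
#' coupling of 0.3 and a regulate coupling of 0.6 (a moderate learned
#' modulation); scenario helpers override them per run.
#'
#' @param taskAmp activation amplitude of the targets during active blocks.
#' @param couplingRest,couplingRegulate shared-component loadings in
#'   \code{[0, 1.5]} during rest / active samples.
#' @param globalAmp global-component loading (all three ROIs).
#' @param noiseSd AR(1) innovation SD (0 only for noise-free tests).
#' @param ar1Phi AR(1) coefficient in (-1, 1).
#' @param driftPerMin linear drift slope per minute.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimParams}.
#' @examples
#' SimParams(seed = 1)
#' @export
SimParams <- function(taskAmp = 1.0, couplingRest = 0.3,
                      couplingRegulate = 0.6, globalAmp = 0.8,
                      noiseSd = 1.0, ar1Phi = 0.3, driftPerMin = 0.2,
                      seed = 1L) {
  new("SimParams", taskAmp = taskAmp, couplingRest = couplingRest,
      couplingRegulate = couplingRegulate, globalAmp = globalAmp,
      noiseSd = noiseSd, ar1Phi = ar1Phi, driftPerMin = driftPerMin,
      seed = as.numeric(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:",
      sprintf("taskAmp=%g couplingRest=%g couplingRegulate=%g",
              object@taskAmp, object@couplingRest, object@couplingRegulate),
      sprintf("globalAmp=%g noiseSd=%g ar1Phi=%g driftPerMin=%g seed=%d\n",
              object@globalAmp, object@noiseSd, object@ar1Phi,
              object@driftPerMin, as.integer(object@seed)))
})

#' Gamma hemodynamic response kernel
#'
#' Gamma-density HRF parameterized by its mean lag and SD, the
#' convolution kernel used both by the simulator and by the first-level
#' regressor builder. The underlying gamma has shape
#' \code{k = (mean/sd)^2} and scale \code{theta = sd^2/mean}; the kernel is
#' sampled every \code{trS} seconds over \code{[0, mean + 5 sd]} and
#' normalized to unit peak. With the default mean lag of 6 s and SD of
#' 3 s the kernel peaks at \code{(k - 1) theta = 4.5} s.
#'
#' @param meanLagS mean lag of the response in seconds (> 0).
#' @param sdS standard deviation of the response in seconds (> 0).
#' @param trS sampling interval in seconds.
#' @return Numeric kernel vector, first element at lag 0.
#' @examples
#' k <- gammaHrf()
#' which.max(k) - 1  # peak near 4.5 s at TR 1
#' @export
gammaHrf <- function(meanLagS = 6, sdS = 3, trS = 1) {
  if (!is.numeric(meanLagS) || meanLagS <= 0 ||
      !is.numeric(sdS) || sdS <= 0 || !is.numeric(trS) || trS <= 0)
    nfStop("invalidArgument", "gammaHrf parameters must be positive")
  shape <- (meanLagS / sdS)^2
  scale <- sdS^2 / meanLagS
  t <- seq(0, meanLagS + 5 * sdS, by = trS)
  k <- dgamma(t, shape = shape, scale = scale)
  k / max(k)
}

# Causal convolution of x with kernel k, truncated to length(x).
convolveCausal <- function(x, k) {
  n <- length(x)
  as.numeric(convolve(x, rev(k), type = "open"))[seq_len(n)]
}

# Stationary AR(1) series of length n, innovation SD s, coefficient phi.
# Consumes n + 1 normal draws from the current RNG stream.
ar1Series <- function(n, phi, s) {
  init <- rnorm(1L, sd = if (abs(phi) < 1) s / sqrt(1 - phi^2) else s)
  innov <- rnorm(n, sd = s)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = init))
}

#' Simulate one run of ROI-mean BOLD data
#'
#' Generative model, per sample \code{t} (labels from the design):
#' \deqn{target_i(t) = taskAmp\, x(t) + c(t)\, s(t) + globalAmp\, g(t) +
#'   drift(t) + e_i(t)}
#' \deqn{nuisance(t) = globalAmp\, g(t) + drift(t) + e_n(t)}
#' where \code{x(t)} is the active-block boxcar convolved with
#' \code{gammaHrf(6, 3, trS)}, \code{s(t)} is a standard-normal shared
#' latent with condition-dependent loading \code{c(t)} (couplingRest on
#' REST samples, couplingRegulate otherwise), \code{g(t)} is standard
#' normal smoothed by the same HRF kernel (rescaled back to unit variance
#' so \code{globalAmp} remains the component's SD), \code{drift} is linear
#' in time, and each \code{e} is an independent stationary AR(1) process.
#'
#' All randomness derives from \code{params@seed} through fixed
#' per-stream sub-seeds (\code{\link{subSeed}} streams 1-5: shared latent,
#' global, target-1 noise, target-2 noise, nuisance noise), so identical
#' inputs are bit-identical and individual streams can be regenerated.
#'
#' @param design a \linkS4class{BlockDesign}.
#' @param params a \linkS4class{SimParams}.
#' @param runId identifier stored in the result's metadata.
#' @return A \linkS4class{RoiTimeSeries}.
#' @examples
#' ts <- simulateRun(makeNfDesign(), SimParams(seed = 7))
#' dim(boldMatrix(ts))
#' @export
simulateRun <- function(design, params, runId = "run") {
  stopifnot(is(design, "BlockDesign"), is(params, "SimParams"))
  validObject(design); validObject(params)
  n <- nSamples(design)
  labels <- labelsPerTr(design)
  active <- labels != REST_LABEL

  kernel <- gammaHrf(6, 3, design@trS)
  L <- length(kernel)
  x <- convolveCausal(as.numeric(active), kernel)
  cLoad <- ifelse(active, params@couplingRegulate, params@couplingRest)
  drift <- params@driftPerMin * ((seq_len(n) - 1L) * design@trS) / 60

  withSeed <- function(stream, expr) {
    set.seed(subSeed(params@seed, stream))
    expr()
  }
  sLatent <- withSeed(1L, function() rnorm(n))
  gRaw <- withSeed(2L, function() rnorm(n + L - 1L))
  # Full-kernel smoothing (every output sample sees the whole kernel),
  # rescaled so the smoothed component has unit variance.
  gFull <- as.numeric(convolve(gRaw, rev(kernel), type = "open"))
  g <- gFull[seq(L, L + n - 1L)] / sqrt(sum(kernel^2))

  e1 <- withSeed(3L, function() ar1Series(n, params@ar1Phi, params@noiseSd))
  e2 <- withSeed(4L, function() ar1Series(n, params@ar1Phi, params@noiseSd))
  en <- withSeed(5L, function() ar1Series(n, params@ar1Phi, params@noiseSd))

  common <- params@globalAmp * g + drift
  target <- params@taskAmp * x + cLoad * sLatent + common
  m <- rbind(dlpfc = target + e1, acc = target + e2, nuisance = common + en)
  RoiTimeSeries(t(m), design = design,
                provenance = list(params = paramsToList(params),
                                  seed = params@seed, runId = runId))
}

paramsToList <- function(p) {
  list(taskAmp = p@taskAmp, couplingRest = p@couplingRest,
       couplingRegulate = p@couplingRegulate, globalAmp = p@globalAmp,
       noiseSd = p@noiseSd, ar1Phi = p@ar1Phi, driftPerMin = p@driftPerMin,
       seed = p@seed)
}

paramsFromList <- function(l) {
  SimParams(taskAmp = l$taskAmp, couplingRest = l$couplingRest,
            couplingRegulate = l$couplingRegulate, globalAmp = l$globalAmp,
            noiseSd = l$noiseSd, ar1Phi = l$ar1Phi,
            driftPerMin = l$driftPerMin, seed = l$seed)
}

#' Construct an RoiTimeSeries from a sample matrix
#'
#' @param samples numeric matrix, one row per TR and columns
#'   \code{dlpfc}, \code{acc}, \code{nuisance} (in that order).
#' @param design a \linkS4class{BlockDesign} matching the number of rows,
#'   or \code{NULL} when only the TR is known.
#' @param trS repetition time in seconds; taken from \code{design} when
#'   one is given.
#' @param provenance free-form list recording where the data came from
#'   (simulation parameters and seed, or a source file).
#' @return A \linkS4class{RoiTimeSeries}.
#' @export
RoiTimeSeries <- function(samples, design = NULL, trS = NULL,
                          provenance = list()) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    nfStop("invalidArgument",
           "samples must have 3 columns (dlpfc, acc, nuisance)")
  colnames(samples) <- c("dlpfc", "acc", "nuisance")
  n <- nrow(samples)
  cd <- S4Vectors::DataFrame(tIndex = seq_len(n) - 1L)
  md <- list(provenance = provenance)
  if (!is.null(design)) {
    validObject(design)
    if (nSamples(design) != n)
      nfStop("invalidArgument", sprintf(
        "design has %d samples but data has %d rows", nSamples(design), n))
    cd$label <- labelsPerTr(design)
    md$design <- design
    md$trS <- trS(design)
  } else {
    if (is.null(trS))
      nfStop("invalidArgument", "trS is required when no design is given")
    md$trS <- as.numeric(trS)
  }
  new("RoiTimeSeries",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(bold = t(samples)), colData = cd, metadata = md))
}

#' @describeIn RoiTimeSeries TR-by-ROI numeric matrix (columns
#'   \code{dlpfc}, \code{acc}, \code{nuisance}).
#' @export
setMethod("boldMatrix", "RoiTimeSeries", function(x) {
  t(SummarizedExperiment::assay(x, "bold"))
})

#' @rdname RoiTimeSeries
#' @param x an \code{RoiTimeSeries}.
#' @export
setMethod("trS", "RoiTimeSeries", function(x) S4Vectors::metadata(x)$trS)

#' @rdname RoiTimeSeries
#' @export
setMethod("nSamples", "RoiTimeSeries", function(x) ncol(x))

#' Simulate a full participant: one localizer plus four neurofeedback runs
#'
#' Scenarios: a \code{responder} raises the regulate coupling over the
#' four runs following \code{responderCoupling} (default 0.5, 0.7, 0.9,
#' 0.8: learning over runs 1-3 with a final-run fall-off); a
#' \code{non_responder} holds regulate coupling at the resting level for
#' all runs (no learned modulation). The localizer run uses a strong
#' task-driven coupling (default 0.9) so the calibrated feedback range is
#' wide. Per-run seeds derive from \code{seed} via \code{\link{subSeed}}
#' streams 100 (localizer) and 101-104 (nf runs).
#'
#' @param scenario \code{"responder"} or \code{"non_responder"}.
#' @param seed participant-level integer seed.
#' @param baseParams \linkS4class{SimParams} template providing the noise,
#'   drift, task and global settings; couplings and seed are overridden
#'   per run.
#' @param localizerCoupling shared-component loading during localizer TASK
#'   blocks.
#' @param responderCoupling length-4 regulate couplings for runs 1-4 of a
#'   responder.
#' @return List with elements \code{localizer} (an
#'   \linkS4class{RoiTimeSeries}) and \code{nfRuns} (list of four
#'   \linkS4class{RoiTimeSeries}).
#' @examples
#' p <- simulateParticipant("responder", seed = 3)
#' length(p$nfRuns)
#' @export
simulateParticipant <- function(scenario = c("responder", "non_responder"),
                                seed, baseParams = SimParams(),
                                localizerCoupling = 0.9,
                                responderCoupling = c(0.5, 0.7, 0.9, 0.8)) {
  scenario <- tryCatch(match.arg(scenario),
                       error = function(e)
                         nfStop("invalidArgument",
                                paste("unknown scenario:", scenario[1L])))
  stopifnot(length(responderCoupling) == 4L)
  regulate <- switch(scenario,
    responder = responderCoupling,
    non_responder = rep(baseParams@couplingRest, 4L))

  locParams <- baseParams
  locParams@couplingRegulate <- localizerCoupling
  locParams@seed <- as.numeric(subSeed(seed, 100L))
  localizer <- simulateRun(makeLocalizerDesign(), locParams,
                           runId = "localizer")

  nfDesign <- makeNfDesign()
  nfRuns <- lapply(seq_len(4L), function(r) {
    p <- baseParams
    p@couplingRegulate <- regulate[r]
    p@seed <- as.numeric(subSeed(seed, 100L + r))
    simulateRun(nfDesign, p, runId = paste0("nf_run", r))
  })
  list(localizer = localizer, nfRuns = nfRuns)
}
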