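#' @rdname BlockDesign-class
#' @param x,object an object.
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))

#' @rdname BlockDesign-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("baselineR", function(x) standardGeneric("baselineR"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("maxR", function(x) standardGeneric("maxR"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("retainedCoeffs", function(x) standardGeneric("retainedCoeffs"))

#' @rdname FeedbackTrace-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FeedbackTrace-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FeedbackTrace-class
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname WindowedSeries-class
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))

#' @rdname WindowedSeries-class
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("boldMatrix", function(x) standardGeneric("boldMatrix"))
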