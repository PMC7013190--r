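# Experimental block designs: construction, per-TR label expansion, text IO.

#' Construct a BlockDesign
#'
#' Low-level constructor; most users want \code{\link{makeLocalizerDesign}}
#' or \code{\link{makeNfDesign}}. Blocks must be contiguous, start at 0 and
#' strictly alternate between \code{REST} and one active label.
#'
#' @param labels character vector of block labels (\code{REST}, \code{TASK}
#'   or \code{REGULATE}).
#' @param durations numeric vector of block durations in seconds.
#' @param trS repetition time (sampling interval) in seconds.
#' @return A \linkS4class{BlockDesign}.
#' @examples
#' BlockDesign(rep(c("REST", "TASK"), 3), rep(30, 6), trS = 1)
#' @export
BlockDesign <- function(labels, durations, trS = 1) {
  onsets <- cumsum(c(0, durations[-length(durations)]))
  new("BlockDesign",
      labels = as.character(labels),
      onsets = as.numeric(onsets),
      durations = as.numeric(durations),
      trS = as.numeric(trS),
      totalDurationS = sum(durations))
}

#' Functional localizer design: 6 x (30 s REST + 30 s TASK)
#'
#' Thirty-second Rest and Task blocks alternate, six blocks per condition,
#' starting with Rest, sampled at TR = 1 s for a total of 360 volumes. The
#' Task blocks present incongruent Stroop trials used to drive DLPFC-ACC
#' coupling for feedback calibration.
#'
#' @return A \linkS4class{BlockDesign} of 360 samples.
#' @examples
#' nSamples(makeLocalizerDesign())
#' @export
makeLocalizerDesign <- function() {
  BlockDesign(rep(c("REST", "TASK"), 6L), rep(30, 12L), trS = 1)
}

#' Neurofeedback run design: 6 x (25 s REST + 45 s REGULATE)
#'
#' Each neurofeedback run alternates 25 s Rest and 45 s Regulate blocks,
#' six of each, starting with Rest, at TR = 1 s for a total of 420 volumes
#' (7 minutes).
#'
#' @return A \linkS4class{BlockDesign} of 420 samples.
#' @examples
#' table(labelsPerTr(makeNfDesign()))
#' @export
makeNfDesign <- function() {
  BlockDesign(rep(c("REST", "REGULATE"), 6L), rep(c(25, 45), 6L), trS = 1)
}

#' Per-TR condition labels of a design
#'
#' Expands a design to one label per acquired sample. Sample \code{t}
#' (0-based) belongs to the block whose half-open interval
#' \code{[onset, onset + duration)} contains time \code{t * trS}, so block
#' boundaries are never double-assigned.
#'
#' @param design a \linkS4class{BlockDesign}.
#' @return Character vector of length \code{nSamples(design)}.
#' @examples
#' labelsPerTr(makeNfDesign())[1:26]
#' @export
labelsPerTr <- function(design) {
  stopifnot(is(design, "BlockDesign"))
  validObject(design)
  n <- nSamples(design)
  times <- (seq_len(n) - 1L) * design@trS
  idx <- findInterval(times, design@onsets)
  design@labels[idx]
}

#' @rdname BlockDesign-class
#' @export
setMethod("trS", "BlockDesign", function(x) x@trS)

#' @rdname BlockDesign-class
#' @export
setMethod("nSamples", "BlockDesign", function(x) {
  as.integer(round(x@totalDurationS / x@trS))
})

#' @describeIn BlockDesign-class number of blocks.
#' @export
setMethod("length", "BlockDesign", function(x) length(x@labels))

setMethod("show", "BlockDesign", function(object) {
  cat("BlockDesign:", length(object@labels), "blocks,",
      object@totalDurationS, "s at TR", object@trS, "s",
      sprintf("(%d samples)\n", nSamples(object)))
  tab <- table(factor(object@labels, levels = unique(object@labels)))
  for (lab in names(tab))
    cat(sprintf("  %-9s %d blocks, %g s total\n", lab, tab[[lab]],
                sum(object@durations[object@labels == lab])))
})

# Compact string identifying a design; used to check contrast compatibility.
designDigest <- function(design) {
  paste0("tr=", design@trS, ";",
         paste(design@labels, design@durations, sep = ":", collapse = ","))
}

#' Write / read a BlockDesign as plain text
#'
#' The on-disk format is a tab-separated table with one row per block and
#' columns \code{label}, \code{onset_s}, \code{duration_s}, preceded by a
#' header comment line \code{# tr_s=<trS>}. The round trip is lossless.
#'
#' @param design a \linkS4class{BlockDesign}.
#' @param path file path.
#' @return \code{readBlockDesign} returns a \linkS4class{BlockDesign};
#'   \code{writeBlockDesign} returns \code{path} invisibly.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeBlockDesign(makeNfDesign(), p)
#' readBlockDesign(p)
#' @export
writeBlockDesign <- function(design, path) {
  stopifnot(is(design, "BlockDesign"))
  validObject(design)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tr_s=", fmtNum(design@trS)), con)
  writeLines("label\tonset_s\tduration_s", con)
  writeLines(paste(design@labels, fmtNum(design@onsets),
                   fmtNum(design@durations), sep = "\t"), con)
  invisible(path)
}

#' @rdname writeBlockDesign
#' @export
readBlockDesign <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "# tr_s="))
    nfStop("parseError",
           sprintf("%s: line 1: expected header '# tr_s=<value>'", path))
  tr <- suppressWarnings(as.numeric(sub("^# tr_s=", "", lines[1L])))
  if (is.na(tr))
    nfStop("parseError", sprintf("%s: line 1: unparseable tr_s", path))
  if (!identical(lines[2L], "label\tonset_s\tduration_s"))
    nfStop("parseError",
           sprintf("%s: line 2: expected column header", path))
  tab <- utils::read.delim(textConnection(lines[-(1:2)]), header = FALSE,
                           col.names = c("label", "onset_s", "duration_s"),
                           stringsAsFactors = FALSE)
  tab$onset_s <- suppressWarnings(as.numeric(tab$onset_s))
  tab$duration_s <- suppressWarnings(as.numeric(tab$duration_s))
  if (anyNA(tab$onset_s) || anyNA(tab$duration_s))
    nfStop("parseError",
           sprintf("%s: non-numeric onset/duration (line %d)", path,
                   2L + which(is.na(tab$onset_s) | is.na(tab$duration_s))[1L]))
  d <- BlockDesign(tab$label, tab$duration_s, trS = tr)
  if (max(abs(d@onsets - tab$onset_s)) > 1e-9)
    nfStop("parseError",
           sprintf("%s: onsets are not contiguous with durations", path))
  validObject(d)
  d
}
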