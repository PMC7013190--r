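# Internal helpers shared across the package.

#' Derive a reproducible sub-seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed through this
#' scheme: stream \code{k} of seed \code{s} uses
#' \code{(31 * (s mod M) + k * 131071) mod M} with \code{M = 2^31 - 1}
#' (mapped to \code{M} when the result is 0, so the sub-seed is always a
#' positive 32-bit integer). Streams are numbered per participant, per run
#' and per noise source so that any component of a simulation can be
#' regenerated in isolation.
#'
#' @param seed Integer top-level seed.
#' @param stream Non-negative integer stream index.
#' @return A positive integer usable with \code{\link[base]{set.seed}}.
#' @export
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647
  s <- (31 * (abs(seed) %% m) + (stream %% m) * 131071) %% m
  if (s == 0) s <- m
  as.integer(s)
}

# Round half away from zero: the "next integer" convention of the gauge.
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Classed error constructor so callers can distinguish failure modes.
nfStop <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(class, "nfconnError", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Format numbers for the on-disk text formats: 10 significant digits.
fmtNum <- function(x) {
  formatC(x, digits = 10L, format = "g")
}

# Sample labels treated as "active" (non-rest) in a design.
REST_LABEL <- "REST"
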