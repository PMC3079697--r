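#' Round half away from zero
#'
#' Commercial rounding: 2.5 -> 3, -2.5 -> -3. Used for the distinguishable-steps
#' count, where `round()`'s round-half-to-even rule would turn a ratio of
#' exactly 2.5 steps into 2 rather than 3.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, rounded to whole numbers.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 1.49))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a per-subject RNG seed from the master seed and a subject counter.
# Keeps subject-level draws reproducible when subjects are added or reordered.
substream_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(i)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}
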