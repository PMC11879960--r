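# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# configuration errors always name the offending field
stop_config <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' One global seed deterministically spawns per-stage and per-replicate seeds,
#' so pipeline stages and experiment replicates use independent but fully
#' reproducible random streams. The label is folded into the seed with a
#' polynomial string hash followed by a Knuth multiplicative mix, modulo
#' 2^31 - 1, so the result is always a valid `set.seed()` input.
#'
#' @param seed Integer global seed.
#' @param label Character scalar identifying the stage/replicate.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "synth")
#' derive_seed(1, "ga-replicate-3")
derive_seed <- function(seed, label) {
  if (!is_count(seed, min = 0)) {
    stop_config("derive_seed: `seed` must be a single non-negative integer")
  }
  h <- 0
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(((seed %% 2147483647) + (h * 2654435761) %% 2147483647) %% 2147483647)
}
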