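# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a component seed from a master seed
#'
#' A single user-facing seed fans out to per-component seeds so that, e.g.,
#' negative sampling and weight initialisation do not consume the same RNG
#' stream. The rule is a fixed affine map modulo 2^31 - 1, documented so a
#' run can be reproduced from its manifest.
#'
#' @param seed master seed (single integer).
#' @param offset non-negative integer identifying the component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729) %% m)
}

# consistent error classes so callers/tests can distinguish validation
# failures from runtime ones
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("atcct_validation_error", "error")))
}

assert_scalar_int <- function(x, name, min = NULL, max = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop_validation("`%s` must be a single integer, got %s", name, deparse(x))
  if (!is.null(min) && x < min)
    stop_validation("`%s` must be >= %s (got %s)", name, min, x)
  if (!is.null(max) && x > max)
    stop_validation("`%s` must be <= %s (got %s)", name, max, x)
  invisible(as.integer(x))
}
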