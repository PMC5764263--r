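#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## All stochastic entry points funnel through this so a given seed yields
## bit-identical output without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("eegdcm_config_error", "error")))
}

#' @noRd
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("eegdcm_input_error", "error")))
}

#' @noRd
assert_prob <- function(p, what = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_config(what, " must be a single value in [0, 1], got ", format(p))
  invisible(p)
}

## Numerically stable log(sum(exp(x))).
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
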