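#' @importFrom rlang %||% abort
#' @importFrom stats rnorm runif sd var quantile cor predict
#' @importFrom utils head modifyList packageVersion read.delim write.table
NULL

# Deterministic seed fan-out: one top-level seed yields stage-specific seeds so
# stages can be rerun in isolation. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 131) %% 2147483563)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%one_of%` <- function(x, choices) {
  if (!x %in% choices) {
    abort(sprintf("'%s' must be one of: %s", x, paste(choices, collapse = ", ")))
  }
  x
}

# sample sd with the n-1 denominator, NA-intolerant by design
col_sds <- function(m) apply(m, 2, stats::sd)
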