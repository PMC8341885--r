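#' @keywords internal
"_PACKAGE"

# Deterministic seed splitting: one user-facing seed fans out into
# independent streams (items, outcome, replicates) via a Lehmer step,
# kept below 2^31 - 1 so the result is always a valid integer seed.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + stream) %% m)
}

# z quantile for a two-sided interval at `level`
ci_z <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

check_outcomes <- function(outcomes, require_both = TRUE) {
  if (anyNA(outcomes)) {
    stop("`outcomes` must not contain missing values", call. = FALSE)
  }
  if (is.logical(outcomes)) outcomes <- as.integer(outcomes)
  if (!is_binary01(outcomes)) {
    stop("`outcomes` must be coded 0/1", call. = FALSE)
  }
  if (require_both && length(unique(outcomes)) < 2L) {
    stop("both outcome classes (0 and 1) must be present", call. = FALSE)
  }
  outcomes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
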