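#' Published count tables packaged as fixtures
#'
#' The published risk-group and cut-score panels for the combined
#' development (N = 17,630) and validation (N = 18,024) cohorts, as printed
#' counts, together with the confusion matrices at cut scores 6 and 9
#' derived by pooling the band counts across cohorts. All totals are
#' verified on load (17,630; 18,024; 35,654 participants; 288 events);
#' a mismatch signals a packaging error.
#'
#' @return A `fixture_set` list:
#' \describe{
#'   \item{development_bands, validation_bands}{per-band `band`, `range`,
#'     `controls`, `attempters`}
#'   \item{cut6_development, cut6_validation}{2x2 split at score >= 6:
#'     `controls_below`, `attempts_below`, `controls_above`, `attempts_above`}
#'   \item{confusion_cut6, confusion_cut9}{pooled `c(tp, fp, fn, tn)`}
#'   \item{n_development, n_validation, n_total, n_events}{totals}
#' }
#' @export
load_fixtures <- function() {
  bands <- c("Lowest risk", "Low risk", "Moderate risk",
             "High risk", "Very high risk", "Highest risk")
  ranges <- c("0-2", "3-5", "6-8", "9-11", "12-14", ">=15")
  dev <- data.frame(
    band = bands, range = ranges,
    controls = c(8055L, 7095L, 1630L, 507L, 141L, 73L),
    attempters = c(2L, 24L, 34L, 28L, 21L, 20L),
    stringsAsFactors = FALSE
  )
  val <- data.frame(
    band = bands, range = ranges,
    controls = c(7844L, 7332L, 1845L, 600L, 176L, 68L),
    attempters = c(2L, 24L, 36L, 41L, 24L, 32L),
    stringsAsFactors = FALSE
  )
  cut6_dev <- c(controls_below = 15150L, attempts_below = 26L,
                controls_above = 2351L, attempts_above = 103L)
  cut6_val <- c(controls_below = 15176L, attempts_below = 26L,
                controls_above = 2689L, attempts_above = 133L)

  high <- bands[4:6]  # bands at or above score 9
  mod_up <- bands[3:6]  # bands at or above score 6
  pool <- rbind(dev, val)
  conf_at <- function(flagged_bands) {
    tp <- sum(pool$attempters[pool$band %in% flagged_bands])
    fp <- sum(pool$controls[pool$band %in% flagged_bands])
    fn <- sum(pool$attempters) - tp
    tn <- sum(pool$controls) - fp
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  fx <- list(
    development_bands = dev,
    validation_bands = val,
    cut6_development = cut6_dev,
    cut6_validation = cut6_val,
    confusion_cut6 = conf_at(mod_up),
    confusion_cut9 = conf_at(high),
    n_development = sum(dev$controls) + sum(dev$attempters),
    n_validation = sum(val$controls) + sum(val$attempters),
    n_total = sum(pool$controls) + sum(pool$attempters),
    n_events = sum(pool$attempters)
  )

  # checksum against the published totals
  ok <- fx$n_development == 17630L &&
    fx$n_validation == 18024L &&
    fx$n_total == 35654L &&
    fx$n_events == 288L &&
    sum(cut6_dev) == 17630L && sum(cut6_val) == 18024L &&
    cut6_dev[["attempts_below"]] + cut6_dev[["attempts_above"]] == 129L &&
    cut6_val[["attempts_below"]] + cut6_val[["attempts_above"]] == 159L &&
    sum(fx$confusion_cut6) == 35654L && sum(fx$confusion_cut9) == 35654L
  if (!ok) stop("packaging error: fixture totals do not match published totals",
                call. = FALSE)
  class(fx) <- "fixture_set"
  fx
}

#' Expand per-band counts to a band-resolution score vector
#'
#' Reconstructs per-participant `(score, outcome)` pairs from band counts,
#' placing every participant at their band's lower bound. Scores are only
#' band-resolved, so analyses that flag whole bands (cut scores at band
#' boundaries, band-level capture curves) are exact; within-band detail is
#' not recoverable.
#'
#' @param bands A band-count data.frame (as in [load_fixtures()]).
#' @param definition Definition supplying band lower bounds (default
#'   [drs_definition()]).
#' @return `data.frame` with `score` and `outcome` columns.
#' @export
expand_band_counts <- function(bands, definition = drs_definition()) {
  lower <- definition$bands$lower[match(bands$band, definition$bands$name)]
  if (anyNA(lower)) {
    stop("band names do not match the definition's bands", call. = FALSE)
  }
  score <- rep(lower, times = bands$controls + bands$attempters)
  outcome <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    c(rep(0L, bands$controls[i]), rep(1L, bands$attempters[i]))
  }))
  data.frame(score = score, outcome = outcome)
}
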