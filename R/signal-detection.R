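#' Confusion counts at a score cutoff
#'
#' A test is positive when `score >= cutoff` (cutoffs label score levels
#' "at or above k").
#'
#' @param scores Integer score vector.
#' @param outcomes Binary 0/1 vector (1 = case).
#' @param cutoff Integer threshold.
#' @return Named integer vector `c(tp, fp, fn, tn)`; counts sum to `length(scores)`.
#' @export
confusion_at_cut <- function(scores, outcomes, cutoff) {
  outcomes <- check_outcomes(outcomes, require_both = FALSE)
  stopifnot(length(scores) == length(outcomes))
  if (length(scores) == 0L) stop("cohort must be non-empty", call. = FALSE)
  pos <- scores >= cutoff
  c(tp = sum(pos & outcomes == 1),
    fp = sum(pos & outcomes == 0),
    fn = sum(!pos & outcomes == 1),
    tn = sum(!pos & outcomes == 0))
}

#' Screening metrics at a single cutoff
#'
#' Computes the full set of screening statistics from a 2x2 confusion
#' matrix: sensitivity, specificity, Youden's J, predictive values,
#' efficiency (raw accuracy), the chance-corrected quality indices, and the
#' odds ratio with Wald interval.
#'
#' The quality indices rescale the predictive values against chance onto a
#' kappa-like `[-1, 1]` scale, so that a perfect test scores 1 and a test
#' independent of outcome scores 0 regardless of prevalence:
#' \deqn{k(1) = (NPV - (1 - P)) / P,\quad k(0) = (PPV - P) / (1 - P),}
#' and `k(0.5)` is the harmonic mean of the two (0 when both vanish). `P` is
#' prevalence and `Q` the positivity rate.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts; both outcome margins
#'   must be non-empty.
#' @param cutoff Optional cutoff label carried into the result.
#' @param level Confidence level for the odds-ratio interval.
#' @return One-row `data.frame` of class `cutpoint_metrics` with columns
#'   `cutoff`, `tp`, `fp`, `fn`, `tn`, `prevalence`, `positivity`,
#'   `sensitivity`, `specificity`, `youden`, `ppv`, `npv`, `efficiency`,
#'   `k1`, `k0`, `k05`, `odds_ratio`, `or_lower`, `or_upper`.
#' @examples
#' cutpoint_metrics(236, 5040, 52, 30326, cutoff = 6)
#' @export
cutpoint_metrics <- function(tp, fp, fn, tn, cutoff = NA_integer_,
                             level = 0.95) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (tp + fn == 0) {
    stop("undefined sensitivity / k(1): no cases (tp + fn = 0)", call. = FALSE)
  }
  if (tn + fp == 0) {
    stop("undefined specificity / k(0): no controls (tn + fp = 0)", call. = FALSE)
  }
  p <- (tp + fn) / n
  q <- (tp + fp) / n
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  k1 <- if (is.na(npv)) NA_real_ else (npv - (1 - p)) / p
  k0 <- if (is.na(ppv)) NA_real_ else (ppv - p) / (1 - p)
  k05 <- if (is.na(k1) || is.na(k0)) {
    NA_real_
  } else if (k1 + k0 == 0) {
    0
  } else {
    2 * k1 * k0 / (k1 + k0)
  }
  or <- or_wald(tp, fp, fn, tn, level = level)
  out <- data.frame(
    cutoff = as.integer(cutoff), tp = tp, fp = fp, fn = fn, tn = tn,
    prevalence = p, positivity = q,
    sensitivity = se, specificity = sp, youden = se + sp - 1,
    ppv = ppv, npv = npv, efficiency = (tp + tn) / n,
    k1 = k1, k0 = k0, k05 = k05,
    odds_ratio = or$or, or_lower = or$lower, or_upper = or$upper
  )
  class(out) <- c("cutpoint_metrics", "data.frame")
  out
}

# Wald OR and CI from confusion counts (a = tp, b = fp, c = fn, d = tn);
# any empty cell yields an infinite / zero estimate with NA interval.
or_wald <- function(tp, fp, fn, tn, level = 0.95) {
  if (min(tp, fp, fn, tn) == 0) {
    or <- if (fp == 0 || fn == 0) Inf else 0
    if (tp == 0 && (fp == 0 || fn == 0)) or <- NaN
    return(list(or = or, lower = NA_real_, upper = NA_real_))
  }
  or <- (tp * tn) / (fp * fn)
  se_log <- sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn)
  z <- ci_z(level)
  list(or = or,
       lower = exp(log(or) - z * se_log),
       upper = exp(log(or) + z * se_log))
}

#' Screening-metric table over a cutoff sweep
#'
#' Applies [confusion_at_cut()] and [cutpoint_metrics()] at each cutoff and
#' stacks the rows, sorted by cutoff.
#'
#' @inheritParams confusion_at_cut
#' @param cutoffs Integer vector of thresholds.
#' @param level Confidence level for odds-ratio intervals.
#' @return `data.frame` of class `cutpoint_table`, one row per cutoff.
#' @export
cutpoint_table <- function(scores, outcomes, cutoffs = NULL, level = 0.95) {
  outcomes <- check_outcomes(outcomes)
  if (is.null(cutoffs)) cutoffs <- seq(1L, max(scores))
  cutoffs <- sort(unique(as.integer(cutoffs)))
  rows <- lapply(cutoffs, function(k) {
    cm <- confusion_at_cut(scores, outcomes, k)
    cutpoint_metrics(cm[["tp"]], cm[["fp"]], cm[["fn"]], cm[["tn"]],
                     cutoff = k, level = level)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutpoint_table", class(out))
  out
}

#' Cutoff maximizing Youden's J
#'
#' Ties are broken toward the lower cutoff (the more sensitive operating
#' point).
#'
#' @param table A [cutpoint_table()] (or any data.frame with `cutoff` and
#'   `youden` columns).
#' @return The optimal integer cutoff.
#' @export
optimal_cut <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("cutoff", "youden") %in% names(table)))
  table <- table[order(table$cutoff), , drop = FALSE]
  table$cutoff[which.max(table$youden)]
}

#' Concentration of risk: events captured in the top score fractions
#'
#' For each requested top fraction `q`, flags the participants with the
#' highest scores — whole score levels only, never splitting a tied score —
#' choosing the smallest threshold whose flagged fraction does not exceed
#' `q` when attainable (otherwise the smallest attainable flagged fraction
#' above `q`), and reports the fraction of all events that occur among the
#' flagged.
#'
#' @inheritParams confusion_at_cut
#' @param top_fractions Fractions in `(0, 1]`.
#' @return `data.frame` of class `capture_curve` with columns `top_fraction`,
#'   `threshold`, `flagged_fraction`, `events_captured`.
#' @export
concentration_of_risk <- function(scores, outcomes,
                                  top_fractions = c(0.01, 0.05, 0.15, 1)) {
  outcomes <- check_outcomes(outcomes, require_both = FALSE)
  stopifnot(length(scores) == length(outcomes))
  if (any(top_fractions <= 0 | top_fractions > 1)) {
    stop("`top_fractions` must lie in (0, 1]", call. = FALSE)
  }
  n_events <- sum(outcomes == 1)
  if (n_events == 0L) {
    stop("undefined capture: cohort has no events", call. = FALSE)
  }
  n <- length(scores)
  levels <- sort(unique(scores))
  frac_at <- vapply(levels, function(s) sum(scores >= s) / n, numeric(1))
  # frac_at is non-increasing in the score level
  rows <- lapply(sort(top_fractions), function(q) {
    ok <- which(frac_at <= q)
    idx <- if (length(ok)) min(ok) else length(levels)
    thr <- levels[idx]
    flagged <- scores >= thr
    data.frame(top_fraction = q, threshold = thr,
               flagged_fraction = mean(flagged),
               events_captured = sum(outcomes[flagged] == 1) / n_events)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("capture_curve", class(out))
  out
}
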