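#' Logistic calibration of a binary outcome on a risk score
#'
#' Fits `logit P(y = 1) = alpha + beta * x` by maximum likelihood (iteratively
#' reweighted least squares via [stats::glm()]), and reports the per-point
#' odds ratio `exp(beta)` with a Wald interval, log-likelihoods, and
#' Nagelkerke's pseudo R-squared
#' \deqn{R^2_N = \frac{1 - \exp(2(LL_0 - LL_1)/n)}{1 - \exp(2 LL_0 / n)}.}
#'
#' @param x Numeric predictor (e.g. the checklist score).
#' @param y Binary 0/1 outcome; both classes must be present.
#' @param level Confidence level for the odds-ratio interval.
#' @return A `logistic_fit`: list with `intercept`, `slope`, `slope_se`,
#'   `odds_ratio`, `or_lower`, `or_upper`, `log_likelihood`,
#'   `null_log_likelihood`, `nagelkerke_r2`, `n`, `converged`, `separation`.
#' @export
fit_logistic <- function(x, y, level = 0.95) {
  y <- check_outcomes(y)
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[2L]
  z <- ci_z(level)
  n <- length(y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(y ~ 1, family = stats::binomial())))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  r2 <- cox_snell / (1 - exp(2 * ll0 / n))

  structure(
    list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
         slope_se = unname(se),
         odds_ratio = exp(unname(cf[2L])),
         or_lower = exp(unname(cf[2L]) - z * se),
         or_upper = exp(unname(cf[2L]) + z * se),
         log_likelihood = ll1, null_log_likelihood = ll0,
         nagelkerke_r2 = r2, n = n,
         converged = fit$converged && !separation,
         separation = separation,
         level = level),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d): intercept %.2f, slope %.3f (SE %.3f)\n",
              x$n, x$intercept, x$slope, x$slope_se))
  cat(sprintf("  OR per point %.2f (%g%% CI %.2f-%.2f), Nagelkerke R2 %.2f\n",
              x$odds_ratio, 100 * x$level, x$or_lower, x$or_upper,
              x$nagelkerke_r2))
  if (!x$converged) cat("  warning: fit did not converge",
                        if (x$separation) "(complete separation suspected)",
                        "\n")
  invisible(x)
}

#' 2x2 contingency analysis: rates, RR, OR, Wald CIs and chi-squared
#'
#' Cell layout: `a` = events among exposed, `b` = non-events among exposed,
#' `c` = events among unexposed, `d` = non-events among unexposed. Intervals
#' are Wald on the log scale; the chi-squared test is Pearson's without
#' continuity correction.
#'
#' @param a,b,c,d Non-negative integer cell counts; each margin positive.
#' @param correction Apply the Haldane-Anscombe +0.5 correction to all cells
#'   when any cell is zero? Default `FALSE` (a zero cell then yields an
#'   infinite or zero estimate with `NA` interval).
#' @param level Confidence level.
#' @return A `contingency_result`: list with the counts, `rate_exposed`,
#'   `rate_unexposed`, `risk_ratio`, `rr_lower`, `rr_upper`, `odds_ratio`,
#'   `or_lower`, `or_upper`, `chi_square`, `p`.
#' @examples
#' two_by_two(32, 68, 2, 7844)   # OR 1845.6, Wald CI ~ 433.6-7855.3
#' @export
two_by_two <- function(a, b, c, d, correction = FALSE, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("each margin of the 2x2 table must be positive", call. = FALSE)
  }
  rate_exp <- a / (a + b)
  rate_unexp <- c / (c + d)
  z <- ci_z(level)

  a_ <- a; b_ <- b; c_ <- c; d_ <- d
  if (correction && min(counts) == 0) {
    a_ <- a + 0.5; b_ <- b + 0.5; c_ <- c + 0.5; d_ <- d + 0.5
  }
  if (min(a_, b_, c_, d_) == 0) {
    or <- if (b_ == 0 || c_ == 0) Inf else 0
    rr <- if (c_ == 0) Inf else (a_ / (a_ + b_)) / (c_ / (c_ + d_))
    or_ci <- rr_ci <- c(NA_real_, NA_real_)
  } else {
    or <- (a_ * d_) / (b_ * c_)
    se_or <- sqrt(1 / a_ + 1 / b_ + 1 / c_ + 1 / d_)
    or_ci <- exp(log(or) + c(-1, 1) * z * se_or)
    rr <- (a_ / (a_ + b_)) / (c_ / (c_ + d_))
    se_rr <- sqrt(1 / a_ - 1 / (a_ + b_) + 1 / c_ - 1 / (c_ + d_))
    rr_ci <- exp(log(rr) + c(-1, 1) * z * se_rr)
  }

  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))

  structure(
    list(a = a, b = b, c = c, d = d,
         rate_exposed = rate_exp, rate_unexposed = rate_unexp,
         risk_ratio = rr, rr_lower = rr_ci[1L], rr_upper = rr_ci[2L],
         odds_ratio = or, or_lower = or_ci[1L], or_upper = or_ci[2L],
         chi_square = unname(chi$statistic), p = chi$p.value,
         level = level),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2: exposed %d/%d (%.2f%%), unexposed %d/%d (%.2f%%)\n",
              x$a, x$a + x$b, 100 * x$rate_exposed,
              x$c, x$c + x$d, 100 * x$rate_unexposed))
  cat(sprintf("  RR %.1f (%.1f-%.1f), OR %.1f (%.1f-%.1f), X2 %.1f, p %.3g\n",
              x$risk_ratio, x$rr_lower, x$rr_upper,
              x$odds_ratio, x$or_lower, x$or_upper, x$chi_square, x$p))
  invisible(x)
}

#' Risk-group table from per-band event counts
#'
#' Core contingency engine shared by [risk_group_table()] and the count-mode
#' pipeline: takes per-band control/event counts (bands ordered lowest
#' first) and computes rates, percentages, and RR/OR versus the lowest band
#' via [two_by_two()].
#'
#' @param bands `data.frame` with columns `band`, `controls`, `attempters`
#'   (one row per band, lowest-risk band first; optional `range` label).
#' @param level Confidence level for the intervals.
#' @return `data.frame` of class `risk_group_table`: per band, counts,
#'   `total`, `pct_sample`, `cum_pct`, `rate`, `risk_ratio`, `odds_ratio`,
#'   `or_lower`, `or_upper`, `p` (reference band: RR = OR = 1, NA interval).
#' @export
risk_group_stats <- function(bands, level = 0.95) {
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  stopifnot(all(c("band", "controls", "attempters") %in% names(bands)))
  n_total <- sum(bands$controls) + sum(bands$attempters)
  ref <- bands[1L, ]
  if (ref$controls + ref$attempters == 0) {
    stop("reference (lowest) band is empty", call. = FALSE)
  }
  total <- bands$controls + bands$attempters
  out <- data.frame(
    band = bands$band,
    range = bands$range %||% NA_character_,
    controls = bands$controls, attempters = bands$attempters,
    total = total,
    pct_sample = 100 * total / n_total,
    cum_pct = 100 * cumsum(total) / n_total,
    rate = bands$attempters / total,
    risk_ratio = NA_real_, odds_ratio = NA_real_,
    or_lower = NA_real_, or_upper = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE
  )
  out$risk_ratio[1L] <- 1
  out$odds_ratio[1L] <- 1
  if (nrow(bands) > 1L) {
    for (i in seq(2L, nrow(bands))) {
      if (total[i] == 0L) next  # unoccupied band: no comparison
      tt <- two_by_two(bands$attempters[i], bands$controls[i],
                       ref$attempters, ref$controls, level = level)
      out$risk_ratio[i] <- tt$risk_ratio
      out$odds_ratio[i] <- tt$odds_ratio
      out$or_lower[i] <- tt$or_lower
      out$or_upper[i] <- tt$or_upper
      out$p[i] <- tt$p
    }
  }
  attr(out, "n_total") <- n_total
  class(out) <- c("risk_group_table", "data.frame")
  out
}

#' Risk-group contingency table for a scored cohort
#'
#' Tabulates participants by risk band and compares each band's event odds
#' and risk against the lowest band.
#'
#' @param scored A `scored_cohort` from [score_cohort()].
#' @param level Confidence level for the intervals.
#' @return A [risk_group_stats()] table, one row per band of the
#'   definition (empty upper bands are kept with zero counts).
#' @export
risk_group_table <- function(scored, level = 0.95) {
  stopifnot(inherits(scored, "scored_cohort"))
  definition <- attr(scored, "definition")
  tab <- table(scored$band, factor(scored$outcome, levels = c(0, 1)))
  bands <- definition$bands
  rng <- ifelse(is.na(bands$upper),
                paste0(">=", bands$lower),
                paste0(bands$lower, "-", bands$upper))
  counts <- data.frame(band = rownames(tab),
                       range = rng[match(rownames(tab), bands$name)],
                       controls = as.integer(tab[, "0"]),
                       attempters = as.integer(tab[, "1"]),
                       stringsAsFactors = FALSE)
  # drop trailing bands with no observations, but never the reference band
  occupied <- which(counts$controls + counts$attempters > 0)
  counts <- counts[seq_len(max(c(1L, occupied))), , drop = FALSE]
  risk_group_stats(counts, level = level)
}

#' Per-subgroup AUC analysis
#'
#' Scores the cohort and computes a DeLong AUC within each level of a
#' subgroup column; levels lacking either outcome class are reported as
#' skipped rather than failing the analysis.
#'
#' @param cohort A [cohort_table()].
#' @param definition A [checklist_definition()].
#' @param group_column Name of the subgroup label column.
#' @param level Confidence level.
#' @return `data.frame`: one row per subgroup with `group`, `n`, `n_cases`,
#'   `auc`, `se`, `ci_lower`, `ci_upper`, `skipped`.
#' @export
subgroup_auc <- function(cohort, definition, group_column, level = 0.95) {
  cohort <- cohort_table(cohort, definition)
  if (!group_column %in% names(cohort)) {
    stop("group column `", group_column, "` not found in cohort", call. = FALSE)
  }
  scored <- score_cohort(cohort, definition)
  groups <- split(scored, scored[[group_column]])
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    if (length(unique(sub$outcome)) < 2L ||
        sum(sub$outcome == 1) < 2L || sum(sub$outcome == 0) < 2L) {
      return(data.frame(group = g, n = nrow(sub), n_cases = sum(sub$outcome),
                        auc = NA_real_, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    res <- auc_delong(sub$score, sub$outcome, level = level)
    data.frame(group = g, n = nrow(sub), n_cases = res$n_cases,
               auc = res$auc, se = res$se,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
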