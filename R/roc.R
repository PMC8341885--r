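#' Rank-based AUC (tie-corrected Mann-Whitney probability)
#'
#' The area under the ROC curve computed as the probability that a randomly
#' chosen case outscores a randomly chosen control, counting exact ties as
#' 1/2. Equivalent to the normalized Mann-Whitney U statistic with midranks;
#' the 1/2 tie convention matters for integer checklist scores, where ties
#' are ubiquitous.
#'
#' @param scores Numeric vector.
#' @param outcomes Binary 0/1 vector of the same length (1 = case).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1))   # 1
#' auc_rank(c(3, 1, 2, 3), c(0, 0, 1, 1))   # 0.625
#' @export
auc_rank <- function(scores, outcomes) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(scores) == length(outcomes))
  if (anyNA(scores)) stop("`scores` must not contain NA", call. = FALSE)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  r <- rank(scores)  # midranks implement the 1/2 tie convention
  u <- sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' AUC of a binary (yes/no) rater from its confusion counts
#'
#' A rater that issues only a positive/negative call has a one-point ROC
#' curve; its AUC is the mean of sensitivity and specificity,
#' `AUC = (Se + Sp) / 2`.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts; both outcome margins
#'   must be non-empty.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_binary_rater(1685, 5996, 1556, 13262)  # 0.60 to 2 dp
#' @export
auc_binary_rater <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn < 1) stop("undefined AUC: no cases (tp + fn = 0)", call. = FALSE)
  if (tn + fp < 1) stop("undefined AUC: no controls (tn + fp = 0)", call. = FALSE)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  (se + sp) / 2
}

#' AUC with DeLong standard error and confidence interval
#'
#' Computes the tie-corrected AUC together with its DeLong variance (from
#' placement values / structural components) and a Wald confidence interval
#' on the AUC scale, truncated to `[0, 1]`. With `logit = TRUE` the interval
#' is instead formed on the logit scale and back-transformed.
#'
#' @param scores Numeric vector.
#' @param outcomes Binary 0/1 vector (1 = case); at least 2 of each class.
#' @param level Confidence level, default 0.95.
#' @param logit Use a logit-scale interval? Default `FALSE` (symmetric
#'   intervals on the AUC scale).
#' @return An `auc_result`: list with `auc`, `se`, `ci_lower`, `ci_upper`,
#'   `level`, `n_cases`, `n_controls`.
#' @export
auc_delong <- function(scores, outcomes, level = 0.95, logit = FALSE) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(scores) == length(outcomes))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 < 2 || n0 < 2) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  roc <- pROC::roc(response = outcomes, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  v <- suppressWarnings(pROC::var(roc, method = "delong"))
  se <- sqrt(max(v, 0))
  z <- ci_z(level)
  if (se == 0) {
    warning("zero DeLong variance (degenerate AUC); CI collapses to a point",
            call. = FALSE)
    ci <- c(auc, auc)
  } else if (logit) {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    ci <- stats::plogis(lg + c(-1, 1) * z * se_lg)
  } else {
    ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  }
  structure(
    list(auc = auc, se = se, ci_lower = ci[1L], ci_upper = ci[2L],
         level = level, n_cases = n1, n_controls = n0),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.4f), %g%% CI %.3f-%.3f  [%d cases / %d controls]\n",
              x$auc, x$se, 100 * x$level, x$ci_lower, x$ci_upper,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same participants, using
#' the DeLong covariance of the paired placement values. A zero-variance
#' difference (e.g. one score a monotone transform of the other, so the
#' ranks coincide) is reported as an exact tie: `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Numeric vectors aligned to the same participants.
#' @param outcomes Binary 0/1 vector (1 = case).
#' @return List with `z`, `p` (two-sided), `auc_a`, `auc_b`.
#' @export
auc_delong_paired <- function(scores_a, scores_b, outcomes) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(scores_a) == length(outcomes),
            length(scores_b) == length(outcomes))
  auc_a <- auc_rank(scores_a, outcomes)
  auc_b <- auc_rank(scores_b, outcomes)
  roc_a <- pROC::roc(response = outcomes, predictor = scores_a,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(response = outcomes, predictor = scores_b,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
  tst <- suppressWarnings(
    try(pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE),
        silent = TRUE)
  )
  if (inherits(tst, "try-error") ||
      !is.finite(unname(tst$statistic)) || !is.finite(tst$p.value)) {
    z <- 0
    p <- 1
  } else {
    z <- unname(tst$statistic)
    p <- tst$p.value
  }
  list(z = z, p = p, auc_a = auc_a, auc_b = auc_b)
}
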