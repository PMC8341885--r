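#' Default per-item prevalence vector for the packaged checklist
#'
#' A documented engineering default: plausible adult general-population
#' prevalences for the 23 packaged items, chosen so that the weighted score
#' has mean close to 3.3 before any dependence is introduced. They are a
#' stand-in for the study cohorts' (unpublished) per-item rates, not
#' estimates of them.
#'
#' @return Named numeric vector of prevalences in (0, 1), one per item of
#'   [drs_definition()].
#' @export
default_item_prevalences <- function() {
  c(suicide_attempt_lifetime   = 0.026,
    hospitalization_past_year  = 0.010,
    hospitalization_lifetime   = 0.050,
    nssi_lifetime              = 0.030,
    suicidal_ideation_past_year = 0.030,
    suicidal_ideation_lifetime = 0.100,
    bpd_lifetime               = 0.060,
    unemployed                 = 0.100,
    poor_perceived_health      = 0.120,
    lower_income               = 0.350,
    child_physical_abuse       = 0.080,
    sexual_abuse_assault       = 0.100,
    severe_sleep_problems      = 0.100,
    ptsd_past_year             = 0.050,
    mood_disorder_lifetime     = 0.300,
    violence_incarceration     = 0.120,
    weekly_binges              = 0.100,
    current_smoker             = 0.250,
    substance_use_disorder     = 0.100,
    younger_than_35            = 0.300,
    less_than_hs_education     = 0.140,
    sexual_minority            = 0.020,
    female_sex                 = 0.580)
}

# Single-factor loading calibrated once (via calibrate_loading) so the
# default weighted score has SD ~= 2.5; see the methods vignette.
DEFAULT_LOADING <- 0.40

#' Specification of a synthetic cohort
#'
#' The generator draws correlated binary risk factors from a single-factor
#' Gaussian threshold (copula) model: participant latent severity
#' `L ~ N(0,1)`; item j is present iff
#' `loading * L + sqrt(1 - loading^2) * e_j > qnorm(1 - p_j)`, which leaves
#' the marginal prevalence at `p_j` for any loading while inducing positive
#' inter-item correlation and a right-skewed weighted score. The binary
#' outcome is then drawn from `Bernoulli(plogis(intercept + slope * score))`.
#'
#' @param n Number of participants.
#' @param item_prevalences Named vector of marginal prevalences in (0, 1),
#'   one per definition item.
#' @param loading Latent factor loading in `[0, 1)`.
#' @param intercept,slope Outcome logistic model on the score.
#' @param seed Integer seed; all randomness flows from it.
#' @param definition A [checklist_definition()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n, item_prevalences, loading, intercept, slope,
                        seed = 1L, definition = drs_definition()) {
  stopifnot(inherits(definition, "checklist_definition"))
  ids <- definition$items$id
  if (is.null(names(item_prevalences)) ||
      !setequal(names(item_prevalences), ids)) {
    stop("`item_prevalences` must be named with exactly the definition's item ids",
         call. = FALSE)
  }
  item_prevalences <- item_prevalences[ids]
  if (any(item_prevalences <= 0 | item_prevalences >= 1)) {
    stop("item prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  if (loading < 0 || loading >= 1) {
    stop("`loading` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(n >= 1, is.finite(intercept), is.finite(slope))
  structure(
    list(n = as.integer(n), item_prevalences = item_prevalences,
         loading = loading, intercept = intercept, slope = slope,
         seed = as.integer(seed), definition = definition),
    class = "cohort_spec"
  )
}

#' Default synthetic cohort specification
#'
#' The conditions the package's simulation experiments assume: 18,024
#' participants, the packaged prevalences, the factor loading calibrated so
#' the score SD is ~2.5 (mean ~3.3, right-skewed), and a rare outcome from
#' the logistic model `plogis(-7.15 + 0.41 * score)` (prevalence ~0.7-0.9%).
#'
#' @param n Cohort size (default 18,024).
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n = 18024L, seed = 1L) {
  cohort_spec(n = n,
              item_prevalences = default_item_prevalences(),
              loading = DEFAULT_LOADING,
              intercept = -7.15, slope = 0.41,
              seed = seed, definition = drs_definition())
}

#' Simulate a cohort from a specification
#'
#' Fully reproducible from `spec$seed`; item and outcome draws use separate
#' derived streams, so the item pattern is unchanged if only the outcome
#' model changes.
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort_table()] with `item_<id>` columns, `outcome`, and
#'   `participant_id`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$item_prevalences
  j <- length(p)
  lam <- spec$loading

  set.seed(split_seed(spec$seed, 1L))
  l <- stats::rnorm(spec$n)
  e <- matrix(stats::rnorm(spec$n * j), nrow = spec$n, ncol = j)
  latent <- lam * l + sqrt(1 - lam^2) * e
  thresh <- stats::qnorm(1 - p)
  x <- sweep(latent, 2L, thresh, `>`) + 0L
  colnames(x) <- names(p)

  score <- as.integer(x %*% spec$definition$items$weight)
  set.seed(split_seed(spec$seed, 2L))
  pr <- stats::plogis(spec$intercept + spec$slope * score)
  outcome <- stats::rbinom(spec$n, 1L, pr)

  data <- data.frame(participant_id = sprintf("S%06d", seq_len(spec$n)),
                     stringsAsFactors = FALSE)
  for (nm in names(p)) data[[paste0("item_", nm)]] <- x[, nm]
  data$outcome <- outcome
  cohort_table(data, spec$definition)
}

#' Calibrate the latent loading to a target score SD
#'
#' The score SD is non-decreasing in the loading (more dependence, more
#' spread), so a bisection on `[0, 0.95]` converges; each evaluation
#' simulates `n_sim` participants from a fixed internal seed.
#'
#' @param spec A [cohort_spec()]; its `loading` is ignored.
#' @param target_sd Target standard deviation of the weighted score.
#' @param tol Convergence tolerance on the SD scale (default 0.05).
#' @param n_sim Simulation size per evaluation (default 50,000).
#' @return The calibrated loading.
#' @export
calibrate_loading <- function(spec, target_sd, tol = 0.05, n_sim = 50000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  sd_at <- function(lam) {
    s <- cohort_spec(n = n_sim, item_prevalences = spec$item_prevalences,
                     loading = lam, intercept = spec$intercept,
                     slope = spec$slope, seed = 761304011L,
                     definition = spec$definition)
    summary(score_cohort(simulate_cohort(s), s$definition))$sd
  }
  lo <- 0; hi <- 0.95
  sd_lo <- sd_at(lo); sd_hi <- sd_at(hi)
  if (target_sd < sd_lo - tol || target_sd > sd_hi + tol) {
    stop(sprintf("target SD %.2f unreachable: achievable range is [%.2f, %.2f]",
                 target_sd, sd_lo, sd_hi), call. = FALSE)
  }
  if (target_sd <= sd_lo) return(lo)
  if (target_sd >= sd_hi) return(hi)
  for (it in seq_len(30L)) {
    mid <- (lo + hi) / 2
    sd_mid <- sd_at(mid)
    if (abs(sd_mid - target_sd) <= tol) return(mid)
    if (sd_mid < target_sd) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
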