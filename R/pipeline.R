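#' End-to-end validation run
#'
#' Scores a cohort against a definition and assembles the full evaluation
#' report: overall DeLong AUC, logistic calibration of outcome on score,
#' risk-group contingency table, signal-detection cut-point table,
#' concentration-of-risk capture curve, optional per-subgroup AUCs, and a
#' provenance block. Deterministic given its inputs.
#'
#' Alternatively, a pre-tabulated band-count table (`counts`) can be
#' supplied instead of a raw cohort ("count mode"); the report then covers
#' the statistics recoverable from counts (risk groups, band-boundary
#' cut-points, band-level capture curve).
#'
#' @param cohort A [cohort_table()], or `NULL` in count mode.
#' @param definition A [checklist_definition()].
#' @param counts Optional band-count data.frame (`band`, `controls`,
#'   `attempters`) for count mode.
#' @param group_columns Character vector of subgroup columns to analyse.
#' @param cutoffs Integer cutoffs for the sweep (default: all attained).
#' @param top_fractions Capture-curve fractions.
#' @param level Confidence level.
#' @return A `validation_report` list.
#' @export
run_validate <- function(cohort = NULL, definition = drs_definition(),
                         counts = NULL, group_columns = character(),
                         cutoffs = NULL,
                         top_fractions = c(0.01, 0.05, 0.15, 1),
                         level = 0.95) {
  if (is.null(cohort) && is.null(counts)) {
    stop("supply either a cohort or a band-count table", call. = FALSE)
  }
  if (!is.null(counts)) {
    expanded <- expand_band_counts(counts, definition)
    if (sum(expanded$outcome) == 0L) {
      stop("cohort has zero events: AUC, logistic fit and capture curve are undefined",
           call. = FALSE)
    }
    band_cuts <- definition$bands$lower[definition$bands$lower > 0]
    report <- list(
      mode = "counts",
      risk_groups = risk_group_stats(counts, level = level),
      cutpoints = cutpoint_table(expanded$score, expanded$outcome,
                                 cutoffs = cutoffs %||% band_cuts,
                                 level = level),
      capture = concentration_of_risk(expanded$score, expanded$outcome,
                                      top_fractions = top_fractions)
    )
  } else {
    cohort <- cohort_table(cohort, definition)
    if (sum(cohort$outcome) == 0L) {
      stop("cohort has zero events: AUC, logistic fit and capture curve are undefined",
           call. = FALSE)
    }
    scored <- score_cohort(cohort, definition)
    report <- list(
      mode = "cohort",
      auc = auc_delong(scored$score, scored$outcome, level = level),
      logistic = fit_logistic(scored$score, scored$outcome, level = level),
      risk_groups = risk_group_table(scored, level = level),
      cutpoints = cutpoint_table(scored$score, scored$outcome,
                                 cutoffs = cutoffs, level = level),
      capture = concentration_of_risk(scored$score, scored$outcome,
                                      top_fractions = top_fractions),
      score_summary = summary(scored)
    )
    if (length(group_columns)) {
      report$subgroups <- lapply(
        stats::setNames(group_columns, group_columns),
        function(g) subgroup_auc(cohort, definition, g, level = level)
      )
    }
  }
  report$provenance <- list(
    package = "checkrisk",
    version = as.character(utils::packageVersion("checkrisk")),
    definition = definition$name,
    definition_version = definition$version,
    level = level
  )
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> mode:", x$mode, "\n")
  if (!is.null(x$auc)) print(x$auc)
  if (!is.null(x$logistic)) print(x$logistic)
  cat("risk groups:\n")
  print(round_report(as.data.frame(x$risk_groups), "paper"))
  invisible(x)
}

#' End-to-end development run
#'
#' Ranks candidates by evidence, forward-selects on incremental AUC across
#' the development cohorts, applies the weight-doubling pass, and returns
#' the resulting checklist definition together with the selection trace.
#'
#' @param evidence Evidence `data.frame` (see [rank_candidates()]).
#' @param cohorts Named list of development [cohort_table()]s.
#' @param params A [selection_params()].
#' @param bands Band definition for the resulting checklist (default: the
#'   packaged six bands).
#' @param name,version Name/version for the resulting definition.
#' @return List with `definition` ([checklist_definition()]) and `trace`
#'   (`selection_trace`).
#' @export
run_develop <- function(evidence, cohorts, params = selection_params(),
                        bands = NULL, name = "developed-checklist",
                        version = "1.0") {
  order <- rank_candidates(evidence)
  trace <- forward_select(order, cohorts, params)
  retained <- retained_items(trace)
  if (length(retained) == 0L) {
    stop("no candidate was retained; cannot build a definition", call. = FALSE)
  }
  weights <- if (length(params$doubling_candidates)) {
    weight_doubling(trace, cohorts, params)
  } else {
    stats::setNames(rep(1L, length(retained)), retained)
  }
  if (is.null(bands)) bands <- drs_definition()$bands
  items <- data.frame(id = names(weights), label = names(weights),
                      weight = as.integer(weights), stringsAsFactors = FALSE)
  definition <- checklist_definition(name = name, version = version,
                                     items = items, bands = bands)
  list(definition = definition, trace = trace)
}

#' Round a report table to publication precision
#'
#' Profile `"paper"` mirrors the conventions of the published tables: rates
#' and percentages to 1 decimal place (percent), odds/risk ratios to 1,
#' AUCs and kappa-like indices to 2. Profile `"full"` returns the input
#' unchanged; full precision is always retained internally.
#'
#' @param table A data.frame of results.
#' @param profile `"paper"` or `"full"`.
#' @return The rounded data.frame.
#' @export
round_report <- function(table, profile = c("paper", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") return(table)
  rules <- list(
    `1` = c("risk_ratio", "odds_ratio", "or_lower", "or_upper",
            "rr_lower", "rr_upper", "pct_sample", "cum_pct"),
    `2` = c("auc", "se", "ci_lower", "ci_upper", "sensitivity",
            "specificity", "youden", "ppv", "npv", "efficiency",
            "k1", "k0", "k05", "nagelkerke_r2"),
    `4` = c("rate", "prevalence", "positivity", "flagged_fraction",
            "events_captured", "top_fraction")
  )
  for (dp in names(rules)) {
    cols <- intersect(rules[[dp]], names(table))
    for (col in cols) table[[col]] <- round(table[[col]], as.integer(dp))
  }
  table
}
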