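#' Literature-evidence record for a candidate variable
#'
#' Candidate risk factors are ranked by the empirical support behind them
#' before any data-driven selection. Four components are scored from a
#' meta-analytic evidence base: the rank (0-10) of the variable's broad risk
#' category for suicide death and for suicide attempts, and the rank of the
#' specific variable among the top predictors of each outcome (0, or 6-10).
#' Totals therefore range from 0 to 40.
#'
#' @param variable_id Identifier.
#' @param category_rank_death,category_rank_attempt Integers 0-10.
#' @param variable_rank_death,variable_rank_attempt Integers 0 or 6-10.
#' @return An `evidence_record` list with a `total` field.
#' @examples
#' evidence_record("suicide_attempt_lifetime", 7, 10, 9, 9)$total  # 35
#' @export
evidence_record <- function(variable_id, category_rank_death,
                            category_rank_attempt, variable_rank_death,
                            variable_rank_attempt) {
  chk_rank <- function(x, nm, top5 = FALSE) {
    if (length(x) != 1L || !is.finite(x) || x != round(x)) {
      stop("`", nm, "` must be a single integer", call. = FALSE)
    }
    ok <- if (top5) x == 0 || (x >= 6 && x <= 10) else x >= 0 && x <= 10
    if (!ok) {
      stop("`", nm, "` out of range: ", x,
           if (top5) " (must be 0 or 6-10)" else " (must be 0-10)",
           call. = FALSE)
    }
    as.integer(x)
  }
  rec <- list(
    variable_id = as.character(variable_id),
    category_rank_death = chk_rank(category_rank_death, "category_rank_death"),
    category_rank_attempt = chk_rank(category_rank_attempt, "category_rank_attempt"),
    variable_rank_death = chk_rank(variable_rank_death, "variable_rank_death", TRUE),
    variable_rank_attempt = chk_rank(variable_rank_attempt, "variable_rank_attempt", TRUE)
  )
  rec$total <- evidence_total(rec)
  class(rec) <- "evidence_record"
  rec
}

#' Total evidence score of a record
#'
#' @param record An [evidence_record()] (or a list/row with the four
#'   component fields).
#' @return Integer total (0-40).
#' @export
evidence_total <- function(record) {
  comps <- c(record$category_rank_death, record$category_rank_attempt,
             record$variable_rank_death, record$variable_rank_attempt)
  if (length(comps) != 4L || anyNA(comps)) {
    stop("evidence record lacks its four rank components", call. = FALSE)
  }
  as.integer(sum(comps))
}

#' Order candidates by evidence
#'
#' Descending by total evidence score; ties broken by the attempt category
#' rank (descending), then lexicographically by id, so the ordering is
#' deterministic.
#'
#' @param records List of [evidence_record()]s, or a `data.frame` with
#'   columns `variable_id`, `category_rank_death`, `category_rank_attempt`,
#'   `variable_rank_death`, `variable_rank_attempt`.
#' @return Character vector of variable ids in entry order.
#' @export
rank_candidates <- function(records) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) {
      evidence_record(records$variable_id[i],
                      records$category_rank_death[i],
                      records$category_rank_attempt[i],
                      records$variable_rank_death[i],
                      records$variable_rank_attempt[i])
    })
  }
  if (length(records) == 0L) stop("no candidate records", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "variable_id")
  if (anyDuplicated(ids)) {
    stop("duplicate variable_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  totals <- vapply(records, evidence_total, integer(1))
  att <- vapply(records, `[[`, integer(1), "category_rank_attempt")
  ids[order(-totals, -att, ids)]
}

#' Selection parameters
#'
#' @param min_gain Minimum cumulative-AUC gain, in at least one development
#'   cohort, for a candidate to be retained (default 0.001).
#' @param max_loss Maximum tolerated cumulative-AUC drop in any other
#'   development cohort (default 0.01).
#' @param doubling_candidates Item ids eligible for the weight-doubling pass.
#' @return A `selection_params` list.
#' @export
selection_params <- function(min_gain = 0.001, max_loss = 0.01,
                             doubling_candidates = character()) {
  stopifnot(min_gain >= 0, max_loss >= 0)
  structure(list(min_gain = min_gain, max_loss = max_loss,
                 doubling_candidates = doubling_candidates),
            class = "selection_params")
}

# pull item columns (missing -> 0) from each usable cohort
selection_matrices <- function(candidates, cohorts) {
  if (length(cohorts) == 0L) {
    stop("at least one development cohort is required", call. = FALSE)
  }
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort_", seq_along(cohorts))
  }
  usable <- vapply(cohorts, function(co) {
    length(unique(co$outcome)) == 2L
  }, logical(1))
  if (any(!usable)) {
    warning("excluding development cohort(s) without outcome variation: ",
            paste(names(cohorts)[!usable], collapse = ", "), call. = FALSE)
  }
  cohorts <- cohorts[usable]
  if (length(cohorts) == 0L) {
    stop("all development cohorts lack outcome variation", call. = FALSE)
  }
  lapply(cohorts, function(co) {
    cols <- paste0("item_", candidates)
    miss <- setdiff(cols, names(co))
    if (length(miss)) {
      stop("candidate(s) not measured in every cohort: ",
           paste(sub("^item_", "", miss), collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(as.data.frame(co)[, cols, drop = FALSE])
    x[is.na(x)] <- 0
    colnames(x) <- candidates
    list(x = x, y = co$outcome)
  })
}

#' Evidence-guided forward selection on incremental AUC
#'
#' Starting from the empty score, candidates are tried in evidence order,
#' each tentatively added with weight 1. A candidate is retained iff
#' (a) its bivariate AUC exceeds 0.5 in at least one development cohort,
#' (b) the cumulative AUC gains at least `min_gain` in at least one cohort,
#' and (c) the cumulative AUC drops by no more than `max_loss` in every
#' other cohort. The trace records the per-cohort cumulative AUC after every
#' decision, so the retained prefix can be re-scored and checked from
#' scratch.
#'
#' @param candidates Character vector of item ids in entry order (see
#'   [rank_candidates()]).
#' @param cohorts Named list of [cohort_table()]s with `item_<id>` columns
#'   for every candidate. Cohorts without outcome variation are excluded
#'   with a warning.
#' @param params A [selection_params()].
#' @return A `selection_trace`: data.frame with one row per candidate
#'   (`step`, `variable_id`, `decision`, `reason`, one `auc_<cohort>` column
#'   per cohort), with attribute `retained` (ids) and `cohorts` (names).
#' @export
forward_select <- function(candidates, cohorts, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"), length(candidates) >= 1L)
  mats <- selection_matrices(candidates, cohorts)
  k <- length(mats)
  score <- lapply(mats, function(m) numeric(nrow(m$x)))
  # all-zero score: every pair tied, AUC 1/2 by the tie convention
  cum_auc <- rep(0.5, k)
  retained <- character()
  rows <- vector("list", length(candidates))

  for (i in seq_along(candidates)) {
    id <- candidates[i]
    biv <- vapply(seq_len(k), function(j) {
      auc_rank(mats[[j]]$x[, id], mats[[j]]$y)
    }, numeric(1))
    new_auc <- vapply(seq_len(k), function(j) {
      auc_rank(score[[j]] + mats[[j]]$x[, id], mats[[j]]$y)
    }, numeric(1))
    gain <- new_auc - cum_auc

    if (!any(biv > 0.5)) {
      decision <- "rejected"; reason <- "no_bivariate_signal"
    } else if (!any(gain >= params$min_gain)) {
      decision <- "rejected"; reason <- "insufficient_gain"
    } else if (any(gain < -params$max_loss)) {
      decision <- "rejected"; reason <- "excess_loss"
    } else {
      decision <- "retained"; reason <- "retained"
    }
    if (decision == "retained") {
      for (j in seq_len(k)) score[[j]] <- score[[j]] + mats[[j]]$x[, id]
      cum_auc <- new_auc
      retained <- c(retained, id)
    }
    rows[[i]] <- data.frame(step = i, variable_id = id, decision = decision,
                            reason = reason, stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      rows[[i]][[paste0("auc_", names(mats)[j])]] <- cum_auc[j]
    }
  }
  trace <- do.call(rbind, rows)
  attr(trace, "retained") <- retained
  attr(trace, "cohorts") <- names(mats)
  class(trace) <- c("selection_trace", "data.frame")
  trace
}

#' Retained items of a selection trace
#' @param trace A `selection_trace` from [forward_select()].
#' @return Character vector of retained item ids, in entry order.
#' @export
retained_items <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  attr(trace, "retained")
}

#' Weight-doubling pass over the retained items
#'
#' After selection, each doubling candidate (in the given evidence order) has
#' its weight raised from 1 to 2 iff the cumulative AUC of the weighted sum
#' improves by at least `min_gain` in one or more cohorts and drops by no
#' more than `max_loss` in all others. Because the AUC is rank-invariant,
#' doubling the sole item of a score can never change it; doubling only
#' helps when the item must outrank combinations of other items.
#'
#' @param trace A `selection_trace` from [forward_select()].
#' @param cohorts The same development cohorts used for selection.
#' @param params A [selection_params()]; `doubling_candidates` must be a
#'   subset of the retained items (non-retained candidates are skipped with
#'   a warning).
#' @return Named integer vector of final weights over the retained items.
#' @export
weight_doubling <- function(trace, cohorts, params = selection_params()) {
  retained <- retained_items(trace)
  if (length(retained) == 0L) stop("no retained items to weight", call. = FALSE)
  mats <- selection_matrices(retained, cohorts)
  k <- length(mats)
  weights <- stats::setNames(rep(1L, length(retained)), retained)

  cum_auc <- vapply(seq_len(k), function(j) {
    auc_rank(mats[[j]]$x %*% weights, mats[[j]]$y)
  }, numeric(1))

  for (id in params$doubling_candidates) {
    if (!id %in% retained) {
      warning("doubling candidate not retained, skipped: ", id, call. = FALSE)
      next
    }
    w2 <- weights
    w2[id] <- 2L
    new_auc <- vapply(seq_len(k), function(j) {
      auc_rank(mats[[j]]$x %*% w2, mats[[j]]$y)
    }, numeric(1))
    gain <- new_auc - cum_auc
    if (any(gain >= params$min_gain) && all(gain >= -params$max_loss)) {
      weights <- w2
      cum_auc <- new_auc
    }
  }
  weights
}
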