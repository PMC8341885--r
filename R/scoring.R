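#' Score a single participant
#'
#' The checklist score is the sum of item weights over items marked present.
#' Missing responses score 0, exactly as a clinician filling in the checklist
#' would leave an unknown item unticked.
#'
#' @param responses Named character vector (or list) mapping every item id of
#'   the definition to one of `"present"`, `"absent"`, `"missing"`; or a
#'   named numeric vector coded 1/0/NA.
#' @param definition A [checklist_definition()].
#' @return Non-negative integer score.
#' @examples
#' def <- drs_definition()
#' resp <- stats::setNames(rep("absent", nrow(def$items)), def$items$id)
#' score_participant(resp, def)             # 0
#' resp["suicide_attempt_lifetime"] <- "present"
#' score_participant(resp, def)             # 2 (double-weighted item)
#' @export
score_participant <- function(responses, definition) {
  stopifnot(inherits(definition, "checklist_definition"))
  responses <- unlist(responses)
  if (is.null(names(responses)) || any(!nzchar(names(responses)))) {
    stop("`responses` must be named by item id", call. = FALSE)
  }
  unknown <- setdiff(names(responses), definition$items$id)
  if (length(unknown)) {
    stop("response for unknown item id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(definition$items$id, names(responses))
  if (length(uncovered)) {
    stop("responses must cover every definition item; missing: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  if (is.character(responses)) {
    bad <- setdiff(unique(responses), c("present", "absent", "missing"))
    if (length(bad)) {
      stop("invalid response state: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    present <- responses == "present"
  } else {
    if (!all(responses %in% c(0, 1) | is.na(responses))) {
      stop("numeric responses must be coded 1/0/NA", call. = FALSE)
    }
    present <- !is.na(responses) & responses == 1
  }
  w <- stats::setNames(definition$items$weight, definition$items$id)
  as.integer(sum(w[names(responses)[present]]))
}

#' Assign scores to risk bands
#'
#' Returns, for each score, the name of the unique band whose interval
#' contains it; the bands of a valid definition partition the non-negative
#' integers, so the assignment is total.
#'
#' @param score Vector of non-negative integer scores.
#' @param definition A [checklist_definition()].
#' @return Factor of band names, levelled in band order.
#' @examples
#' assign_band(c(0, 6, 22), drs_definition())
#' @export
assign_band <- function(score, definition) {
  stopifnot(inherits(definition, "checklist_definition"))
  if (any(score < 0)) stop("scores must be non-negative", call. = FALSE)
  bands <- definition$bands
  breaks <- c(bands$lower, Inf)
  idx <- findInterval(score, breaks)
  factor(bands$name[idx], levels = bands$name)
}

#' Score every participant in a cohort
#'
#' Applies the scoring rule row-wise (missing responses contribute 0),
#' assigns risk bands, counts missing items per participant, and attaches a
#' score-distribution summary (mean, sample SD, median, mode, moment
#' skewness, excess kurtosis, min, max).
#'
#' @param cohort A [cohort_table()].
#' @param definition A [checklist_definition()].
#' @param item_mask Optional character vector of item ids: score over this
#'   subset only (all other items ignored), supporting item-exclusion
#'   sensitivity analyses. Must be a non-empty subset of the definition's
#'   items.
#' @param max_missing_frac Optional completeness filter: drop participants
#'   whose fraction of missing (unmasked) item responses exceeds this value.
#'   Default `NULL` (no filter).
#' @return A `scored_cohort`: data.frame with columns `participant_id`,
#'   `score`, `band`, `n_missing`, `outcome` and any subgroup columns, with
#'   attributes `summary` (named list of moments) and `definition`.
#' @export
score_cohort <- function(cohort, definition, item_mask = NULL,
                         max_missing_frac = NULL) {
  cohort <- cohort_table(cohort, definition)
  items <- definition$items
  if (!is.null(item_mask)) {
    if (length(item_mask) == 0L) {
      stop("`item_mask` must not be empty", call. = FALSE)
    }
    bad <- setdiff(item_mask, items$id)
    if (length(bad)) {
      stop("`item_mask` contains unknown item ids: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    items <- items[items$id %in% item_mask, , drop = FALSE]
  }
  resp <- as.matrix(cohort[, paste0("item_", items$id), drop = FALSE])
  n_missing <- as.integer(rowSums(is.na(resp)))
  resp[is.na(resp)] <- 0
  score <- as.integer(resp %*% items$weight)

  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(max_missing_frac)) {
    keep <- n_missing / nrow(items) <= max_missing_frac
  }

  extra <- setdiff(names(cohort),
                   c("participant_id", "outcome",
                     grep("^item_", names(cohort), value = TRUE)))
  out <- data.frame(participant_id = cohort$participant_id,
                    score = score,
                    band = assign_band(score, definition),
                    n_missing = n_missing,
                    outcome = cohort$outcome,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- cohort[[col]]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  attr(out, "summary") <- score_summary(out$score)
  attr(out, "definition") <- definition
  class(out) <- c("scored_cohort", "data.frame")
  out
}

# distribution summary: sample SD, plain moment skewness, excess kurtosis
score_summary <- function(score) {
  mode_tab <- table(score)
  list(
    n = length(score),
    mean = mean(score),
    sd = stats::sd(score),
    median = stats::median(score),
    mode = as.integer(names(mode_tab)[which.max(mode_tab)]),
    skewness = e1071::skewness(score, type = 1),
    kurtosis = e1071::kurtosis(score, type = 1),
    min = min(score),
    max = max(score)
  )
}

#' @export
print.scored_cohort <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<scored_cohort> ", s$n, " participants, ",
      sum(x$outcome), " events\n", sep = "")
  cat(sprintf("  score: mean %.2f, SD %.2f, median %g, mode %g, skew %.2f, range %g-%g\n",
              s$mean, s$sd, s$median, s$mode, s$skewness, s$min, s$max))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.scored_cohort <- function(object, ...) {
  attr(object, "summary")
}
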