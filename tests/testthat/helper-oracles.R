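# Independent oracles and fixture builders shared across tests.

# Brute-force AUC: enumerate every case-control pair, ties count 1/2.
auc_brute <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Small hand-rolled cohort: explicit item responses per participant.
# `responses` is a matrix (participants x items) of 0/1/NA.
make_cohort <- function(responses, outcome, item_ids, ...) {
  d <- data.frame(participant_id = paste0("p", seq_len(nrow(responses))),
                  stringsAsFactors = FALSE)
  for (j in seq_along(item_ids)) d[[paste0("item_", item_ids[j])]] <- responses[, j]
  d$outcome <- outcome
  extra <- list(...)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  cohort_table(d)
}

# Random response cohort over the full packaged definition.
random_drs_cohort <- function(n, seed, p_present = 0.15, p_missing = 0.05) {
  set.seed(seed)
  def <- drs_definition()
  ids <- def$items$id
  m <- matrix(rbinom(n * length(ids), 1, p_present), n)
  m[matrix(runif(n * length(ids)) < p_missing, n)] <- NA
  outcome <- rbinom(n, 1, 0.2)
  if (sum(outcome) == 0) outcome[1] <- 1
  if (sum(outcome) == n) outcome[1] <- 0
  make_cohort(m, outcome, ids)
}

# Development-cohort generator for the selection recovery experiment:
# 23 independent Bernoulli(0.2) items, the first `n_info` truly raising the
# outcome log-odds by `b_info` each, the rest pure noise.
make_recovery_cohort <- function(n, seed, n_info = 10, n_null = 13,
                                 b_info = 0.9, intercept = -4.3) {
  set.seed(seed)
  ids <- c(sprintf("inf%02d", seq_len(n_info)),
           sprintf("nul%02d", seq_len(n_null)))
  x <- matrix(rbinom(n * length(ids), 1, 0.2), n)
  eta <- intercept + x[, seq_len(n_info), drop = FALSE] %*% rep(b_info, n_info)
  y <- rbinom(n, 1, plogis(eta))
  make_cohort(x, y, ids)
}

recovery_candidates <- function(n_info = 10, n_null = 13) {
  c(sprintf("inf%02d", seq_len(n_info)), sprintf("nul%02d", seq_len(n_null)))
}
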