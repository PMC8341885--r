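test_that("evidence totals sum the four rank components with range checks", {
  expect_equal(evidence_record("a", 7, 10, 9, 9)$total, 35L)
  expect_equal(evidence_record("b", 0, 0, 0, 0)$total, 0L)
  expect_equal(evidence_record("c", 10, 5, 10, 6)$total, 31L)
  expect_error(evidence_record("d", 11, 0, 0, 0), "out of range")
  expect_error(evidence_record("e", 5, 5, 3, 0), "0 or 6-10")
})

test_that("candidate ranking is by total, then attempt category, then id", {
  recs <- list(evidence_record("mid", 10, 5, 10, 6),   # 31
               evidence_record("top", 7, 10, 9, 9),    # 35
               evidence_record("low", 8, 8, 0, 7))     # 23
  expect_equal(rank_candidates(recs), c("top", "mid", "low"))
  # order-invariance of the input list
  expect_equal(rank_candidates(rev(recs)), c("top", "mid", "low"))

  # equal totals and components: lexicographic id
  tie <- list(evidence_record("zeta", 5, 5, 0, 0),
              evidence_record("alpha", 5, 5, 0, 0))
  expect_equal(rank_candidates(tie), c("alpha", "zeta"))
  # equal totals, different attempt category: higher attempt rank first
  att <- list(evidence_record("a", 6, 4, 0, 0),
              evidence_record("b", 4, 6, 0, 0))
  expect_equal(rank_candidates(att), c("b", "a"))

  dup <- list(evidence_record("x", 1, 1, 0, 0), evidence_record("x", 2, 2, 0, 0))
  expect_error(rank_candidates(dup), "duplicate")
})

test_that("a perfectly predictive candidate is retained with cumulative AUC 1", {
  x <- matrix(c(rep(1, 5), rep(0, 15)), ncol = 1)
  co <- make_cohort(x, c(rep(1, 5), rep(0, 15)), "hit")
  tr <- forward_select("hit", list(dev = co))
  expect_equal(retained_items(tr), "hit")
  expect_equal(tr$auc_dev, 1)
})

test_that("candidates independent of the outcome are rejected", {
  set.seed(701)
  cohorts <- lapply(1:3, function(i) make_recovery_cohort(3000, 700 + i))
  names(cohorts) <- paste0("dev", 1:3)
  tr <- forward_select(c("inf01", "nul01", "nul02", "nul03"), cohorts)
  expect_true("inf01" %in% retained_items(tr))
  expect_false(any(c("nul01", "nul02", "nul03") %in% retained_items(tr)))
})

test_that("trace cumulative AUCs are reproducible by rescoring the prefix", {
  cohorts <- list(d1 = make_recovery_cohort(2000, 711),
                  d2 = make_recovery_cohort(2000, 712))
  cand <- recovery_candidates()
  tr <- forward_select(cand, cohorts)
  # at each retained step, rescore the retained prefix from scratch
  retained_so_far <- character()
  for (i in seq_len(nrow(tr))) {
    if (tr$decision[i] != "retained") next
    retained_so_far <- c(retained_so_far, tr$variable_id[i])
    for (nm in names(cohorts)) {
      co <- as.data.frame(cohorts[[nm]])
      s <- rowSums(co[, paste0("item_", retained_so_far), drop = FALSE])
      expect_equal(tr[[paste0("auc_", nm)]][i],
                   auc_rank(s, co$outcome))
    }
  }
  # determinism
  expect_identical(forward_select(cand, cohorts), tr)
})

test_that("with one cohort and zero gain threshold the trace never decreases", {
  co <- make_recovery_cohort(2500, 721)
  tr <- forward_select(recovery_candidates(), list(dev = co),
                       selection_params(min_gain = 0, max_loss = 0.01))
  expect_true(all(diff(tr$auc_dev) >= -1e-12))
})

test_that("cohorts without outcome variation are excluded, all-excluded errors", {
  good <- make_recovery_cohort(1500, 731)
  flat <- as.data.frame(make_recovery_cohort(200, 732))
  flat$outcome <- 0L
  flat <- cohort_table(flat)
  expect_warning(tr <- forward_select("inf01", list(g = good, f = flat)),
                 "excluding")
  expect_false("auc_f" %in% names(tr))
  expect_error(suppressWarnings(forward_select("inf01", list(f = flat))),
               "all development cohorts")
})

test_that("doubling the sole predictor never changes the AUC (rank invariance)", {
  x <- matrix(rbinom(400, 1, 0.3), ncol = 1)
  y <- rbinom(400, 1, plogis(-2 + 2 * x[, 1]))
  co <- make_cohort(x, y, "only")
  tr <- forward_select("only", list(dev = co))
  w <- weight_doubling(tr, list(dev = co),
                       selection_params(doubling_candidates = "only"))
  expect_equal(unname(w["only"]), 1L)
})

test_that("an item with twice the log-odds contribution gets doubled", {
  set.seed(741)
  make_co <- function(seed) {
    set.seed(seed)
    ids <- c("big", sprintf("sm%d", 1:5))
    x <- matrix(rbinom(5000 * 6, 1, 0.25), 5000)
    y <- rbinom(5000, 1, plogis(-3.4 + x %*% c(1.6, rep(0.8, 5))))
    make_cohort(x, y, ids)
  }
  cohorts <- list(a = make_co(742), b = make_co(743))
  tr <- forward_select(c("big", sprintf("sm%d", 1:5)), cohorts)
  expect_true("big" %in% retained_items(tr))
  w <- weight_doubling(tr, cohorts,
                       selection_params(doubling_candidates = c("big", "sm1")))
  expect_equal(unname(w["big"]), 2L)

  # empty doubling set leaves the weights unchanged
  w0 <- weight_doubling(tr, cohorts, selection_params())
  expect_true(all(w0 == 1L))

  # non-retained doubling candidate is skipped with a warning
  expect_warning(
    weight_doubling(tr, cohorts,
                    selection_params(doubling_candidates = "ghost")),
    "not retained"
  )
})
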