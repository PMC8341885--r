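test_that("logistic fit recovers the null and flags degenerate inputs", {
  set.seed(601)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, 0.3)  # independent of x
  f <- fit_logistic(x, y)
  expect_true(f$converged)
  expect_lt(abs(f$slope), 3 * f$slope_se)
  expect_lt(f$nagelkerke_r2, 0.01)
  expect_equal(f$odds_ratio, exp(f$slope))
  expect_gte(f$nagelkerke_r2, 0)

  expect_error(fit_logistic(x, rep(1, 2000)), "both outcome classes")
  # complete separation is reported, not silently accepted
  xs <- c(1:10, 21:30)
  ys <- rep(c(0, 1), each = 10)
  fs <- fit_logistic(xs, ys)
  expect_true(fs$separation)
  expect_false(fs$converged)
})

test_that("logistic slope matches the 2x2 odds ratio for a binary exposure", {
  set.seed(602)
  x <- rbinom(500, 1, 0.4)
  y <- rbinom(500, 1, plogis(-1.5 + 1.2 * x))
  f <- fit_logistic(x, y)
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  tt <- two_by_two(a, b, c_, d)
  expect_equal(f$odds_ratio, tt$odds_ratio, tolerance = 1e-6)
})

test_that("Nagelkerke R2 grows with a truly informative predictor", {
  set.seed(603)
  x <- rnorm(3000)
  y <- rbinom(3000, 1, plogis(-2 + 1.5 * x))
  f_info <- fit_logistic(x, y)
  f_null <- fit_logistic(rnorm(3000), y)
  expect_gt(f_info$nagelkerke_r2, f_null$nagelkerke_r2)
  expect_lte(f_info$nagelkerke_r2, 1)
})

test_that("2x2 analysis reproduces its defining formulas and symmetries", {
  tt <- two_by_two(12, 12, 12, 12)
  expect_equal(tt$odds_ratio, 1)
  expect_equal(tt$risk_ratio, 1)
  expect_equal(tt$chi_square, 0)

  tt2 <- two_by_two(20, 80, 10, 90)
  expect_equal(tt2$odds_ratio, (20 * 90) / (80 * 10))
  expect_equal(tt2$risk_ratio, (20 / 100) / (10 / 100))
  # chi-squared equals brute-force sum over (O - E)^2 / E
  o <- matrix(c(20, 80, 10, 90), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(tt2$chi_square, sum((o - e)^2 / e))
  # CIs contain the point estimates
  expect_lt(tt2$or_lower, tt2$odds_ratio)
  expect_gt(tt2$or_upper, tt2$odds_ratio)
  expect_lt(tt2$rr_lower, tt2$risk_ratio)

  expect_error(two_by_two(0, 0, 3, 4), "margin")
})

test_that("zero cells give infinite estimates unless Haldane-corrected", {
  raw <- two_by_two(5, 5, 0, 10)
  expect_equal(raw$odds_ratio, Inf)
  corr <- two_by_two(5, 5, 0, 10, correction = TRUE)
  expect_true(is.finite(corr$odds_ratio))
  expect_true(is.finite(corr$or_lower))
})

test_that("risk-group table compares each band to the lowest band", {
  def <- drs_definition()
  # counts chosen so rates rise sharply across three occupied bands
  counts <- data.frame(band = c("Lowest risk", "Low risk", "Moderate risk"),
                       controls = c(900, 500, 80),
                       attempters = c(1, 5, 12))
  rg <- risk_group_stats(counts)
  expect_equal(rg$risk_ratio[1], 1)
  expect_equal(rg$odds_ratio[1], 1)
  expect_equal(sum(rg$total), 1498)
  expect_equal(rg$cum_pct[3], 100)
  tt <- two_by_two(12, 80, 1, 900)
  expect_equal(rg$odds_ratio[3], tt$odds_ratio)
  expect_equal(rg$p[3], tt$p)

  # scored-cohort route agrees with the count route
  cohort <- random_drs_cohort(300, seed = 604)
  scored <- score_cohort(cohort, def)
  rg2 <- risk_group_table(scored)
  expect_equal(sum(rg2$total), 300)
  expect_equal(rg2$odds_ratio[1], 1)

  # cohort entirely in one band: 100% there, no comparisons computed
  one_band <- make_cohort(matrix(0, 10, 23), rep(c(0, 1), 5),
                          def$items$id)
  rg3 <- risk_group_table(score_cohort(one_band, def))
  expect_equal(nrow(rg3), 1L)
  expect_equal(rg3$pct_sample, 100)

  expect_error(risk_group_stats(data.frame(band = "x", controls = 0,
                                           attempters = 0)),
               "reference")
})

test_that("subgroup AUCs reproduce the pooled AUC and skip degenerate groups", {
  def <- drs_definition()
  half <- random_drs_cohort(120, seed = 605)
  # duplicate the cohort into two identical labelled halves
  both <- as.data.frame(half)
  a <- transform(both, participant_id = paste0(participant_id, "a"), grp = "A")
  b <- transform(both, participant_id = paste0(participant_id, "b"), grp = "B")
  cohort <- cohort_table(rbind(a, b))
  res <- subgroup_auc(cohort, def, "grp")
  expect_equal(res$auc[res$group == "A"], res$auc[res$group == "B"])
  pooled <- auc_delong(score_cohort(cohort, def)$score, cohort$outcome)
  expect_equal(res$auc[1], pooled$auc)

  # a group with a single outcome class is skipped, not fatal
  c_ <- transform(both[both$outcome == 0, ],
                  participant_id = paste0(participant_id, "c"), grp = "C")
  cohort3 <- cohort_table(rbind(a, b, c_))
  res3 <- subgroup_auc(cohort3, def, "grp")
  expect_true(res3$skipped[res3$group == "C"])
  expect_false(any(res3$skipped[res3$group != "C"]))
})

test_that("group labels independent of the data leave the AUC unchanged", {
  def <- drs_definition()
  set.seed(606)
  cohort <- random_drs_cohort(2000, seed = 607)
  cohort$grp <- sample(c("x", "y"), 2000, replace = TRUE)
  res <- subgroup_auc(cohort, def, "grp")
  pooled <- auc_delong(score_cohort(cohort, def)$score, cohort$outcome)
  expect_true(all(abs(res$auc - pooled$auc) < 0.06))  # Monte-Carlo tolerance
})
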