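test_that("packaged definitions load with the documented structure", {
  def <- drs_definition()
  expect_s3_class(def, "checklist_definition")
  expect_equal(nrow(def$items), 23L)
  expect_equal(max_score(def), 27L)
  expect_equal(sum(def$items$weight == 2L), 4L)
  expect_setequal(def$items$id[def$items$weight == 2L],
                  c("suicide_attempt_lifetime", "hospitalization_lifetime",
                    "nssi_lifetime", "bpd_lifetime"))
  expect_equal(def$bands$name[1], "Lowest risk")
  expect_true(is.na(def$bands$upper[nrow(def$bands)]))

  sps <- sad_persons_definition()
  expect_equal(nrow(sps$items), 10L)
  expect_equal(max_score(sps), 10L)
  expect_true(all(sps$items$weight == 1L))
})

test_that("definition schema violations name the offending field", {
  items <- data.frame(id = c("a", "b"), label = c("A", "B"), weight = c(1, 1))
  bands <- data.frame(name = c("lo", "hi"), lower = c(0, 3), upper = c(2, NA))
  expect_error(
    checklist_definition("x", "1", items[c(1, 1), ], bands),
    "duplicate item id.*items\\.id"
  )
  expect_error(
    checklist_definition("x", "1", transform(items, weight = c(0, 1)), bands),
    "items\\.weight"
  )
  gap <- data.frame(name = c("lo", "hi"), lower = c(0, 4), upper = c(2, NA))
  expect_error(checklist_definition("x", "1", items, gap), "gap or overlap")
  nolast <- data.frame(name = c("lo", "hi"), lower = c(0, 3), upper = c(2, 9))
  expect_error(checklist_definition("x", "1", items, nolast), "unbounded")
})

test_that("JSON and YAML definitions round-trip", {
  def <- drs_definition()
  json_path <- withr::local_tempfile(fileext = ".json")
  write_definition(def, json_path)
  back <- load_definition(json_path)
  expect_equal(back$items, def$items)
  expect_equal(back$bands, def$bands)

  yml_path <- withr::local_tempfile(fileext = ".yaml")
  doc <- list(name = def$name, version = def$version,
              items = lapply(seq_len(nrow(def$items)), function(i) {
                as.list(def$items[i, ])
              }),
              bands = lapply(seq_len(nrow(def$bands)), function(i) {
                b <- as.list(def$bands[i, ])
                if (is.na(b$upper)) b$upper <- NULL
                b
              }),
              missing_policy = def$missing_policy)
  yaml::write_yaml(doc, yml_path)
  expect_equal(load_definition(yml_path)$items$weight, def$items$weight)
})

test_that("participant scoring sums weights over present items, missing as absent", {
  def <- drs_definition()
  resp <- setNames(rep("absent", 23), def$items$id)
  expect_identical(score_participant(resp, def), 0L)

  resp["suicide_attempt_lifetime"] <- "present"
  expect_identical(score_participant(resp, def), 2L)

  all_present <- setNames(rep("present", 23), def$items$id)
  expect_identical(score_participant(all_present, def), 27L)

  # missing scores exactly like absent
  resp_missing <- setNames(rep("missing", 23), def$items$id)
  resp_missing["suicide_attempt_lifetime"] <- "present"
  expect_identical(score_participant(resp_missing, def), 2L)

  # numeric coding accepted
  num <- setNames(c(1, rep(0, 21), NA), def$items$id)
  expect_identical(score_participant(num, def), 2L)

  expect_error(score_participant(c(resp, bogus = "present"), def),
               "unknown item")
  expect_error(score_participant(resp[-1], def), "cover every")
})

test_that("band assignment matches the published ranges and partitions scores", {
  def <- drs_definition()
  expect_equal(as.character(assign_band(c(0, 2, 3, 6, 9, 12, 15, 22), def)),
               c("Lowest risk", "Lowest risk", "Low risk", "Moderate risk",
                 "High risk", "Very high risk", "Highest risk", "Highest risk"))
  # partition: every score in 0..27 lands in exactly one band
  b <- assign_band(0:27, def)
  expect_false(anyNA(b))
  expect_equal(sum(table(b)), 28L)
})

test_that("cohort scoring equals participant-wise scoring and is pure", {
  def <- drs_definition()
  cohort <- random_drs_cohort(60, seed = 301)
  scored <- score_cohort(cohort, def)
  expect_equal(nrow(scored), nrow(cohort))

  # oracle equivalence, participant by participant
  ids <- def$items$id
  for (i in c(1, 7, 33, 60)) {
    resp <- setNames(as.numeric(cohort[i, paste0("item_", ids)]), ids)
    expect_identical(scored$score[i], score_participant(resp, def))
  }
  # determinism
  expect_identical(score_cohort(cohort, def), scored)
  # summary recomputable from the scores
  s <- summary(scored)
  expect_equal(s$mean, mean(scored$score))
  expect_equal(s$sd, sd(scored$score))
  # band counts partition the cohort
  expect_equal(sum(table(scored$band)), nrow(scored))
})

test_that("item masking drops masked items and is invariant for all-absent items", {
  def <- drs_definition()
  cohort <- random_drs_cohort(40, seed = 302)
  cohort$item_female_sex <- 0  # force one item absent everywhere
  full <- score_cohort(cohort, def)
  masked <- score_cohort(cohort, def,
                         item_mask = setdiff(def$items$id, "female_sex"))
  expect_equal(masked$score, full$score)

  # masking a present-somewhere item lowers some scores, never raises any
  masked2 <- score_cohort(cohort, def,
                          item_mask = setdiff(def$items$id, "lower_income"))
  expect_true(all(masked2$score <= full$score))

  expect_error(score_cohort(cohort, def, item_mask = character()), "empty")
  expect_error(score_cohort(cohort, def, item_mask = "nope"), "unknown")
})

test_that("scoring is monotone in present items", {
  def <- drs_definition()
  set.seed(303)
  ids <- def$items$id
  for (rep in 1:20) {
    resp <- setNames(sample(c("present", "absent", "missing"), 23, TRUE), ids)
    base <- score_participant(resp, def)
    flip <- sample(which(resp != "present"), 1)
    resp[flip] <- "present"
    expect_gte(score_participant(resp, def), base)
  }
})

test_that("completeness filter drops high-missingness participants only", {
  def <- drs_definition()
  cohort <- random_drs_cohort(50, seed = 304, p_missing = 0)
  # participant 1: 10 of 23 items missing (43% > 35%)
  cohort[1, paste0("item_", def$items$id[1:10])] <- NA
  kept <- score_cohort(cohort, def, max_missing_frac = 0.35)
  expect_equal(nrow(kept), 49L)
  expect_false("p1" %in% kept$participant_id)
  expect_equal(nrow(score_cohort(cohort, def)), 50L)  # default: no filter
})
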