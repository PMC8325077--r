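test_that("the same configuration reproduces the cohort exactly", {
  cfg <- generator_config(seed = 5, n_legit = 20, n_fraud = 15,
                          min_indicators_per_fraud = 2,
                          stage1_counts = c(stage_0 = 2))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(generator_config(seed = 6, n_legit = 20,
                                            n_fraud = 15,
                                            min_indicators_per_fraud = 2,
                                            stage1_counts = c(stage_0 = 2)))
  expect_false(identical(generate_cohort(cfg)$cohort, other$cohort))
})

test_that("plant_burst builds an arithmetic run of timestamps", {
  base <- as.POSIXct("2020-10-09 10:00:00", tz = "America/New_York")
  expect_equal(plant_burst(base, 3, 2), base + c(0, 120, 240))
  expect_error(plant_burst(base, 0, 2), "at least 1")
  # a 10-long run at 4-minute gaps fires the burst clause,
  # the same run at 6-minute gaps does not
  cohort <- cohort_template(10)
  cohort$submission_timestamp <- plant_burst(base, 10, 4)
  expect_setequal(flag_suspicious_timing(cohort), cohort$respondent_id)
  cohort$submission_timestamp <- plant_burst(base, 10, 6)
  expect_length(flag_suspicious_timing(cohort), 0L)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(generator_config(seed = 1, n_fraud = 5, burst_size = 10,
                                indicator_probs = c(SUSPICIOUS_TIMING = 0.5)),
               "burst_size")
  expect_error(generator_config(seed = 1, n_fraud = 10,
                                indicator_counts = c(DUP_EMAIL = 1)),
               "duplicate")
  expect_error(generator_config(seed = 1, n_fraud = 10,
                                indicator_counts = c(AGE_DISCORD = 11)),
               "indicator counts")
  expect_error(generator_config(seed = 1, indicator_probs = c(bogus = 0.5)),
               "unknown indicator")
  expect_error(generator_config(seed = 1, n_legit = -1), "non-negative")
})

test_that("a cohort without planted problems passes the screen untouched", {
  sim <- generate_cohort(generator_config(seed = 3, n_legit = 50,
                                          n_fraud = 0))
  res <- run_pipeline(sim$cohort)
  expect_equal(res$flow_counts$retained, 50L)
})

test_that("one fraud record with exactly two indicators is the only removal", {
  sim <- generate_cohort(generator_config(
    seed = 4, n_legit = 10, n_fraud = 1,
    indicator_counts = c(AGE_DISCORD = 1, SUSPICIOUS_EMAIL_ADDRESS = 1),
    min_indicators_per_fraud = 2))
  res <- run_pipeline(sim$cohort)
  expect_equal(res$flow_counts$retained, 10L)
  removed <- res$decisions$respondent_id[res$decisions$outcome != "retained"]
  expect_equal(removed,
               sim$truth$respondent_id[sim$truth$class == "fraud"])
})

test_that("fraud planted with a single indicator each survives the screen", {
  sim <- generate_cohort(generator_config(
    seed = 6, n_legit = 10, n_fraud = 8,
    indicator_counts = c(AGE_DISCORD = 8),
    min_indicators_per_fraud = 0))
  res <- run_pipeline(sim$cohort)
  ev <- evaluate_detection(res$decisions, sim$truth)
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
})

test_that("exact planting yields exact recovery, indicator by indicator", {
  sim <- generate_cohort(generator_config(
    seed = 12, n_legit = 30, n_fraud = 40,
    stage1_counts = c(non_us = 2, stage_0 = 2, no_diagnosis = 2,
                      nonmelanoma_only = 3, excess_missingness = 4,
                      discordant_gender = 2, discordant_sex_site = 2),
    indicator_counts = c(AGE_DISCORD = 10, RARE_CANCER_YOUNG = 8,
                         SOURCE_INCONGRUENT = 25, OFFTOPIC_TEXT = 5,
                         DUP_TELEHEALTH = 4, DUP_SUGGESTION = 6,
                         DUP_EMAIL = 3, TIMELINE_DX_LT2_TX_2TO5 = 2,
                         TIMELINE_DX_LE5_TX_GT5 = 5,
                         SUSPICIOUS_TIMING = 30,
                         SUSPICIOUS_EMAIL_ADDRESS = 9,
                         SUSPICIOUS_NAME = 7),
    min_indicators_per_fraud = 2))
  res <- run_pipeline(sim$cohort)
  ev <- evaluate_detection(res$decisions, sim$truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$stage1_recovery, 1)
  expect_true(all(ev$per_indicator$false_neg == 0))
  expect_true(all(ev$per_indicator$false_pos == 0))
  expect_equal(ev$per_indicator$planted, ev$per_indicator$detected)
})

test_that("generated age profiles match the configured class means", {
  sim <- generate_cohort(generator_config(seed = 23, n_legit = 400,
                                          n_fraud = 400,
                                          min_indicators_per_fraud = 0,
                                          indicator_probs = c(AGE_DISCORD = 0)))
  ages <- sim$cohort$reported_age
  legit <- sim$truth$class == "legit"
  expect_lt(abs(mean(ages[legit]) - 55.9), 2 * 13.1 / sqrt(400))
  expect_lt(abs(mean(ages[!legit]) - 41.4), 2 * 8.2 / sqrt(400) + 0.5)
})

test_that("detection evaluation requires matching cohorts", {
  sim <- generate_cohort(generator_config(seed = 2, n_legit = 5,
                                          n_fraud = 3,
                                          min_indicators_per_fraud = 2))
  res <- run_pipeline(sim$cohort)
  truth <- sim$truth
  truth$respondent_id[1] <- "R99999"
  expect_error(evaluate_detection(res$decisions, truth), "different")
})
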