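set_cancer <- function(cohort, rows, types) {
  for (col in grep("^cancer_type___", names(cohort), value = TRUE))
    cohort[[col]][rows] <- 0L
  for (tp in types) cohort[[paste0("cancer_type___", tp)]][rows] <- 1L
  cohort
}

test_that("core ineligibility reasons fire on the defining conditions only", {
  cohort <- cohort_template(5)
  cohort$country_of_residence[2] <- "Canada"
  cohort$cancer_stage[3] <- "0"
  cohort <- set_cancer(cohort, 4, character(0))
  cohort$cancer_stage[4] <- "none"
  cohort <- set_cancer(cohort, 5, "nonmelanoma_skin")
  r <- check_ineligible(cohort)
  expect_false(any(unlist(r[1, ])))                 # US resident, stage II
  expect_true(r$non_us_resident[2])
  expect_true(r$stage_0[3])
  expect_true(r$no_cancer_diagnosis[4])
  expect_true(r$nonmelanoma_only[5])
  # nonmelanoma together with another cancer is eligible
  cohort <- set_cancer(cohort, 5, c("nonmelanoma_skin", "breast"))
  expect_false(check_ineligible(cohort)$nonmelanoma_only[5])
})

test_that("gender contradiction fires on configured exclusive pairs only", {
  cohort <- cohort_template(3)
  cohort$gender___cisgender_male[1] <- 1L       # + cisgender_female
  cohort$gender___cisgender_female[2] <- 0L
  cohort$gender___transgender_male[2] <- 1L     # single selection
  cohort$gender___gender_fluid[2] <- 1L         # not an exclusive pair
  expect_equal(check_gender_contradiction(cohort), c(TRUE, FALSE, FALSE))
})

test_that("sex/site contradiction follows the incompatibility map both ways", {
  cohort <- cohort_template(3)
  cohort$sex_assigned_at_birth <- c("male", "female", "male")
  cohort <- set_cancer(cohort, 1, "uterine_cervical")
  cohort <- set_cancer(cohort, 2, "prostate")
  cohort <- set_cancer(cohort, 3, "colorectal")
  expect_equal(check_sex_site_contradiction(cohort), c(TRUE, TRUE, FALSE))
})

test_that("stage-1 removals are attributed to the first failing stage", {
  cohort <- cohort_template(3)
  # record 2 fails both missingness and gender contradiction
  schema <- survey_schema()
  blankable <- setdiff(names(schema$inventory),
                       c("country_of_residence", "cancer_stage",
                         "cancer_type"))
  for (item in blankable[1:10]) {
    for (col in schema$inventory[[item]])
      cohort[[col]][2] <- if (is.numeric(cohort[[col]])) NA_integer_ else NA
  }
  cohort$gender___cisgender_male[2] <- 1L
  cohort$gender___cisgender_female[2] <- 1L
  screen <- screen_cohort(cohort)
  expect_equal(screen$verdicts$removed_at[2], "excess_missingness")
  expect_setequal(screen$verdicts$reasons[[2]],
                  c("excess_missingness", "discordant_gender"))
  expect_equal(unname(screen$counts[["excess_missingness"]]), 1L)
  expect_equal(unname(screen$counts[["discordant_gender"]]), 0L)
})

test_that("an all-clean cohort is fully eligible with zero counts", {
  screen <- screen_cohort(cohort_template(10))
  expect_true(all(screen$verdicts$eligible))
  expect_true(all(screen$counts == 0L))
})

test_that("stage counts are disjoint, conserve the cohort and ignore row order", {
  for (s in c(4L, 21L)) {
    sim <- generate_cohort(generator_config(
      seed = s, n_legit = 20, n_fraud = 10, min_indicators_per_fraud = 2,
      stage1_counts = c(non_us = 3, stage_0 = 2, no_diagnosis = 2,
                        nonmelanoma_only = 3, excess_missingness = 4,
                        discordant_gender = 2, discordant_sex_site = 3)))
    screen <- screen_cohort(sim$cohort)
    expect_equal(sum(screen$verdicts$eligible) + sum(screen$counts),
                 nrow(sim$cohort))
    # verdicts are a pure function of the record, not of row order
    perm <- sample(nrow(sim$cohort))
    shuffled <- screen_cohort(sim$cohort[perm, ])
    reord <- shuffled$verdicts[match(screen$verdicts$respondent_id,
                                     shuffled$verdicts$respondent_id), ]
    expect_equal(reord$removed_at, screen$verdicts$removed_at)
    expect_equal(unname(shuffled$counts), unname(screen$counts))
  }
})
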