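test_that("a cohort round-trips through CSV field for field", {
  cohort <- cohort_template(3)
  cohort$telehealth_comment[2] <- 'He said, "all good, really" -- and left.'
  cohort$income_bracket[3] <- NA_character_
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort, path)
  back <- read_responses(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
  expect_identical(back$respondent_id, cohort$respondent_id)
})

test_that("generated cohorts round-trip through CSV (property)", {
  for (s in c(2L, 11L)) {
    sim <- generate_cohort(generator_config(
      seed = s, n_legit = 15, n_fraud = 10, min_indicators_per_fraud = 2,
      stage1_counts = c(non_us = 2, excess_missingness = 2,
                        discordant_gender = 1)))
    path <- withr::local_tempfile(fileext = ".csv")
    write_responses(sim$cohort, path)
    expect_equal(as.data.frame(read_responses(path)),
                 as.data.frame(sim$cohort))
  }
})

test_that("an empty cohort writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort_template(0), path)
  expect_length(readLines(path), 1L)
  expect_identical(nrow(read_responses(path)), 0L)
})

test_that("unparseable and empty cells become missing and feed the mask", {
  cohort <- cohort_template(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort, path)
  txt <- readLines(path)
  txt[2] <- sub("50k_75k", "", txt[2])       # empty income cell
  txt[3] <- sub("50k_75k", "banana", txt[3]) # not a level of the variable
  writeLines(txt, path)
  back <- read_responses(path)
  expect_true(is.na(back$income_bracket[1]))
  expect_true(is.na(back$income_bracket[2]))
  mask <- item_missing_matrix(back)
  expect_true(all(mask[, "income_bracket"]))
  expect_false(any(mask[, "education"]))
})

test_that("a missing mandatory column raises a schema error naming it", {
  cohort <- cohort_template(2)
  cohort$email <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path)
  expect_error(read_responses(path), "email")
})

test_that("duplicate respondent ids are an integrity error", {
  cohort <- cohort_template(2)
  cohort$respondent_id <- c("R1", "R1")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path)
  expect_error(read_responses(path), "unique")
})

test_that("timestamps with explicit offsets are honored, naive ones follow the flag", {
  cohort <- cohort_template(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort, path)
  txt <- readLines(path)
  txt[2] <- sub("2020-10-20T09:00:00-0400", "2020-10-20T13:00:00+0000",
                txt[2])
  writeLines(txt, path)
  back <- read_responses(path)
  expect_equal(back$submission_timestamp, cohort$submission_timestamp)

  txt[2] <- sub("2020-10-20T13:00:00\\+0000", "2020-10-20 09:00:00", txt[2])
  writeLines(txt, path)
  naive <- read_responses(path, assume_eastern = TRUE)
  expect_equal(naive$submission_timestamp, cohort$submission_timestamp)
})

test_that("missingness fraction matches hand counts and is order-invariant", {
  cohort <- cohort_template(2)
  expect_equal(missingness_fraction(cohort), c(0, 0))

  # fully blank record over the default inventory
  blank <- cohort_template(1)
  schema <- survey_schema()
  for (item in schema$inventory) {
    for (col in item) {
      blank[[col]] <- if (is.numeric(blank[[col]])) NA_integer_ else NA
    }
  }
  expect_equal(missingness_fraction(blank), 1)

  # 40-item custom inventory with 14 items missing: 14/40 = 0.35 exactly
  wide <- tibble::as_tibble(setNames(as.list(rep("x", 40)),
                                     sprintf("q%02d", 1:40)))
  wide[sprintf("q%02d", 1:14)] <- NA_character_
  inventory <- setNames(as.list(sprintf("q%02d", 1:40)),
                        sprintf("q%02d", 1:40))
  expect_equal(missingness_fraction(wide, inventory), 0.35)
  shuffled <- inventory[sample(names(inventory))]
  expect_equal(missingness_fraction(wide, shuffled), 0.35)
})

test_that("prefer-not-to-answer counts as answered, empty checkbox groups as missing", {
  cohort <- cohort_template(1)
  cohort$income_bracket <- "prefer_not_to_answer"
  mask <- item_missing_matrix(cohort)
  expect_false(mask[, "income_bracket"])
  for (col in grep("^race___", names(cohort), value = TRUE))
    cohort[[col]] <- 0L
  expect_true(item_missing_matrix(cohort)[, "race"])
})

test_that("screening settings read from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("thresholds:", "  missingness_cutoff: 0.5",
               "  burst_min_run: 8", "calendar:",
               "  patient_portal: 2020-10-20"), path)
  s <- read_screening_settings(path)
  expect_equal(s$thresholds$missingness_cutoff, 0.5)
  expect_equal(s$thresholds$burst_min_run, 8L)
  expect_equal(s$thresholds$indicator_elimination_count, 2L)
  expect_equal(unname(unclass(s$calendar["patient_portal"])),
               unclass(as.Date("2020-10-20")))
})
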