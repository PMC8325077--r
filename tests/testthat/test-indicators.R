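eastern <- function(x) as.POSIXct(x, tz = "America/New_York")

test_that("age discordance fires on survey-year DOB and >1-year disagreement", {
  cohort <- cohort_template(4)
  cohort$submission_timestamp <- rep(eastern("2020-10-10 10:00:00"), 4)
  cohort$reported_age <- c(45L, 45L, 30L, 44L)
  cohort$date_of_birth <- as.Date(c("2020-01-01",  # degenerate DOB
                                    "1975-06-01",  # computed age 45, agrees
                                    "1960-01-01",  # computed age 60, off 30
                                    "1975-06-01")) # computed 45 vs 44: off 1
  expect_equal(flag_age_discordance(cohort), c(TRUE, FALSE, TRUE, FALSE))
  # missing date of birth cannot fire
  cohort$date_of_birth[3] <- NA
  expect_false(flag_age_discordance(cohort)[3])
})

test_that("rare-cancer flag needs both young age and a catalog cancer", {
  cohort <- cohort_template(3)
  cohort$reported_age <- c(35L, 45L, 35L)
  cohort$cancer_type___breast <- c(0L, 0L, 1L)
  cohort$cancer_type___lung <- c(1L, 1L, 0L)
  expect_equal(flag_rare_cancer_young(cohort), c(TRUE, FALSE, FALSE))
  # monotone in the age cutoff
  wider <- flag_rare_cancer_young(
    cohort, thresholds = screening_thresholds(young_age_cutoff = 50))
  expect_true(all(flag_rare_cancer_young(cohort) <= wider))
})

test_that("source incongruence compares submission date with the channel date", {
  cohort <- cohort_template(3)
  cohort$submission_timestamp <- rep(eastern("2020-10-09 10:00:00"), 3)
  cohort$survey_source <- c("coc_email",          # disseminated Oct 13
                            "community_partner",  # disseminated Oct 8
                            "mystery_channel")    # unknown to the calendar
  expect_warning(res <- flag_source_incongruence(cohort), "mystery_channel")
  expect_equal(res, c(TRUE, FALSE, FALSE))
})

test_that("off-topic text needs an IT term and no care-related term", {
  cohort <- cohort_template(3)
  cohort$telehealth_comment <- c(
    "great software, nice user interface and network",
    "my oncologist was kind over video",
    "")
  expect_equal(flag_offtopic_text(cohort), c(TRUE, FALSE, FALSE))
  # a care-related term anchors a comment even when IT terms appear
  cohort$telehealth_comment[1] <-
    "the software worked but my oncologist was kind"
  expect_false(flag_offtopic_text(cohort)[1])
})

test_that("duplicate text flags whole groups and matches brute force", {
  cohort <- cohort_template(6)
  shared <- "The video call with the care team went smoothly for me."
  cohort$telehealth_comment <- c(shared, shared, shared,
                                 "A unique comment about my treatment plan.",
                                 "short note",  # below the length floor
                                 "short note")
  got <- flag_duplicate_text(cohort, "telehealth_comment")
  expect_setequal(got, cohort$respondent_id[1:3])
  expect_setequal(got, duplicate_oracle(cohort$respondent_id,
                                        cohort$telehealth_comment))
  # normalization: case, punctuation and spacing do not hide duplicates
  cohort$telehealth_comment[2] <- toupper(gsub(",", " ,  ", shared))
  expect_setequal(flag_duplicate_text(cohort, "telehealth_comment"),
                  cohort$respondent_id[1:3])
  # randomized cross-check against the pairwise oracle
  withr::with_seed(42, {
    pool <- c("Thanks for the helpful telehealth visits this year.",
              "The care team responded quickly to my messages.",
              "My treatment questions were answered fully.", "n/a")
    cohort2 <- cohort_template(12)
    cohort2$final_suggestion <- sample(pool, 12, replace = TRUE)
    expect_setequal(flag_duplicate_text(cohort2, "final_suggestion"),
                    duplicate_oracle(cohort2$respondent_id,
                                     cohort2$final_suggestion))
  })
})

test_that("duplicate email matching is case-insensitive and skips missing", {
  cohort <- cohort_template(4)
  cohort$email <- c("A@x.com", "a@x.com", NA, NA)
  expect_setequal(flag_duplicate_email(cohort), cohort$respondent_id[1:2])
  cohort$email <- c("a@x.com", "b@x.com", "c@x.com", "d@x.com")
  expect_length(flag_duplicate_email(cohort), 0L)
})

test_that("timeline contradictions follow the two impossible combinations", {
  cohort <- cohort_template(4)
  cohort$time_since_diagnosis <- c("lt2", "2to5", "gt5", NA)
  cohort$time_since_treatment <- c("2to5", "gt5", "gt5", "gt5")
  tl <- flag_timeline_inconsistency(cohort)
  expect_equal(tl$TIMELINE_DX_LT2_TX_2TO5, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(tl$TIMELINE_DX_LE5_TX_GT5, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("suspicious timing flags long bursts and night submissions", {
  cohort <- cohort_template(12)
  cohort$submission_timestamp <- plant_burst(eastern("2020-10-20 10:00:00"),
                                             12, 2)
  expect_setequal(flag_suspicious_timing(cohort), cohort$respondent_id)

  nine <- cohort_template(9)
  nine$submission_timestamp <- plant_burst(eastern("2020-10-20 10:00:00"),
                                           9, 1)
  expect_length(flag_suspicious_timing(nine), 0L)

  one <- cohort_template(1)
  one$submission_timestamp <- eastern("2020-10-20 02:30:00")
  expect_setequal(flag_suspicious_timing(one), one$respondent_id)
  # 04:00 exactly is outside the half-open night window
  one$submission_timestamp <- eastern("2020-10-20 04:00:00")
  expect_length(flag_suspicious_timing(one), 0L)

  # lowering the burst threshold never unflags anyone (monotonicity)
  strict <- flag_suspicious_timing(nine)
  loose <- flag_suspicious_timing(
    nine, screening_thresholds(burst_min_run = 5))
  expect_true(all(strict %in% loose))
  expect_setequal(loose, nine$respondent_id)
})

test_that("a six-minute spacing breaks a run regardless of its length", {
  cohort <- cohort_template(15)
  cohort$submission_timestamp <- plant_burst(eastern("2020-10-20 10:00:00"),
                                             15, 6)
  expect_length(flag_suspicious_timing(cohort), 0L)
})

test_that("record-local detectors ignore cohort permutation", {
  sim <- generate_cohort(generator_config(seed = 8, n_legit = 10,
                                          n_fraud = 15,
                                          min_indicators_per_fraud = 2))
  cohort <- sim$cohort
  perm <- withr::with_seed(1, sample(nrow(cohort)))
  for (fn in list(flag_age_discordance, flag_rare_cancer_young,
                  flag_offtopic_text, flag_suspicious_email_address,
                  flag_suspicious_name)) {
    expect_equal(fn(cohort)[perm], fn(cohort[perm, ]))
  }
  # cohort-level detectors are permutation-invariant as sets
  expect_setequal(flag_suspicious_timing(cohort),
                  flag_suspicious_timing(cohort[perm, ]))
  expect_setequal(flag_duplicate_email(cohort),
                  flag_duplicate_email(cohort[perm, ]))
})

test_that("profiles union the detectors and count fired codes", {
  cohort <- cohort_template(3)
  cohort$submission_timestamp[2] <- eastern("2020-10-20 02:00:00")
  cohort$date_of_birth[2] <- as.Date("2020-05-01")
  prof <- profile_cohort(cohort)
  expect_equal(prof$count, c(0L, 2L, 0L))
  expect_setequal(prof$fired[[2]], c("AGE_DISCORD", "SUSPICIOUS_TIMING"))
})

test_that("the honeypot indicator is opt-in", {
  cohort <- cohort_template(2)
  cohort$honeypot_value[2] <- "filled by a bot"
  expect_equal(profile_cohort(cohort)$count, c(0L, 0L))
  prof <- profile_cohort(cohort, include_honeypot = TRUE)
  expect_equal(prof$count, c(0L, 1L))
  expect_equal(prof$fired[[2]], "HONEYPOT")
})
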