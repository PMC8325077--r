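# Synthetic survey-cohort generator with planted ground truth.
#
# The generator emits cohorts with three record classes:
#   legit      - satisfies no elimination rule at all
#   ineligible - instantiates exactly one planted stage-1 reason
#   fraud      - instantiates exactly its planted indicator set
# so that the screening pipeline's decisions can be compared against known
# truth. Plantings are constructive: a planted source-incongruent record
# really claims the accredited-center email channel while being dated
# before that channel's dissemination date; a planted burst really is an
# arithmetic run of closely spaced timestamps; clean records are verified
# against the detectors and re-drawn on the rare accidental hit, so exact
# planting yields exact recovery by construction rather than by tuning.

CODE_T1 <- "TIMELINE_DX_LT2_TX_2TO5"
CODE_T2 <- "TIMELINE_DX_LE5_TX_GT5"
DUP_CODES <- c("DUP_TELEHEALTH", "DUP_SUGGESTION", "DUP_EMAIL")
# pairs that cannot be instantiated on one record: the two timeline
# contradictions need different treatment categories, and a duplicated
# (shared, on-topic) telehealth comment cannot simultaneously be off-topic
# without making every member of the duplicate group off-topic too
FORBIDDEN_PAIRS <- list(c(CODE_T1, CODE_T2),
                        c("OFFTOPIC_TEXT", "DUP_TELEHEALTH"))
TOPUP_ORDER <- c("SUSPICIOUS_TIMING", "SOURCE_INCONGRUENT", "AGE_DISCORD",
                 "SUSPICIOUS_EMAIL_ADDRESS", "SUSPICIOUS_NAME",
                 "OFFTOPIC_TEXT", CODE_T2)

STAGE1_REASONS <- c("non_us", "stage_0", "no_diagnosis", "nonmelanoma_only",
                    "excess_missingness", "discordant_gender",
                    "discordant_sex_site")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample() treats a length-1 numeric first argument as 1:x; never do that
safe_sample <- function(x, k) if (length(x) == 1L) rep(x, k) else sample(x, k)

#' Synthetic-cohort generator configuration
#'
#' Defines the composition of a synthetic cohort: class sizes, planted
#' stage-1 reason counts, and per-indicator planting for the fraud class,
#' either as exact marginal counts (`indicator_counts`) or as independent
#' per-record Bernoulli probabilities (`indicator_probs`). With
#' `min_indicators_per_fraud = 2` every fraud record is guaranteed at
#' least two indicators (exact counts are preserved by reassigning
#' indicators from indicator-rich records); with `0`, plantings are left
#' exactly as drawn, so fraud records may carry fewer than two indicators
#' and survive the screen — the regime used to check the binomial
#' detection model.
#'
#' @param seed Integer; fully determines the cohort.
#' @param n_legit,n_fraud Class sizes.
#' @param stage1_counts Named integer vector over
#'   `c("non_us","stage_0","no_diagnosis","nonmelanoma_only",
#'   "excess_missingness","discordant_gender","discordant_sex_site")`;
#'   its sum is the ineligible class size.
#' @param indicator_counts Named integer vector over [indicator_codes()]:
#'   exact number of fraud records planted with each indicator.
#' @param indicator_probs Named numeric vector over [indicator_codes()]:
#'   independent planting probability per fraud record. Exactly one of
#'   `indicator_counts` / `indicator_probs` is used; if both are `NULL`, a
#'   moderate default probability profile is applied.
#' @param min_indicators_per_fraud Minimum planted indicators per fraud
#'   record (default 2); 0 disables enforcement.
#' @param burst_size,burst_gap_minutes Submission-burst geometry for
#'   timing-planted records (default runs of 30 at 2-minute gaps).
#' @param legit_age_mean,legit_age_sd,fraud_age_mean,fraud_age_sd Reported
#'   age profiles per class (years).
#' @param end_date Last submission date of the field period.
#' @param calendar A [dissemination_calendar()].
#' @param thresholds The [screening_thresholds()] the plantings instantiate.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_legit = 40L, n_fraud = 20L,
                             stage1_counts = NULL,
                             indicator_counts = NULL,
                             indicator_probs = NULL,
                             min_indicators_per_fraud = 2L,
                             burst_size = 30L, burst_gap_minutes = 2,
                             legit_age_mean = 55.9, legit_age_sd = 13.1,
                             fraud_age_mean = 41.4, fraud_age_sd = 8.2,
                             end_date = as.Date("2020-12-02"),
                             calendar = dissemination_calendar(),
                             thresholds = screening_thresholds()) {
  s1 <- setNames(rep(0L, length(STAGE1_REASONS)), STAGE1_REASONS)
  if (!is.null(stage1_counts)) {
    bad <- setdiff(names(stage1_counts), STAGE1_REASONS)
    if (length(bad))
      stop("unknown stage-1 reason(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    s1[names(stage1_counts)] <- as.integer(stage1_counts)
  }
  if (!is.null(indicator_counts) && !is.null(indicator_probs))
    stop("give indicator_counts or indicator_probs, not both", call. = FALSE)
  if (is.null(indicator_counts) && is.null(indicator_probs)) {
    indicator_probs <- setNames(rep(0, length(INDICATOR_CODES)),
                                INDICATOR_CODES)
    indicator_probs[c("AGE_DISCORD", "SOURCE_INCONGRUENT",
                      "SUSPICIOUS_TIMING", "RARE_CANCER_YOUNG",
                      "SUSPICIOUS_EMAIL_ADDRESS")] <-
      c(0.25, 0.6, 0.7, 0.2, 0.15)
  }
  norm_ind <- function(x) {
    out <- setNames(rep(0, length(INDICATOR_CODES)), INDICATOR_CODES)
    if (!is.null(x)) {
      if (is.null(names(x)) || any(names(x) == ""))
        stop("indicator plantings must be named by indicator code",
             call. = FALSE)
      bad <- setdiff(names(x), INDICATOR_CODES)
      if (length(bad))
        stop("unknown indicator code(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      out[names(x)] <- unname(x)
    }
    out
  }
  if (missing(burst_size))
    burst_size <- max(1L, min(30L, as.integer(n_fraud)))
  cfg <- list(seed = as.integer(seed),
              n_legit = as.integer(n_legit), n_fraud = as.integer(n_fraud),
              stage1_counts = s1,
              indicator_counts = if (is.null(indicator_counts)) NULL
                                 else norm_ind(indicator_counts),
              indicator_probs = if (is.null(indicator_probs)) NULL
                                else norm_ind(indicator_probs),
              min_indicators_per_fraud = as.integer(min_indicators_per_fraud),
              burst_size = as.integer(burst_size),
              burst_gap_minutes = burst_gap_minutes,
              legit_age_mean = legit_age_mean, legit_age_sd = legit_age_sd,
              fraud_age_mean = fraud_age_mean, fraud_age_sd = fraud_age_sd,
              end_date = as.Date(end_date),
              calendar = calendar, thresholds = thresholds)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_legit < 0L || cfg$n_fraud < 0L || any(cfg$stage1_counts < 0L))
    stop("class sizes and stage-1 counts must be non-negative", call. = FALSE)
  if (!is.null(cfg$indicator_probs) &&
      (any(cfg$indicator_probs < 0) || any(cfg$indicator_probs > 1)))
    stop("indicator probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(cfg$indicator_counts)) {
    if (any(cfg$indicator_counts < 0L) ||
        any(cfg$indicator_counts > cfg$n_fraud))
      stop("indicator counts must lie in [0, n_fraud]", call. = FALSE)
    dup1 <- DUP_CODES[cfg$indicator_counts[DUP_CODES] == 1L]
    if (length(dup1))
      stop("a duplicate-type indicator cannot be planted on exactly one ",
           "record: ", paste(dup1, collapse = ", "), call. = FALSE)
  }
  timing_planted <- (!is.null(cfg$indicator_counts) &&
                       cfg$indicator_counts[["SUSPICIOUS_TIMING"]] > 0L) ||
    (!is.null(cfg$indicator_probs) &&
       cfg$indicator_probs[["SUSPICIOUS_TIMING"]] > 0)
  if (timing_planted && cfg$n_fraud > 0L && cfg$burst_size > cfg$n_fraud)
    stop("burst_size exceeds the number of fraud records", call. = FALSE)
  if (cfg$burst_size < 1L) stop("burst_size must be at least 1",
                                call. = FALSE)
  invisible(cfg)
}

#' Full-scale cohort configuration
#'
#' The 1977-response layout the screening procedure is demonstrated on:
#' 569 legitimate records, 1081 fraud records each planted with at least
#' two indicators (exact per-indicator marginals), and 327 ineligible
#' records split 28/28/27 across non-US residence, stage 0 and no
#' diagnosis, plus 46 nonmelanoma-only, 149 high-missingness, 12
#' gender-contradictory and 37 sex/site-contradictory records.
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
fullscale_config <- function(seed = 1L) {
  generator_config(
    seed = seed, n_legit = 569L, n_fraud = 1081L,
    stage1_counts = c(non_us = 28L, stage_0 = 28L, no_diagnosis = 27L,
                      nonmelanoma_only = 46L, excess_missingness = 149L,
                      discordant_gender = 12L, discordant_sex_site = 37L),
    indicator_counts = c(AGE_DISCORD = 250L, RARE_CANCER_YOUNG = 283L,
                         SOURCE_INCONGRUENT = 820L, OFFTOPIC_TEXT = 56L,
                         DUP_TELEHEALTH = 34L, DUP_SUGGESTION = 107L,
                         DUP_EMAIL = 20L, TIMELINE_DX_LT2_TX_2TO5 = 11L,
                         TIMELINE_DX_LE5_TX_GT5 = 57L,
                         SUSPICIOUS_TIMING = 986L,
                         SUSPICIOUS_EMAIL_ADDRESS = 166L,
                         SUSPICIOUS_NAME = 78L),
    min_indicators_per_fraud = 2L
  )
}

#' Arithmetic burst of submission timestamps
#'
#' @param base First timestamp (`POSIXct`).
#' @param size Number of submissions in the burst.
#' @param gap_minutes Spacing between successive submissions, in minutes.
#' @return `POSIXct` vector of length `size`.
#' @export
#' @examples
#' plant_burst(as.POSIXct("2020-10-09 10:00:00", tz = "America/New_York"),
#'             3, 2)
plant_burst <- function(base, size, gap_minutes) {
  if (size < 1L) stop("burst size must be at least 1", call. = FALSE)
  base + (seq_len(size) - 1L) * gap_minutes * 60
}

# ---- indicator assignment ------------------------------------------------

pair_partner <- function(code) {
  unlist(lapply(FORBIDDEN_PAIRS, function(p)
    if (code %in% p) setdiff(p, code) else character(0)))
}

code_allowed <- function(A, row, code, rare_rows) {
  if (A[row, code]) return(FALSE)
  if (code == "RARE_CANCER_YOUNG" && !(row %in% rare_rows)) return(FALSE)
  partners <- pair_partner(code)
  if (length(partners) && any(A[row, partners])) return(FALSE)
  TRUE
}

# Exact-marginal assignment with repair: per-indicator column sums equal
# `counts` exactly, no record carries a forbidden pair, and (when enforced)
# every record carries at least `min_per` indicators. Repairs move an
# assignment from an indicator-rich record to a deficient one, preserving
# marginals.
assign_indicators_exact <- function(n, counts, rare_rows, min_per) {
  A <- matrix(FALSE, n, length(INDICATOR_CODES),
              dimnames = list(NULL, INDICATOR_CODES))
  for (cd in INDICATOR_CODES) {
    k <- counts[[cd]]
    if (k == 0L) next
    pool <- if (cd == "RARE_CANCER_YOUNG") rare_rows else seq_len(n)
    if (k > length(pool))
      stop("infeasible configuration: cannot plant ", k, " ", cd,
           " records", call. = FALSE)
    A[safe_sample(pool, k), cd] <- TRUE
  }
  for (fp in FORBIDDEN_PAIRS) {
    bad <- which(A[, fp[1]] & A[, fp[2]])
    for (r in bad) {
      dest <- which(!A[, fp[1]] & !A[, fp[2]])
      dest <- setdiff(dest, r)
      if (!length(dest))
        stop("infeasible configuration: cannot separate ",
             paste(fp, collapse = " and "), call. = FALSE)
      d <- if (length(dest) == 1L) dest else sample(dest, 1L)
      A[r, fp[1]] <- FALSE
      A[d, fp[1]] <- TRUE
    }
  }
  if (min_per > 0L) {
    for (iter in seq_len(50L * n + 50L)) {
      deficient <- which(rowSums(A) < min_per)
      if (!length(deficient)) break
      r <- deficient[1L]
      moved <- FALSE
      for (cd in sample(INDICATOR_CODES)) {
        if (!code_allowed(A, r, cd, rare_rows)) next
        donors <- which(A[, cd] & rowSums(A) >= min_per + 1L)
        donors <- setdiff(donors, deficient)
        if (!length(donors)) next
        d <- if (length(donors) == 1L) donors else sample(donors, 1L)
        A[d, cd] <- FALSE
        A[r, cd] <- TRUE
        moved <- TRUE
        break
      }
      if (!moved)
        stop("infeasible configuration: not enough planted indicators to ",
             "give every fraud record ", min_per, call. = FALSE)
    }
    if (any(rowSums(A) < min_per))
      stop("infeasible configuration: indicator repair did not converge",
           call. = FALSE)
  }
  A
}

# Independent Bernoulli assignment; forbidden pairs are resolved by
# dropping one member at random, duplicate-type indicators drawn on exactly
# one record are un-planted (a single record cannot be a duplicate), and
# (optionally) records below the minimum are topped up with
# deterministically ordered non-duplicate codes.
assign_indicators_bernoulli <- function(n, probs, min_per) {
  A <- vapply(INDICATOR_CODES, function(cd) runif(n) < probs[[cd]],
              logical(n))
  if (n == 1L) A <- matrix(A, nrow = 1L,
                           dimnames = list(NULL, INDICATOR_CODES))
  for (fp in FORBIDDEN_PAIRS) {
    bad <- which(A[, fp[1]] & A[, fp[2]])
    if (length(bad)) {
      drop_first <- runif(length(bad)) < 0.5
      A[bad[drop_first], fp[1]] <- FALSE
      A[bad[!drop_first], fp[2]] <- FALSE
    }
  }
  for (cd in DUP_CODES) if (sum(A[, cd]) == 1L) A[, cd] <- FALSE
  if (min_per > 0L) {
    for (r in which(rowSums(A) < min_per)) {
      for (cd in TOPUP_ORDER) {
        if (rowSums(A)[r] >= min_per) break
        if (code_allowed(A, r, cd, rare_rows = seq_len(n))) A[r, cd] <- TRUE
      }
      if (sum(A[r, ]) < min_per)
        stop("infeasible configuration: cannot reach ", min_per,
             " indicators per fraud record", call. = FALSE)
    }
  }
  A
}

# ---- timestamp allocation ------------------------------------------------

slot_grid <- function(days, start_min, end_min, step_min = 6) {
  mins <- seq(start_min, end_min, by = step_min)
  stamps <- paste(rep(as.character(days), each = length(mins)),
                  sprintf("%02d:%02d:00", rep(mins %/% 60, length(days)),
                          rep(mins %% 60, length(days))))
  as.POSIXct(stamps, tz = EASTERN_TZ)
}

# Assigns every record a submission timestamp consistent with its planted
# timing/source indicators and clean for everyone else:
#  - timing+source records: daytime-evening bursts (runs of `burst_size`
#    at `burst_gap_minutes`) on Oct 9-12, overflow into the Oct 9-12 night
#    window; both fall before the claimed channel's dissemination date
#  - source-only records: Oct 9-12 morning grid, successive gaps > 5 min
#  - timing-only records: night window (00:06-03:54) on later days
#  - everyone else: daytime grid on later days, gaps > 5 min
allocate_timestamps <- function(A, cfg) {
  n <- nrow(A)
  th <- cfg$thresholds
  tim <- A[, "SUSPICIOUS_TIMING"]
  src <- A[, "SOURCE_INCONGRUENT"]
  early <- seq(as.Date("2020-10-09"), as.Date("2020-10-12"), by = "day")
  late <- seq(as.Date("2020-10-14"), cfg$end_date, by = "day")
  if (!length(late))
    stop("infeasible configuration: field period ends before 2020-10-14",
         call. = FALSE)
  nw <- th$night_window
  night_start <- nw[1] * 60 + 6
  night_end <- nw[2] * 60 - 6
  ts <- .POSIXct(rep(NA_real_, n), tz = EASTERN_TZ)
  # whole-second jitter: timestamps must survive text serialization
  jit <- function(x) x + floor(runif(length(x), 0, 30))

  g_both <- which(tim & src)
  g_src <- which(src & !tim)
  g_tim <- which(tim & !src)
  g_rest <- which(!tim & !src)

  members <- if (length(g_both) > 1L) sample(g_both) else g_both
  gap_s <- cfg$burst_gap_minutes * 60
  use_bursts <- cfg$burst_size >= th$burst_min_run
  if (use_bursts && length(members) >= cfg$burst_size) {
    burst_len_s <- cfg$burst_size * gap_s
    for (day in as.list(early)) {
      t0 <- as.POSIXct(paste(as.character(day), "16:12:00"),
                       tz = EASTERN_TZ)
      day_end <- as.POSIXct(paste(as.character(day), "23:54:00"),
                            tz = EASTERN_TZ)
      while (length(members) >= cfg$burst_size &&
             as.numeric(day_end) - as.numeric(t0) >= burst_len_s) {
        take <- members[seq_len(cfg$burst_size)]
        ts[take] <- plant_burst(t0, cfg$burst_size, cfg$burst_gap_minutes)
        members <- members[-seq_len(cfg$burst_size)]
        t0 <- t0 + burst_len_s + 12 * 60
      }
    }
  }
  night_early <- slot_grid(early, night_start, night_end)
  if (length(members) > length(night_early))
    stop("infeasible configuration: too many timing+source records for ",
         "the pre-dissemination window", call. = FALSE)
  if (length(members))
    ts[members] <- jit(sample(night_early, length(members)))

  morning_early <- slot_grid(early, 8 * 60, 15 * 60 + 54)
  if (length(g_src) > length(morning_early))
    stop("infeasible configuration: too many source-incongruent records",
         call. = FALSE)
  if (length(g_src))
    ts[g_src] <- jit(sample(morning_early, length(g_src)))

  night_late <- slot_grid(late, night_start, night_end)
  if (length(g_tim) > length(night_late))
    stop("infeasible configuration: too many night-timing records",
         call. = FALSE)
  if (length(g_tim))
    ts[g_tim] <- jit(sample(night_late, length(g_tim)))

  day_late <- slot_grid(late, 8 * 60, 21 * 60 + 54)
  if (length(g_rest) > length(day_late))
    stop("infeasible configuration: cohort exceeds daytime capacity of ",
         "the field period", call. = FALSE)
  if (length(g_rest))
    ts[g_rest] <- jit(sample(day_late, length(g_rest)))
  ts
}

# ---- identity and text pools --------------------------------------------

STREET_NAMES <- c("Maple", "Oak", "Cedar", "Elm", "Walnut", "Chestnut",
                  "Spruce", "Willow", "Aspen", "Birch", "Magnolia",
                  "Juniper", "Sycamore", "Laurel")
STREET_TYPES <- c("St", "Ave", "Rd", "Ln", "Dr", "Ct")
CITY_NAMES <- c("Springfield", "Dayton", "Columbus", "Madison", "Franklin",
                "Georgetown", "Clinton", "Salem", "Fairview", "Bristol",
                "Clayton", "Arlington")
STATE_CODES <- c("OH", "IL", "PA", "NY", "VA", "NC", "GA", "MI", "TN", "MO")
EMAIL_DOMAINS <- c("gmail.com", "yahoo.com", "outlook.com", "example.org")

TELEHEALTH_TEMPLATES <- c(
  "My oncologist explained my scan results clearly during the visit.",
  "The nurse helped me schedule my next appointment without trouble.",
  "I felt my doctor listened to my symptoms during the telehealth visit.",
  "Talking to my care team from home made treatment follow up easier.",
  "The clinic staff were patient while I described my pain levels.",
  "It was reassuring to see my doctor even though the visit was remote.",
  "My questions about medication side effects were answered with care.",
  "The telehealth appointment saved me a long drive to the hospital.")

SUGGESTION_TEMPLATES <- c(
  "Please keep telehealth visits available for routine cancer follow up.",
  "It would help to have evening appointment slots at the clinic.",
  "More guidance on insurance coverage for telehealth would be welcome.",
  "I hope my care team continues offering remote appointments.",
  "Shorter waits to see the oncologist would improve my experience.",
  "Please send appointment reminders for every telehealth visit.")

OFFTOPIC_TEMPLATES <- c(
  "Great software and a very clean interface, the server was fast.",
  "The website loaded quickly in my browser and the network was stable.",
  "Nice database design, the login page and password reset worked fine.",
  "Excellent bandwidth, smooth download speeds and a modern webpage.",
  "The interface runs well on android and the upload was quick.")

DUP_TELEHEALTH_TEXT <- paste(
  "The video sessions with my oncology team were convenient",
  "and worked well for me overall.")
DUP_SUGGESTION_TEXT <- paste(
  "Please continue to offer telehealth appointments",
  "for routine follow up care.")

generator_name_pools <- function() {
  female <- read_term_file(pkg_resource("given_names_female.txt"))
  male <- read_term_file(pkg_resource("given_names_male.txt"))
  surnames <- read_term_file(pkg_resource("surnames.txt"))
  given <- c(female, male)
  list(female = female, male = male, surnames = surnames,
       surname_only = setdiff(surnames, given),
       given_only_female = setdiff(female, c(male, surnames)),
       given_only = setdiff(given, surnames))
}

random_run_local <- function(k = 1L, len = 12L) {
  consonants <- setdiff(letters, c("a", "e", "i", "o", "u"))
  vapply(seq_len(k), function(i) {
    chars <- c(sample(consonants, len - 3L, replace = TRUE),
               sample(as.character(0:9), 3L, replace = TRUE))
    paste(sample(chars), collapse = "")
  }, character(1))
}

# ---- cohort generation ---------------------------------------------------

#' Generate a synthetic survey cohort with planted ground truth
#'
#' Deterministic given the seed in the configuration. Legitimate records
#' satisfy no elimination rule; ineligible records instantiate exactly
#' their planted stage-1 reason; fraud records instantiate exactly their
#' planted indicator set (a planted source-incongruent record claims a
#' channel dated after its submission, a planted burst is a real run of
#' closely spaced timestamps, and so on).
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (tibble in [survey_schema()] layout) and
#'   `truth` (tibble with `respondent_id`, `class`, `stage1_reason`, one
#'   logical column per indicator code, `planted` list-column and
#'   `planted_count`).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  th <- cfg$thresholds
  schema <- survey_schema()
  n_inel <- sum(cfg$stage1_counts)
  n <- cfg$n_legit + cfg$n_fraud + n_inel
  if (n == 0L)
    return(list(cohort = cohort_template(0L),
                truth = tibble::tibble(respondent_id = character(0),
                                       class = character(0),
                                       stage1_reason = character(0))))
  class <- sample(rep(c("legit", "fraud", "ineligible"),
                      c(cfg$n_legit, cfg$n_fraud, n_inel)))
  id <- sprintf("R%05d", seq_len(n))
  fraud_rows <- which(class == "fraud")
  inel_rows <- which(class == "ineligible")

  reason <- rep(NA_character_, n)
  if (n_inel > 0L) {
    pool <- rep(names(cfg$stage1_counts), cfg$stage1_counts)
    reason[inel_rows] <- if (length(pool) > 1L) sample(pool) else pool
  }

  age <- integer(n)
  nl <- class == "legit" | class == "ineligible"
  age[nl] <- as.integer(clamp(round(rnorm(sum(nl), cfg$legit_age_mean,
                                          cfg$legit_age_sd)), 18, 90))
  age[fraud_rows] <- as.integer(clamp(round(rnorm(length(fraud_rows),
                                                  cfg$fraud_age_mean,
                                                  cfg$fraud_age_sd)), 18, 90))

  # indicator plantings over the fraud class
  A_f <- matrix(FALSE, length(fraud_rows), length(INDICATOR_CODES),
                dimnames = list(NULL, INDICATOR_CODES))
  if (length(fraud_rows)) {
    if (!is.null(cfg$indicator_counts)) {
      # exact marginals require enough under-40 fraud records for the
      # rare-cancer indicator; convert the youngest surplus if short
      need <- cfg$indicator_counts[["RARE_CANCER_YOUNG"]]
      young <- which(age[fraud_rows] < th$young_age_cutoff)
      short <- need - length(young)
      if (short > 0L) {
        old <- setdiff(seq_along(fraud_rows), young)
        if (short > length(old))
          stop("infeasible configuration: rare-cancer planting exceeds ",
               "fraud class size", call. = FALSE)
        conv <- safe_sample(old, short)
        age[fraud_rows[conv]] <- as.integer(sample(22:39, short,
                                                   replace = TRUE))
        young <- which(age[fraud_rows] < th$young_age_cutoff)
      }
      A_f <- assign_indicators_exact(length(fraud_rows),
                                     cfg$indicator_counts, young,
                                     cfg$min_indicators_per_fraud)
    } else {
      A_f <- assign_indicators_bernoulli(length(fraud_rows),
                                         cfg$indicator_probs,
                                         cfg$min_indicators_per_fraud)
      forced <- which(A_f[, "RARE_CANCER_YOUNG"] &
                        age[fraud_rows] >= th$young_age_cutoff)
      if (length(forced))
        age[fraud_rows[forced]] <- as.integer(sample(22:39, length(forced),
                                                     replace = TRUE))
    }
  }
  A <- matrix(FALSE, n, length(INDICATOR_CODES),
              dimnames = list(NULL, INDICATOR_CODES))
  A[fraud_rows, ] <- A_f

  ts <- allocate_timestamps(A, cfg)
  sub_date <- as.Date(ts, tz = EASTERN_TZ)

  # survey source: incongruent where planted, valid everywhere else
  cal <- cfg$calendar
  cal_dates <- unclass(as.Date(cal))
  src <- character(n)
  for (i in seq_len(n)) {
    if (A[i, "SOURCE_INCONGRUENT"]) {
      after <- names(cal)[!is.na(cal_dates) & cal_dates > unclass(sub_date[i])]
      if (!length(after))
        stop("infeasible configuration: no dissemination channel postdates ",
             sub_date[i], call. = FALSE)
      src[i] <- after[which.max(cal_dates[match(after, names(cal))])]
    } else {
      before <- names(cal)[!is.na(cal_dates) &
                             cal_dates <= unclass(sub_date[i])]
      if (!length(before))
        stop("infeasible configuration: submission predates every channel",
             call. = FALSE)
      src[i] <- if (length(before) == 1L) before else sample(before, 1L)
    }
  }

  # cancer type (single selection), then sex/gender consistent with it
  legit_type_probs <- c(breast = 0.50, colorectal = 0.07, blood = 0.08,
                        melanoma = 0.05, uterine_cervical = 0.055,
                        thyroid = 0.055, prostate = 0.06, lung = 0.04,
                        kidney = 0.015, bladder = 0.015, other = 0.11)
  fraud_type_probs <- c(lung = 0.17, breast = 0.15, uterine_cervical = 0.14,
                        colorectal = 0.11, thyroid = 0.08, prostate = 0.08,
                        kidney = 0.06, bladder = 0.075, melanoma = 0.05,
                        blood = 0.075, other = 0.01)
  ctype <- character(n)
  ctype[nl] <- sample(names(legit_type_probs), sum(nl), TRUE,
                      prob = legit_type_probs)
  if (length(fraud_rows))
    ctype[fraud_rows] <- sample(names(fraud_type_probs), length(fraud_rows),
                                TRUE, prob = fraud_type_probs)
  rare_planted <- A[, "RARE_CANCER_YOUNG"]
  if (any(rare_planted))
    ctype[rare_planted] <- sample(c("lung", "kidney", "bladder"),
                                  sum(rare_planted), TRUE)
  # clean records under the young-age cutoff must avoid the rare catalog
  safe_types <- c("breast", "colorectal", "blood", "melanoma", "thyroid",
                  "other")
  fix <- !rare_planted & age < th$young_age_cutoff &
    ctype %in% rare_cancer_catalog()
  if (any(fix)) ctype[fix] <- sample(safe_types, sum(fix), TRUE)

  gender <- character(n)
  sex <- character(n)
  g_levels <- c("cisgender_female", "cisgender_male", "other",
                "transgender_male")
  legit_g <- c(0.72, 0.21, 0.05, 0.02)
  fraud_g <- c(0.43, 0.52, 0.02, 0.03)
  gender[nl] <- sample(g_levels, sum(nl), TRUE, prob = legit_g)
  if (length(fraud_rows))
    gender[fraud_rows] <- sample(g_levels, length(fraud_rows), TRUE,
                                 prob = fraud_g)
  sex <- dplyr::case_match(gender,
                           "cisgender_female" ~ "female",
                           "cisgender_male" ~ "male",
                           "transgender_male" ~ "female",
                           .default = "female")
  forced_f <- ctype == "uterine_cervical"
  forced_m <- ctype == "prostate"
  sex[forced_f] <- "female"; gender[forced_f] <- "cisgender_female"
  sex[forced_m] <- "male"; gender[forced_m] <- "cisgender_male"

  # diagnosis / treatment timeline (consistent unless planted)
  dx <- sample(c("lt2", "2to5", "gt5"), n, TRUE, prob = c(0.40, 0.37, 0.23))
  tx <- unname(vapply(dx, function(d) switch(d,
    lt2 = "lt2",
    `2to5` = sample(c("lt2", "2to5"), 1L, prob = c(0.45, 0.55)),
    gt5 = sample(c("lt2", "2to5", "gt5"), 1L, prob = c(0.2, 0.3, 0.5))),
    character(1)))
  t1 <- A[, CODE_T1]; t2 <- A[, CODE_T2]
  dx[t1] <- "lt2"; tx[t1] <- "2to5"
  if (any(t2)) dx[t2] <- sample(c("lt2", "2to5"), sum(t2), TRUE)
  tx[t2] <- "gt5"
  dx_offset <- vapply(dx, function(d) switch(d,
    lt2 = sample(0:1, 1L), `2to5` = sample(2:5, 1L),
    gt5 = sample(6:15, 1L)), integer(1))
  age_dx <- as.integer(clamp(age - dx_offset, 16, 90))

  # date of birth: consistent with reported age unless discordance planted
  dob <- sub_date - round((age + 0.4) * 365.25)
  ad <- which(A[, "AGE_DISCORD"])
  if (length(ad)) {
    v1 <- ad[seq_along(ad) %% 2L == 1L]   # degenerate survey-year DOB
    v2 <- ad[seq_along(ad) %% 2L == 0L]   # off-by-many-years DOB
    dob[v1] <- as.Date(paste0(format(sub_date[v1], "%Y"), "-01-15"))
    if (length(v2))
      dob[v2] <- sub_date[v2] -
        round((age[v2] + sample(5:30, length(v2), TRUE) + 0.4) * 365.25)
  }

  # identity fields
  pools <- generator_name_pools()
  draw_first <- function(k, sexes) {
    out <- character(k)
    f <- sexes == "female"
    out[f] <- sample(pools$female, sum(f), replace = TRUE)
    out[!f] <- sample(pools$male, sum(!f), replace = TRUE)
    out
  }
  first <- draw_first(n, sex)
  last <- sample(pools$surnames, n, replace = TRUE)
  suffix <- rep(NA_character_, n)
  email <- sprintf("%s.%s.%d@%s", tolower(first), tolower(last), seq_len(n),
                   sample(EMAIL_DOMAINS, n, TRUE))
  address <- sprintf("%d %s %s, %s, %s %05d",
                     sample(100:9999, n, TRUE),
                     sample(STREET_NAMES, n, TRUE),
                     sample(STREET_TYPES, n, TRUE),
                     sample(CITY_NAMES, n, TRUE),
                     sample(STATE_CODES, n, TRUE),
                     sample(10000:99999, n, TRUE))

  sn <- which(A[, "SUSPICIOUS_NAME"])
  if (length(sn)) {
    variant <- seq_along(sn) %% 3L
    flip <- sn[variant == 1L]
    first[flip] <- sample(pools$surname_only, length(flip), TRUE)
    last[flip] <- sample(pools$given_only, length(flip), TRUE)
    sfx_junk <- sn[variant == 2L]
    suffix[sfx_junk] <- sample(c("Jr4", "X9", "2b"), length(sfx_junk), TRUE)
    sfx_gender <- sn[variant == 0L]
    first[sfx_gender] <- sample(pools$given_only_female,
                                length(sfx_gender), TRUE)
    suffix[sfx_gender] <- "Jr"
  }
  se <- which(A[, "SUSPICIOUS_EMAIL_ADDRESS"])
  if (length(se)) {
    # records also planted as duplicate emails keep the shared email and
    # take the suspicious-address variant instead
    email_variant <- seq_along(se) %% 2L == 1L & !A[se, "DUP_EMAIL"]
    v_email <- se[email_variant]
    v_addr <- se[!email_variant]
    email[v_email] <- paste0(
      random_run_local(length(v_email), th$random_run_min_length + 2L),
      "@mail.com")
    address[v_addr] <- sprintf("\"%s\" %d %s",
                               sample(STREET_NAMES, length(v_addr), TRUE),
                               sample(100:999, length(v_addr), TRUE),
                               sample(CITY_NAMES, length(v_addr), TRUE))
  }
  de <- which(A[, "DUP_EMAIL"])
  if (length(de)) {
    base_local <- paste0(tolower(sample(pools$given_only, 1L)), ".",
                         tolower(sample(pools$surname_only, 1L)), ".home")
    shared <- paste0(base_local, "@gmail.com")
    shared_uc <- paste0(toupper(substr(shared, 1, 1)),
                        substr(shared, 2, nchar(shared)))
    email[de] <- ifelse(seq_along(de) %% 2L == 0L, shared_uc, shared)
  }

  # open text
  tele <- paste0(sample(TELEHEALTH_TEMPLATES, n, TRUE),
                 " Visit note ", seq_len(n), ".")
  sugg <- paste0(sample(SUGGESTION_TEMPLATES, n, TRUE),
                 " Note ", seq_len(n), ".")
  off <- which(A[, "OFFTOPIC_TEXT"])
  if (length(off))
    tele[off] <- paste0(sample(OFFTOPIC_TEMPLATES, length(off), TRUE),
                        " Case ", off, ".")
  tele[A[, "DUP_TELEHEALTH"]] <- DUP_TELEHEALTH_TEXT
  sugg[A[, "DUP_SUGGESTION"]] <- DUP_SUGGESTION_TEXT

  # remaining demographics, class-conditional
  pick <- function(levels, p_legit, p_fraud) {
    out <- character(n)
    out[nl] <- sample(levels, sum(nl), TRUE, prob = p_legit)
    if (length(fraud_rows))
      out[fraud_rows] <- sample(levels, length(fraud_rows), TRUE,
                                prob = p_fraud)
    out
  }
  orientation <- pick(c("straight", "lgbq_two_spirit", "other"),
                      c(0.93, 0.04, 0.03), c(0.91, 0.08, 0.01))
  marital <- pick(SINGLE_LEVELS$marital_status,
                  c(0.16, 0.68, 0.11, 0.05), c(0.14, 0.82, 0.03, 0.01))
  education <- pick(SINGLE_LEVELS$education,
                    c(0.03, 0.16, 0.29, 0.27, 0.25),
                    c(0.04, 0.27, 0.38, 0.24, 0.07))
  income <- pick(SINGLE_LEVELS$income_bracket,
                 c(0.10, 0.19, 0.22, 0.11, 0.22, 0.16),
                 c(0.04, 0.35, 0.35, 0.17, 0.08, 0.01))
  stage <- pick(c("I", "II", "III", "IV", "unknown"),
                c(0.30, 0.30, 0.16, 0.11, 0.13),
                c(0.42, 0.34, 0.16, 0.05, 0.03))
  health <- pick(SINGLE_LEVELS$self_reported_health,
                 c(0.29, 0.40, 0.18, 0.13), c(0.35, 0.29, 0.24, 0.12))
  race <- pick(c("white", "black", "hispanic_latinx", "asian",
                 "native_american_ak_pi", "other"),
               c(0.72, 0.14, 0.07, 0.03, 0.03, 0.01),
               c(0.60, 0.18, 0.08, 0.05, 0.08, 0.01))
  care <- pick(c("remission_ned", "chronic", "palliative", "hospice",
                 "none_apply"),
               c(0.78, 0.13, 0.05, 0.00001, 0.04),
               c(0.55, 0.21, 0.16, 0.05, 0.03))
  care[nl & care == "hospice"] <- "remission_ned"
  employment <- pick(c("retired", "paid_work", "unpaid_work", "unemployed"),
                     c(0.35, 0.44, 0.08, 0.13), c(0.04, 0.62, 0.12, 0.22))
  insurance <- pick(c("private", "medicaid", "medicare",
                      "tricare_cobra_other", "none"),
                    c(0.45, 0.12, 0.30, 0.07, 0.06),
                    c(0.25, 0.30, 0.37, 0.04, 0.04))
  household <- integer(n)
  household[nl] <- as.integer(clamp(round(rnorm(sum(nl), 2.6, 1.3)), 1, 10))
  if (length(fraud_rows))
    household[fraud_rows] <- as.integer(clamp(round(rnorm(
      length(fraud_rows), 3.3, 0.9)), 1, 10))
  tribe <- logical(n)
  tribe[nl] <- runif(sum(nl)) < 0.072
  if (length(fraud_rows))
    tribe[fraud_rows] <- runif(length(fraud_rows)) < 0.381

  cohort <- cohort_template(n, schema)
  cohort$respondent_id <- id
  cohort$submission_timestamp <- ts
  cohort$survey_source <- src
  cohort$reported_age <- age
  cohort$date_of_birth <- dob
  cohort$sex_assigned_at_birth <- sex
  cohort$sexual_orientation <- orientation
  cohort$marital_status <- marital
  cohort$household_size <- household
  cohort$education <- education
  cohort$income_bracket <- income
  cohort$cancer_stage <- stage
  cohort$age_at_diagnosis <- age_dx
  cohort$time_since_diagnosis <- dx
  cohort$time_since_treatment <- tx
  cohort$tribe_or_territory <- tribe
  cohort$self_reported_health <- health
  cohort$telehealth_comment <- tele
  cohort$final_suggestion <- sugg
  cohort$email <- email
  cohort$first_name <- first
  cohort$last_name <- last
  cohort$name_suffix <- suffix
  cohort$postal_address <- address

  set_checkbox <- function(cohort, group, values) {
    for (col in checkbox_cols(group)) cohort[[col]] <- 0L
    for (lv in unique(values[!is.na(values)])) {
      cohort[[paste0(group, "___", lv)]][!is.na(values) & values == lv] <- 1L
    }
    cohort
  }
  cohort <- set_checkbox(cohort, "gender", gender)
  cohort <- set_checkbox(cohort, "race", race)
  cohort <- set_checkbox(cohort, "cancer_type", ctype)
  cohort <- set_checkbox(cohort, "care_status", care)
  cohort <- set_checkbox(cohort, "employment", employment)
  cohort <- set_checkbox(cohort, "insurance", insurance)

  cohort <- apply_stage1_plantings(cohort, reason, th, schema)
  cohort <- sanitize_clean_identities(cohort, A, th, pools)

  planted <- apply(A, 1L, function(r) colnames(A)[r], simplify = FALSE)
  truth <- tibble::tibble(respondent_id = id, class = class,
                          stage1_reason = reason)
  for (cd in INDICATOR_CODES) truth[[cd]] <- A[, cd]
  truth$planted <- planted
  truth$planted_count <- as.integer(rowSums(A))
  list(cohort = cohort, truth = truth)
}

# Instantiate stage-1 reasons on the ineligible class. Each planted record
# fails exactly its own stage: earlier-stage fields are kept clean so that
# first-failure attribution recovers the planted reason.
apply_stage1_plantings <- function(cohort, reason, th, schema) {
  clear_group <- function(cohort, group, rows) {
    for (col in checkbox_cols(group)) cohort[[col]][rows] <- 0L
    cohort
  }
  set_only <- function(cohort, group, level, rows) {
    cohort <- clear_group(cohort, group, rows)
    cohort[[paste0(group, "___", level)]][rows] <- 1L
    cohort
  }
  r <- function(code) which(!is.na(reason) & reason == code)

  rows <- r("non_us")
  cohort$country_of_residence[rows] <-
    sample(c("Canada", "United Kingdom", "Australia"), length(rows), TRUE)
  rows <- r("stage_0")
  cohort$cancer_stage[rows] <- "0"
  rows <- r("no_diagnosis")
  if (length(rows)) {
    cohort <- clear_group(cohort, "cancer_type", rows)
    cohort$cancer_stage[rows] <- "none"
    cohort$age_at_diagnosis[rows] <- NA_integer_
    cohort$time_since_diagnosis[rows] <- NA_character_
    cohort$time_since_treatment[rows] <- NA_character_
    cohort <- set_only(cohort, "care_status", "none_apply", rows)
  }
  rows <- r("nonmelanoma_only")
  if (length(rows)) cohort <- set_only(cohort, "cancer_type",
                                       "nonmelanoma_skin", rows)
  rows <- r("discordant_gender")
  if (length(rows)) {
    cohort <- clear_group(cohort, "gender", rows)
    cohort[["gender___cisgender_male"]][rows] <- 1L
    cohort[["gender___cisgender_female"]][rows] <- 1L
  }
  rows <- r("discordant_sex_site")
  if (length(rows)) {
    cohort$sex_assigned_at_birth[rows] <- "male"
    cohort <- set_only(cohort, "cancer_type", "uterine_cervical", rows)
    cohort <- set_only(cohort, "gender", "cisgender_male", rows)
  }
  rows <- r("excess_missingness")
  if (length(rows)) {
    inventory <- schema$inventory
    protected <- c("survey_source", "country_of_residence", "cancer_stage",
                   "cancer_type")
    blankable <- setdiff(names(inventory), protected)
    k <- ceiling(th$missingness_cutoff * length(inventory))
    if (k > length(blankable))
      stop("infeasible configuration: missingness planting cannot reach ",
           "the cutoff without touching eligibility fields", call. = FALSE)
    for (row in rows) {
      items <- sample(blankable, k)
      for (it in items) {
        cols <- inventory[[it]]
        if (length(cols) > 1L) {
          for (col in cols) cohort[[col]][row] <- 0L
        } else {
          cohort[[cols]][row] <- NA
        }
      }
    }
  }
  cohort
}

# Clean records occasionally collide with the identity heuristics (e.g. a
# drawn surname contained in the given name). Re-draw those identities
# until no unplanted record fires, keeping planted rows untouched.
sanitize_clean_identities <- function(cohort, A, th, pools) {
  for (iter in seq_len(10L)) {
    name_hit <- flag_suspicious_name(cohort) & !A[, "SUSPICIOUS_NAME"]
    mail_hit <- flag_suspicious_email_address(cohort, th) &
      !A[, "SUSPICIOUS_EMAIL_ADDRESS"]
    if (!any(name_hit | mail_hit)) return(cohort)
    redo <- which(name_hit | mail_hit)
    for (row in redo) {
      fn_pool <- if (cohort$sex_assigned_at_birth[row] %in% "male")
        pools$male else pools$female
      cohort$first_name[row] <- sample(fn_pool, 1L)
      cohort$last_name[row] <- sample(pools$surnames, 1L)
      if (!A[row, "DUP_EMAIL"] && !A[row, "SUSPICIOUS_EMAIL_ADDRESS"])
        cohort$email[row] <- sprintf("%s.%s.%d@%s",
                                     tolower(cohort$first_name[row]),
                                     tolower(cohort$last_name[row]), row,
                                     sample(EMAIL_DOMAINS, 1L))
      cohort$postal_address[row] <- sprintf(
        "%d %s %s, %s, %s %05d", sample(100:9999, 1L),
        sample(STREET_NAMES, 1L), sample(STREET_TYPES, 1L),
        sample(CITY_NAMES, 1L), sample(STATE_CODES, 1L),
        sample(10000:99999, 1L))
    }
  }
  stop("internal error: could not generate rule-clean identities",
       call. = FALSE)
}

#' Compare pipeline decisions against generator ground truth
#'
#' Sensitivity is the fraction of fraud records excluded by the pipeline
#' (at any stage); specificity is the fraction of legitimate records
#' retained. Per-indicator recovery counts, computed over the fraud class,
#' compare each detector's firings with the planted truth.
#'
#' @param decisions Decision tibble from [run_pipeline()].
#' @param truth Truth tibble from [generate_cohort()].
#' @return List with `sensitivity`, `specificity`, `stage1_recovery`
#'   (fraction of ineligible records removed at their planted stage) and
#'   `per_indicator` (tibble with planted/detected/true-positive/
#'   false-negative/false-positive counts per code).
#' @export
evaluate_detection <- function(decisions, truth) {
  if (!setequal(decisions$respondent_id, truth$respondent_id))
    stop("decisions and truth cover different respondents", call. = FALSE)
  d <- dplyr::inner_join(decisions, truth, by = "respondent_id")
  excluded <- d$outcome != "retained"
  fraud <- d$class == "fraud"
  legit <- d$class == "legit"
  inel <- d$class == "ineligible"
  stage_map <- c(non_us = "ineligible_core", stage_0 = "ineligible_core",
                 no_diagnosis = "ineligible_core",
                 nonmelanoma_only = "nonmelanoma_only",
                 excess_missingness = "excess_missingness",
                 discordant_gender = "discordant_gender",
                 discordant_sex_site = "discordant_sex_site")
  per <- lapply(INDICATOR_CODES, function(cd) {
    det <- vapply(d$indicators, function(f) cd %in% f, logical(1))
    pl <- d[[cd]]
    tibble::tibble(code = cd,
                   planted = sum(pl[fraud]),
                   detected = sum(det[fraud]),
                   true_pos = sum(pl[fraud] & det[fraud]),
                   false_neg = sum(pl[fraud] & !det[fraud]),
                   false_pos = sum(!pl & det & !is.na(d$indicator_count)))
  })
  list(
    sensitivity = if (any(fraud)) mean(excluded[fraud]) else NA_real_,
    specificity = if (any(legit)) mean(!excluded[legit]) else NA_real_,
    stage1_recovery = if (any(inel))
      mean(d$outcome[inel] == stage_map[d$stage1_reason[inel]])
      else NA_real_,
    per_indicator = dplyr::bind_rows(per)
  )
}
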