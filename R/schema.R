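# Survey response schema: column inventory, checkbox (multi-select) groups,
# and the question inventory that defines the missingness denominator.

CHECKBOX_GROUPS <- list(
  gender = c("cisgender_male", "cisgender_female", "transgender_male",
             "transgender_female", "gender_fluid", "two_spirit", "other",
             "prefer_not_to_answer", "do_not_understand"),
  race = c("asian", "black", "hispanic_latinx", "native_american_ak_pi",
           "white", "other", "prefer_not_to_answer"),
  cancer_type = c("melanoma", "lung", "prostate", "breast", "colorectal",
                  "kidney", "bladder", "blood", "uterine_cervical", "thyroid",
                  "nonmelanoma_skin", "other"),
  care_status = c("remission_ned", "chronic", "palliative", "hospice",
                  "none_apply"),
  employment = c("retired", "paid_work", "unpaid_work", "unemployed"),
  insurance = c("private", "medicaid", "medicare", "tricare_cobra_other",
                "none")
)

SINGLE_LEVELS <- list(
  sex_assigned_at_birth = c("male", "female", "intersex",
                            "prefer_not_to_answer"),
  sexual_orientation = c("straight", "lgbq_two_spirit", "other",
                         "prefer_not_to_answer", "do_not_understand"),
  marital_status = c("single", "married_partnered", "divorced_separated",
                     "widowed"),
  education = c("some_high_school", "high_school_ged_vocational",
                "some_college", "four_year_degree", "graduate_school"),
  income_bracket = c("lt_25k", "25k_50k", "50k_75k", "75k_100k", "gt_100k",
                     "prefer_not_to_answer"),
  cancer_stage = c("0", "I", "II", "III", "IV", "unknown", "none"),
  time_since_diagnosis = c("lt2", "2to5", "gt5"),
  time_since_treatment = c("lt2", "2to5", "gt5"),
  self_reported_health = c("excellent_very_good", "good", "fair", "poor")
)

SINGLE_TYPES <- c(
  respondent_id = "character",
  submission_timestamp = "datetime",
  survey_source = "character",
  survey_source_other = "character",
  reported_age = "integer",
  date_of_birth = "date",
  sex_assigned_at_birth = "factorlike",
  sexual_orientation = "factorlike",
  marital_status = "factorlike",
  household_size = "integer",
  education = "factorlike",
  income_bracket = "factorlike",
  country_of_residence = "character",
  cancer_stage = "factorlike",
  age_at_diagnosis = "integer",
  time_since_diagnosis = "factorlike",
  time_since_treatment = "factorlike",
  tribe_or_territory = "logical",
  self_reported_health = "factorlike",
  telehealth_comment = "character",
  final_suggestion = "character",
  email = "character",
  first_name = "character",
  last_name = "character",
  name_suffix = "character",
  postal_address = "character",
  honeypot_value = "character",
  retyped_word = "character",
  acknowledgement_checked = "logical"
)

checkbox_cols <- function(group) {
  paste0(group, "___", CHECKBOX_GROUPS[[group]])
}

#' Survey response schema
#'
#' Describes the wide, one-row-per-respondent layout the screening pipeline
#' operates on: single-valued columns, multi-select checkbox groups encoded
#' REDCap-style as one 0/1 column per level (`group___level`), and the
#' question inventory used as the denominator of the missingness rule.
#'
#' The default inventory counts every substantive survey item (demographics,
#' cancer history, open text, survey source) and deliberately leaves out
#' identity and anti-bot fields (name, email, postal address, honeypot,
#' retyped word, acknowledgement): a respondent skipping those is not
#' "missing data" in the eligibility sense. A "prefer not to answer"
#' selection is an answer, not a missing item.
#'
#' @return An object of class `survey_schema`: a list with elements
#'   `single` (named type vector), `checkbox` (named list of level sets),
#'   `levels` (level sets for single-select columns), `columns` (all column
#'   names in canonical order) and `inventory` (named list mapping each
#'   counted question to its column(s)).
#' @export
survey_schema <- function() {
  columns <- c(names(SINGLE_TYPES),
               unlist(lapply(names(CHECKBOX_GROUPS), checkbox_cols),
                      use.names = FALSE))
  inventory_items <- c(
    "survey_source", "reported_age", "date_of_birth", "sex_assigned_at_birth",
    "sexual_orientation", "marital_status", "household_size", "education",
    "income_bracket", "country_of_residence", "cancer_stage",
    "age_at_diagnosis", "time_since_diagnosis", "time_since_treatment",
    "tribe_or_territory", "self_reported_health", "telehealth_comment",
    "final_suggestion"
  )
  inventory <- c(
    setNames(as.list(inventory_items), inventory_items),
    lapply(setNames(names(CHECKBOX_GROUPS), names(CHECKBOX_GROUPS)),
           checkbox_cols)
  )
  structure(
    list(single = SINGLE_TYPES, checkbox = CHECKBOX_GROUPS,
         levels = SINGLE_LEVELS, columns = columns, inventory = inventory),
    class = "survey_schema"
  )
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("<survey_schema>\n")
  cat("  ", length(x$columns), " columns (", length(x$single),
      " single-valued, ", length(x$checkbox), " checkbox groups)\n", sep = "")
  cat("  ", length(x$inventory),
      " questions in the missingness inventory\n", sep = "")
  invisible(x)
}

#' Screening thresholds
#'
#' Numeric constants of the screening procedure. Defaults are the values the
#' procedure was defined with: elimination at >= 35% item missingness,
#' elimination at >= 2 suspicious indicators, age discordance beyond 1 year,
#' rare-cancer flag below age 40, submission bursts of >= 10 responses with
#' successive gaps of <= 5 minutes, a midnight-to-4-AM Eastern night window,
#' and >= 10-character random alphanumeric runs in email addresses.
#'
#' @param missingness_cutoff Fraction of inventory questions missing at or
#'   above which a response is removed (default 0.35).
#' @param indicator_elimination_count Number of suspicious indicators at or
#'   above which a response is removed (default 2).
#' @param age_discordance_years Allowed difference, in whole years, between
#'   reported age and age computed from date of birth (default 1).
#' @param young_age_cutoff Age, in years, below which the rare-cancer
#'   indicator applies (default 40).
#' @param burst_min_run Minimum run length for the submission-burst rule
#'   (default 10).
#' @param burst_max_gap_minutes Maximum gap, in minutes, between successive
#'   submissions within a burst (default 5).
#' @param night_window Two clock hours (Eastern) bounding the night-time
#'   submission window, closed on the left, open on the right
#'   (default `c(0, 4)`, i.e. midnight to 4 AM).
#' @param random_run_min_length Minimum length of an alphanumeric run in an
#'   email local part for the random-run rule (default 10).
#' @param duplicate_min_chars Minimum normalized length for an open-text
#'   answer to participate in duplicate matching (default 15); shorter texts
#'   such as "none" or "n/a" never flag.
#' @param address_min_tokens Minimum whitespace-separated tokens for a
#'   postal address to count as complete (default 4).
#' @return A `screening_thresholds` list.
#' @export
screening_thresholds <- function(missingness_cutoff = 0.35,
                                 indicator_elimination_count = 2L,
                                 age_discordance_years = 1L,
                                 young_age_cutoff = 40L,
                                 burst_min_run = 10L,
                                 burst_max_gap_minutes = 5,
                                 night_window = c(0L, 4L),
                                 random_run_min_length = 10L,
                                 duplicate_min_chars = 15L,
                                 address_min_tokens = 4L) {
  th <- list(missingness_cutoff = missingness_cutoff,
             indicator_elimination_count = as.integer(indicator_elimination_count),
             age_discordance_years = as.integer(age_discordance_years),
             young_age_cutoff = as.integer(young_age_cutoff),
             burst_min_run = as.integer(burst_min_run),
             burst_max_gap_minutes = burst_max_gap_minutes,
             night_window = as.integer(night_window),
             random_run_min_length = as.integer(random_run_min_length),
             duplicate_min_chars = as.integer(duplicate_min_chars),
             address_min_tokens = as.integer(address_min_tokens))
  scalar <- th[setdiff(names(th), "night_window")]
  if (any(vapply(scalar, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("all screening thresholds must be strictly positive", call. = FALSE)
  if (length(th$night_window) != 2L || th$night_window[1] >= th$night_window[2])
    stop("night_window must be an increasing pair of clock hours", call. = FALSE)
  structure(th, class = "screening_thresholds")
}

#' Dissemination calendar
#'
#' Maps each survey dissemination channel to the earliest date (US Eastern)
#' on which the survey was distributed through it. A respondent claiming a
#' source before that source existed is flagged by the source-incongruence
#' indicator. A source mapped to `NA` is explicitly "unknown" and never
#' flags. The defaults reflect the study calendar the procedure was built
#' around: community partners and professional listservs from October 8,
#' 2020, the social-media posting window opening October 9, 2020, and the
#' accredited-center email (with the newsletter) on October 13, 2020.
#'
#' @param ... Named dates (anything `as.Date()` accepts) overriding or
#'   extending the default entries; use `NA` for an explicitly unknown
#'   source.
#' @return A named `Date` vector of class `dissemination_calendar`.
#' @export
#' @examples
#' dissemination_calendar(patient_portal = "2020-10-20")
dissemination_calendar <- function(...) {
  defaults <- c(coc_email = "2020-10-13",
                community_partner = "2020-10-08",
                professional_listserv = "2020-10-08",
                social_media = "2020-10-09",
                newsletter = "2020-10-13")
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("calendar entries must be named by survey source", call. = FALSE)
    defaults[names(extra)] <- vapply(extra, function(d)
      if (is.na(d)) NA_character_ else as.character(as.Date(d)), character(1))
  }
  structure(as.Date(defaults), names = names(defaults),
            class = c("dissemination_calendar", "Date"))
}

#' Template cohort with clean default values
#'
#' Returns an `n`-row cohort tibble with every schema column present and
#' filled with internally consistent, rule-clean values: US residents with a
#' staged cancer diagnosis, a date of birth agreeing with the reported age,
#' unique emails and open-text answers, and daytime submission timestamps
#' spaced ten minutes apart. Useful as a starting point for constructing
#' examples and tests by perturbing single fields.
#'
#' @param n Number of rows.
#' @param schema A [survey_schema()].
#' @return A tibble with `n` rows.
#' @export
cohort_template <- function(n, schema = survey_schema()) {
  ts <- lubridate::ymd_hms("2020-10-20 09:00:00", tz = EASTERN_TZ) +
    (seq_len(n) - 1L) * 600
  age <- rep(55L, n)
  dob <- as.Date(ts, tz = EASTERN_TZ) - round((age + 0.4) * 365.25)
  df <- tibble::tibble(
    respondent_id = sprintf("R%05d", seq_len(n)),
    submission_timestamp = ts,
    survey_source = "community_partner",
    survey_source_other = NA_character_,
    reported_age = age,
    date_of_birth = dob,
    sex_assigned_at_birth = "female",
    sexual_orientation = "straight",
    marital_status = "married_partnered",
    household_size = 2L,
    education = "four_year_degree",
    income_bracket = "50k_75k",
    country_of_residence = "United States",
    cancer_stage = "II",
    age_at_diagnosis = 50L,
    time_since_diagnosis = "2to5",
    time_since_treatment = "2to5",
    tribe_or_territory = FALSE,
    self_reported_health = "good",
    telehealth_comment = paste0(
      "My oncologist was helpful during the telehealth visit number ",
      seq_len(n), "."),
    final_suggestion = paste0(
      "Please keep offering telehealth appointments for follow up care, note ",
      seq_len(n), "."),
    email = sprintf("alice.carter.%d@example.org", seq_len(n)),
    first_name = "Alice",
    last_name = "Carter",
    name_suffix = NA_character_,
    postal_address = "120 Maple St, Dayton, OH 45402",
    honeypot_value = NA_character_,
    retyped_word = "purple",
    acknowledgement_checked = TRUE
  )
  for (grp in names(schema$checkbox)) {
    for (col in checkbox_cols(grp)) df[[col]] <- 0L
  }
  df[["gender___cisgender_female"]] <- 1L
  df[["race___white"]] <- 1L
  df[["cancer_type___breast"]] <- 1L
  df[["care_status___remission_ned"]] <- 1L
  df[["employment___paid_work"]] <- 1L
  df[["insurance___private"]] <- 1L
  df[, schema$columns]
}

# ---- reading and writing -------------------------------------------------

parse_timestamps <- function(x, assume_eastern = TRUE) {
  has_offset <- grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  out <- .POSIXct(rep(NA_real_, length(x)), tz = EASTERN_TZ)
  if (any(has_offset & !is.na(x))) {
    idx <- which(has_offset & !is.na(x))
    parsed <- lubridate::ymd_hms(x[idx], tz = "UTC", quiet = TRUE)
    out[idx] <- lubridate::with_tz(parsed, EASTERN_TZ)
  }
  idx <- which(!has_offset & !is.na(x))
  if (length(idx)) {
    tz <- if (assume_eastern) EASTERN_TZ else "UTC"
    parsed <- lubridate::ymd_hms(x[idx], tz = tz, quiet = TRUE)
    out[idx] <- lubridate::with_tz(parsed, EASTERN_TZ)
  }
  out
}

coerce_single <- function(x, type, levels = NULL) {
  switch(type,
    character = dplyr::na_if(x, ""),
    integer = suppressWarnings(as.integer(x)),
    date = suppressWarnings(as.Date(lubridate::ymd(x, quiet = TRUE))),
    logical = suppressWarnings(as.logical(x)),
    factorlike = {
      v <- dplyr::na_if(x, "")
      v[!is.na(v) & !(v %in% levels)] <- NA_character_
      v
    },
    x)
}

#' Read a cohort of survey responses
#'
#' Reads a delimited (CSV) REDCap-style export into the canonical cohort
#' tibble. Every schema column must be present; unparseable cells (a word in
#' an integer column, an unknown level in a categorical column) become
#' missing values rather than errors, so that malformed bot input flows into
#' the missingness rule instead of aborting the screen.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [survey_schema()].
#' @param assume_eastern Logical; if `TRUE` (default), timestamps without an
#'   explicit UTC offset are interpreted as US Eastern local time. Timestamps
#'   carrying an offset are always honored and converted to Eastern.
#' @return A cohort tibble with one row per respondent, columns in schema
#'   order, timestamps as Eastern `POSIXct`.
#' @export
read_responses <- function(path, schema = survey_schema(),
                           assume_eastern = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing_cols <- setdiff(schema$columns, names(raw))
  if (length(missing_cols))
    stop("input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, schema$columns]
  out <- raw
  for (col in names(schema$single)) {
    type <- schema$single[[col]]
    if (type == "datetime") {
      out[[col]] <- parse_timestamps(dplyr::na_if(raw[[col]], ""),
                                     assume_eastern)
    } else {
      out[[col]] <- coerce_single(raw[[col]], type, schema$levels[[col]])
    }
  }
  for (grp in names(schema$checkbox)) {
    for (col in checkbox_cols(grp)) {
      v <- suppressWarnings(as.integer(out[[col]]))
      v[!is.na(v) & !(v %in% c(0L, 1L))] <- NA_integer_
      out[[col]] <- v
    }
  }
  ids <- out$respondent_id
  if (anyNA(ids) || any(duplicated(ids)))
    stop("respondent_id must be present and unique within a cohort",
         call. = FALSE)
  tibble::as_tibble(out)
}

#' Write a cohort of survey responses
#'
#' Inverse of [read_responses()]: writes the cohort as RFC-4180 CSV with
#' timestamps rendered in Eastern local time with an explicit UTC offset, so
#' that a write/read round trip reproduces the cohort field for field.
#'
#' @param cohort Cohort tibble.
#' @param path Output file path.
#' @param schema A [survey_schema()].
#' @return Invisibly, `path`.
#' @export
write_responses <- function(cohort, path, schema = survey_schema()) {
  missing_cols <- setdiff(schema$columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- cohort[, schema$columns]
  ts <- out$submission_timestamp
  out$submission_timestamp <- ifelse(
    is.na(ts), NA_character_,
    format(lubridate::with_tz(ts, EASTERN_TZ), "%Y-%m-%dT%H:%M:%S%z"))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# ---- missingness ---------------------------------------------------------

#' Per-question missingness matrix
#'
#' For each question in the inventory, decides per respondent whether it was
#' answered. A single-valued question is missing when `NA` (or blank text);
#' a checkbox group is missing when no level is selected. A "prefer not to
#' answer" level is an answer.
#'
#' @param cohort Cohort tibble.
#' @param schema A [survey_schema()], or a named list mapping item names to
#'   character vectors of column names (a custom inventory).
#' @return Logical matrix, rows = respondents, columns = inventory items;
#'   `TRUE` means missing.
#' @export
item_missing_matrix <- function(cohort, schema = survey_schema()) {
  inventory <- if (inherits(schema, "survey_schema")) schema$inventory else schema
  if (!length(inventory)) stop("question inventory is empty", call. = FALSE)
  m <- vapply(inventory, function(cols) {
    if (length(cols) == 1L) {
      is_blank(cohort[[cols]])
    } else {
      sub <- as.matrix(cohort[, cols])
      rowSums(sub == 1L, na.rm = TRUE) == 0L
    }
  }, logical(nrow(cohort)))
  if (nrow(cohort) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(NULL, names(inventory)))
  m
}

#' Fraction of inventory questions missing per respondent
#'
#' The quantity compared against the 35% elimination cutoff: the number of
#' inventory questions left unanswered divided by the inventory size.
#'
#' @inheritParams item_missing_matrix
#' @return Numeric vector in \[0, 1\], one value per respondent.
#' @export
missingness_fraction <- function(cohort, schema = survey_schema()) {
  rowMeans(item_missing_matrix(cohort, schema))
}

# ---- configuration files -------------------------------------------------

#' Read screening thresholds and calendar from a YAML file
#'
#' Reads a YAML document with optional top-level keys `thresholds` (named
#' scalars passed to [screening_thresholds()]) and `calendar` (source-to-date
#' mapping passed to [dissemination_calendar()]).
#'
#' @param path Path to a YAML file.
#' @return List with elements `thresholds` and `calendar`.
#' @export
read_screening_settings <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(screening_thresholds, y$thresholds %||% list())
  cal <- do.call(dissemination_calendar, as.list(y$calendar %||% list()))
  list(thresholds = th, calendar = cal)
}
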