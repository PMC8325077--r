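# The twelve suspicious-response indicators, implemented as independent
# detectors. Record-local detectors are pure functions of one row plus
# configuration; duplicate and timing detectors operate on the whole cohort
# but are permutation-invariant. A response accumulating two or more
# indicators is eliminated by the pipeline.

INDICATOR_CODES <- c(
  "AGE_DISCORD", "RARE_CANCER_YOUNG", "SOURCE_INCONGRUENT", "OFFTOPIC_TEXT",
  "DUP_TELEHEALTH", "DUP_SUGGESTION", "DUP_EMAIL",
  "TIMELINE_DX_LT2_TX_2TO5", "TIMELINE_DX_LE5_TX_GT5",
  "SUSPICIOUS_TIMING", "SUSPICIOUS_EMAIL_ADDRESS", "SUSPICIOUS_NAME"
)

INDICATOR_LABELS <- c(
  AGE_DISCORD = "Reported age and age calculated from date of birth discordant",
  RARE_CANCER_YOUNG = "Reported age under 40 with a cancer type rare at that age",
  SOURCE_INCONGRUENT = "Survey source claimed before its dissemination date",
  OFFTOPIC_TEXT = "Open-ended comments about information technology, off topic",
  DUP_TELEHEALTH = "Open-ended telehealth comments are duplicates",
  DUP_SUGGESTION = "Final open-ended suggestions are duplicates",
  DUP_EMAIL = "Email addresses are duplicates",
  TIMELINE_DX_LT2_TX_2TO5 = "Diagnosis under 2 years ago but treatment 2-5 years ago",
  TIMELINE_DX_LE5_TX_GT5 = "Diagnosis 5 or fewer years ago but treatment over 5 years ago",
  SUSPICIOUS_TIMING = "Suspicious submission time (burst or midnight-4 AM Eastern)",
  SUSPICIOUS_EMAIL_ADDRESS = "Suspicious email or postal address",
  SUSPICIOUS_NAME = "Suspicious name or name suffix"
)

#' Indicator codes
#'
#' The twelve suspicious-response indicator codes, in reporting order.
#'
#' @param labels Logical; if `TRUE`, return the named descriptive labels.
#' @return Character vector.
#' @export
indicator_codes <- function(labels = FALSE) {
  if (labels) INDICATOR_LABELS else INDICATOR_CODES
}

# ---- record-local detectors ---------------------------------------------

#' Age discordance indicator
#'
#' Fires when the reported year of birth equals the submission year (a
#' degenerate date of birth, e.g. "2020") or when reported age and the age
#' computed from date of birth at submission differ by more than the allowed
#' number of years. A missing date of birth cannot fire; the age-difference
#' clause additionally requires a reported age.
#'
#' @param cohort Cohort tibble.
#' @param thresholds A [screening_thresholds()].
#' @return Logical vector.
#' @export
flag_age_discordance <- function(cohort, thresholds = screening_thresholds()) {
  dob <- cohort$date_of_birth
  age <- cohort$reported_age
  sub_date <- as.Date(cohort$submission_timestamp, tz = EASTERN_TZ)
  degenerate <- !is.na(dob) & !is.na(sub_date) &
    lubridate::year(dob) == lubridate::year(sub_date)
  calc_age <- floor(as.numeric(sub_date - dob) / 365.25)
  discord <- !is.na(dob) & !is.na(age) & !is.na(calc_age) &
    abs(age - calc_age) > thresholds$age_discordance_years
  degenerate | discord
}

#' Rare-cancer-at-young-age indicator
#'
#' Fires when the reported age is below the young-age cutoff and any
#' reported cancer type belongs to the rare-below-cutoff catalog.
#'
#' @param cohort Cohort tibble.
#' @param catalog A [rare_cancer_catalog()].
#' @param thresholds A [screening_thresholds()].
#' @return Logical vector.
#' @export
flag_rare_cancer_young <- function(cohort, catalog = rare_cancer_catalog(),
                                   thresholds = screening_thresholds()) {
  types <- selected_levels(cohort, "cancer_type")
  rare <- rowSums(types[, intersect(catalog, colnames(types)),
                        drop = FALSE]) > 0L
  age <- cohort$reported_age
  !is.na(age) & age < thresholds$young_age_cutoff & rare
}

#' Source-incongruence indicator
#'
#' Fires when the claimed survey source has a known earliest dissemination
#' date and the submission date (Eastern) precedes it. Sources missing from
#' the calendar, or mapped to `NA`, never fire (and missing sources are
#' reported via a warning so a calendar gap is never silent).
#'
#' @param cohort Cohort tibble.
#' @param calendar A [dissemination_calendar()].
#' @return Logical vector.
#' @export
flag_source_incongruence <- function(cohort,
                                     calendar = dissemination_calendar()) {
  src <- cohort$survey_source
  unknown <- setdiff(unique(src[!is.na(src)]), names(calendar))
  if (length(unknown))
    warning("survey source(s) absent from the dissemination calendar ",
            "(treated as unknown, never flagged): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  earliest <- unname(unclass(calendar)[match(src, names(calendar))])
  sub_date <- unclass(as.Date(cohort$submission_timestamp, tz = EASTERN_TZ))
  !is.na(earliest) & !is.na(sub_date) & sub_date < earliest
}

#' Off-topic open-text indicator
#'
#' Fires when any open-text field (telehealth comment, final suggestion)
#' contains at least one term from the off-topic (information-technology)
#' lexicon and no term from the on-topic (care-related) lexicon. Empty text
#' never fires.
#'
#' @param cohort Cohort tibble.
#' @param lexicons List with `offtopic` and `ontopic` character vectors,
#'   see [default_lexicons()].
#' @return Logical vector.
#' @export
flag_offtopic_text <- function(cohort, lexicons = default_lexicons()) {
  field_hit <- function(x) {
    toks <- text_tokens(x)
    vapply(toks, function(tk) {
      if (!length(tk) || all(is.na(tk))) return(FALSE)
      any(tk %in% lexicons$offtopic) && !any(tk %in% lexicons$ontopic)
    }, logical(1))
  }
  field_hit(cohort$telehealth_comment) | field_hit(cohort$final_suggestion)
}

#' Timeline-inconsistency indicators
#'
#' The two contradictions between ordinal time since diagnosis and time
#' since treatment: diagnosis under 2 years ago with treatment 2-5 years
#' ago, and diagnosis 5 or fewer years ago with treatment more than 5 years
#' ago. Treatment cannot precede diagnosis, so either combination is
#' impossible. A missing category never fires.
#'
#' @param cohort Cohort tibble.
#' @return Tibble with logical columns `TIMELINE_DX_LT2_TX_2TO5` and
#'   `TIMELINE_DX_LE5_TX_GT5`.
#' @export
flag_timeline_inconsistency <- function(cohort) {
  dx <- cohort$time_since_diagnosis
  tx <- cohort$time_since_treatment
  tibble::tibble(
    TIMELINE_DX_LT2_TX_2TO5 = !is.na(dx) & !is.na(tx) &
      dx == "lt2" & tx == "2to5",
    TIMELINE_DX_LE5_TX_GT5 = !is.na(dx) & !is.na(tx) &
      dx %in% c("lt2", "2to5") & tx == "gt5"
  )
}

# ---- cohort-level detectors ---------------------------------------------

#' Duplicate open-text indicator
#'
#' Normalizes the chosen open-text field (lower case, punctuation stripped,
#' whitespace collapsed) and flags every respondent whose non-empty
#' normalized text is shared by at least two respondents. Texts shorter than
#' the configured minimum never flag, so trivial answers ("none", "n/a") do
#' not create duplicate groups.
#'
#' @param cohort Cohort tibble.
#' @param field `"telehealth_comment"` or `"final_suggestion"`.
#' @param thresholds A [screening_thresholds()].
#' @return Character vector of flagged `respondent_id`s.
#' @export
flag_duplicate_text <- function(cohort,
                                field = c("telehealth_comment",
                                          "final_suggestion"),
                                thresholds = screening_thresholds()) {
  field <- match.arg(field)
  norm <- normalize_text(cohort[[field]])
  ok <- !is.na(norm) & nchar(norm) >= thresholds$duplicate_min_chars
  dup_keys <- unique(norm[ok][duplicated(norm[ok])])
  cohort$respondent_id[ok & norm %in% dup_keys]
}

#' Duplicate email indicator
#'
#' Case-insensitive exact matching on trimmed email addresses; all members
#' of any duplicate group are flagged. Missing or empty emails never flag.
#'
#' @param cohort Cohort tibble.
#' @return Character vector of flagged `respondent_id`s.
#' @export
flag_duplicate_email <- function(cohort) {
  norm <- tolower(trimws(cohort$email))
  ok <- !is.na(norm) & nzchar(norm)
  dup_keys <- unique(norm[ok][duplicated(norm[ok])])
  cohort$respondent_id[ok & norm %in% dup_keys]
}

#' Suspicious submission-timing indicator
#'
#' Two clauses, unioned: (a) sort the cohort by timestamp and partition it
#' into maximal runs in which each successive gap is at most the burst gap;
#' every member of a run of at least the minimum length is flagged; (b) any
#' submission whose Eastern local time falls in the night window (default
#' midnight to 4 AM, closed-open) is flagged.
#'
#' @param cohort Cohort tibble.
#' @param thresholds A [screening_thresholds()].
#' @return Character vector of flagged `respondent_id`s.
#' @export
flag_suspicious_timing <- function(cohort,
                                   thresholds = screening_thresholds()) {
  ts <- cohort$submission_timestamp
  id <- cohort$respondent_id
  present <- !is.na(ts)
  flagged <- character(0)

  ord <- order(ts[present])
  ts_s <- ts[present][ord]
  id_s <- id[present][ord]
  if (length(ts_s) > 1L) {
    gaps <- diff(as.numeric(ts_s))
    run_id <- cumsum(c(0, gaps > thresholds$burst_max_gap_minutes * 60))
    run_len <- ave(run_id, run_id, FUN = length)
    flagged <- id_s[run_len >= thresholds$burst_min_run]
  }

  hrs <- lubridate::hour(lubridate::with_tz(ts[present], EASTERN_TZ)) +
    lubridate::minute(lubridate::with_tz(ts[present], EASTERN_TZ)) / 60
  night <- hrs >= thresholds$night_window[1] & hrs < thresholds$night_window[2]
  union(flagged, id[present][night])
}

# ---- identity heuristics -------------------------------------------------

EMAIL_PUNCT_PATTERNS <- c("\\.\\.", "[!#$%^&*(){}\\[\\]|;:,<>?/=~`]",
                          "([a-z][A-Z]){3,}")
ADDRESS_ANOMALY_PATTERNS <- c("[\"“”]", "\\s{2,}", "[a-z][A-Z]",
                              "\\b[A-Z]{4,}\\b")

has_random_run <- function(local_part, min_len) {
  runs <- stringr::str_extract_all(local_part, "[A-Za-z0-9]+")
  vapply(runs, function(r) {
    r <- r[nchar(r) >= min_len]
    if (!length(r)) return(FALSE)
    mixed <- grepl("[0-9]", r) & grepl("[A-Za-z]", r)
    vowel_free <- grepl("[^aeiou]{5}", tolower(r))
    any(mixed | vowel_free)
  }, logical(1))
}

#' Suspicious email / postal-address indicator
#'
#' Fires on either identity field. Email: the local part contains an
#' alphanumeric run of at least the configured length that scores "random"
#' (mixes digits and letters, or contains a five-character vowel-free
#' window), or the address matches an anomalous-punctuation/capitalization
#' pattern. Postal address: fewer tokens than a complete address, quotation
#' marks, a business keyword, or anomalous internal capitalization or
#' spacing. Missing fields never fire.
#'
#' @param cohort Cohort tibble.
#' @param thresholds A [screening_thresholds()].
#' @param lexicons List containing a `business` keyword vector, see
#'   [default_lexicons()].
#' @param email_patterns,address_patterns Regular-expression sets for the
#'   punctuation/capitalization clauses; override to tighten or loosen.
#' @return Logical vector.
#' @export
flag_suspicious_email_address <- function(cohort,
                                          thresholds = screening_thresholds(),
                                          lexicons = default_lexicons(),
                                          email_patterns = EMAIL_PUNCT_PATTERNS,
                                          address_patterns = ADDRESS_ANOMALY_PATTERNS) {
  email <- cohort$email
  local_part <- sub("@.*$", "", email)
  email_ok <- !is.na(email) & nzchar(trimws(email))
  run_hit <- email_ok & has_random_run(local_part,
                                       thresholds$random_run_min_length)
  punct_hit <- email_ok &
    Reduce(`|`, lapply(email_patterns, function(p) grepl(p, local_part)))

  addr <- cohort$postal_address
  addr_ok <- !is.na(addr) & nzchar(trimws(addr))
  n_tokens <- lengths(strsplit(trimws(addr), "\\s+"))
  incomplete <- addr_ok & n_tokens < thresholds$address_min_tokens
  anomaly <- addr_ok &
    Reduce(`|`, lapply(address_patterns, function(p) grepl(p, addr)))
  addr_tokens <- text_tokens(addr)
  business <- addr_ok & vapply(addr_tokens, function(tk)
    any(tk %in% lexicons$business), logical(1))

  run_hit | punct_hit | incomplete | anomaly | business
}

#' Suspicious name / suffix indicator
#'
#' Fires when first and last name are flipped relative to the bundled name
#' lists (first name known only as a surname while last name is known only
#' as a given name), when one name field is contained in the other (four or
#' more shared characters), when a conventionally male generational suffix
#' accompanies a first name known only as female, or when the suffix
#' contains digits or falls outside the suffix whitelist.
#'
#' @param cohort Cohort tibble.
#' @param name_lists See [default_name_lists()].
#' @return Logical vector.
#' @export
flag_suspicious_name <- function(cohort, name_lists = default_name_lists()) {
  required <- c("given", "surnames", "female_given", "male_given",
                "suffix_whitelist", "male_suffixes")
  if (!all(required %in% names(name_lists)) ||
      !length(name_lists$given) || !length(name_lists$surnames))
    stop("name_lists must provide non-empty given-name and surname lists",
         call. = FALSE)
  fn <- normalize_text(cohort$first_name)
  ln <- normalize_text(cohort$last_name)
  fn[is.na(fn)] <- ""
  ln[is.na(ln)] <- ""

  flipped <- fn %in% name_lists$surnames & !(fn %in% name_lists$given) &
    ln %in% name_lists$given & !(ln %in% name_lists$surnames)

  contained <- (nchar(ln) >= 4 & stringr::str_detect(fn, stringr::fixed(ln))) |
    (nchar(fn) >= 4 & stringr::str_detect(ln, stringr::fixed(fn)))
  contained <- contained & nzchar(fn) & nzchar(ln)

  sfx_raw <- trimws(ifelse(is.na(cohort$name_suffix), "",
                           cohort$name_suffix))
  has_sfx <- nzchar(sfx_raw)
  sfx_digits <- has_sfx & grepl("[0-9]", sfx_raw)
  sfx <- gsub("[[:punct:]]", "", tolower(sfx_raw))
  sfx_unknown <- has_sfx & !(sfx %in% name_lists$suffix_whitelist)
  sfx_gender <- has_sfx & sfx %in% name_lists$male_suffixes &
    fn %in% name_lists$female_given & !(fn %in% name_lists$male_given)

  flipped | contained | sfx_digits | sfx_unknown | sfx_gender
}

# ---- honeypot (optional thirteenth indicator) ---------------------------

#' Honeypot indicator (optional)
#'
#' A non-empty value in the hidden honeypot field, which human respondents
#' cannot see, suggests automated completion. Not part of the twelve-code
#' indicator set and disabled by default in [profile_cohort()].
#'
#' @param cohort Cohort tibble.
#' @return Logical vector.
#' @export
flag_honeypot <- function(cohort) {
  !is.na(cohort$honeypot_value) & nzchar(trimws(cohort$honeypot_value))
}

# ---- profiling -----------------------------------------------------------

#' Run all indicator detectors over a cohort
#'
#' Applies the twelve detectors and collects, per respondent, the set of
#' indicator codes that fired and its size. A respondent is counted under
#' every indicator its response triggers.
#'
#' @param cohort Cohort tibble.
#' @param config A [screening_config()].
#' @param include_honeypot Logical; add the optional `HONEYPOT` code for a
#'   non-empty hidden-item value (default `FALSE`).
#' @return Tibble with `respondent_id`, one logical column per indicator
#'   code, `count` (number of indicators fired) and list-column `fired`.
#' @export
profile_cohort <- function(cohort, config = screening_config(),
                           include_honeypot = FALSE) {
  th <- config$thresholds
  m <- matrix(FALSE, nrow(cohort), length(INDICATOR_CODES),
              dimnames = list(NULL, INDICATOR_CODES))
  m[, "AGE_DISCORD"] <- flag_age_discordance(cohort, th)
  m[, "RARE_CANCER_YOUNG"] <- flag_rare_cancer_young(cohort,
                                                     config$rare_catalog, th)
  m[, "SOURCE_INCONGRUENT"] <- flag_source_incongruence(cohort,
                                                        config$calendar)
  m[, "OFFTOPIC_TEXT"] <- flag_offtopic_text(cohort, config$lexicons)
  m[, "DUP_TELEHEALTH"] <- cohort$respondent_id %in%
    flag_duplicate_text(cohort, "telehealth_comment", th)
  m[, "DUP_SUGGESTION"] <- cohort$respondent_id %in%
    flag_duplicate_text(cohort, "final_suggestion", th)
  m[, "DUP_EMAIL"] <- cohort$respondent_id %in% flag_duplicate_email(cohort)
  tl <- flag_timeline_inconsistency(cohort)
  m[, "TIMELINE_DX_LT2_TX_2TO5"] <- tl$TIMELINE_DX_LT2_TX_2TO5
  m[, "TIMELINE_DX_LE5_TX_GT5"] <- tl$TIMELINE_DX_LE5_TX_GT5
  m[, "SUSPICIOUS_TIMING"] <- cohort$respondent_id %in%
    flag_suspicious_timing(cohort, th)
  m[, "SUSPICIOUS_EMAIL_ADDRESS"] <- flag_suspicious_email_address(
    cohort, th, config$lexicons)
  m[, "SUSPICIOUS_NAME"] <- flag_suspicious_name(cohort, config$name_lists)
  if (include_honeypot) {
    m <- cbind(m, HONEYPOT = flag_honeypot(cohort))
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out$count <- as.integer(rowSums(m))
  out$fired <- apply(m, 1L, function(r) colnames(m)[r], simplify = FALSE)
  tibble::tibble(respondent_id = cohort$respondent_id) |>
    dplyr::bind_cols(out)
}
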