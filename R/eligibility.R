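# Stage-1 eligibility and contradiction screen. Rules are applied in a
# fixed sequence and each record is attributed to the FIRST stage it fails,
# so per-stage removal counts are disjoint and sum to the total removed:
#   1. core ineligibility (non-US residence, stage 0, no cancer diagnosis)
#   2. only nonmelanoma skin cancer
#   3. missing >= 35% of inventory questions
#   4. mutually contradictory gender identities
#   5. sex assigned at birth incompatible with the anatomic cancer site

US_SYNONYMS <- c("united states", "united states of america", "usa", "us",
                 "u s", "u s a", "america", "us of a")

STAGE1_STAGES <- c("ineligible_core", "nonmelanoma_only",
                   "excess_missingness", "discordant_gender",
                   "discordant_sex_site")

selected_levels <- function(cohort, group) {
  cols <- checkbox_cols(group)
  m <- as.matrix(cohort[, cols]) == 1L
  m[is.na(m)] <- FALSE
  colnames(m) <- CHECKBOX_GROUPS[[group]]
  m
}

#' Core ineligibility reasons
#'
#' Flags the four cohort-definition failures: residence outside the United
#' States, stage 0 cancer, no cancer diagnosis (no cancer type selected and
#' stage reported as "none"), and a cancer history consisting only of
#' nonmelanoma skin cancer. A missing country or stage never fires a reason
#' on its own; incomplete records fall to the missingness rule instead.
#'
#' @param cohort Cohort tibble.
#' @return Tibble with logical columns `non_us_resident`, `stage_0`,
#'   `no_cancer_diagnosis`, `nonmelanoma_only`, one row per respondent.
#' @export
check_ineligible <- function(cohort) {
  country <- normalize_text(cohort$country_of_residence)
  non_us <- !is.na(country) & nzchar(country) & !(country %in% US_SYNONYMS)
  stage0 <- !is.na(cohort$cancer_stage) & cohort$cancer_stage == "0"
  types <- selected_levels(cohort, "cancer_type")
  n_types <- rowSums(types)
  no_dx <- n_types == 0L & !is.na(cohort$cancer_stage) &
    cohort$cancer_stage == "none"
  nonmel <- n_types == 1L & types[, "nonmelanoma_skin"]
  tibble::tibble(non_us_resident = non_us, stage_0 = stage0,
                 no_cancer_diagnosis = no_dx, nonmelanoma_only = nonmel)
}

#' Contradictory gender identities
#'
#' `TRUE` where the multi-select gender-identity answer contains a
#' configured mutually exclusive pair, e.g. both cisgender male and
#' cisgender female.
#'
#' @param cohort Cohort tibble.
#' @param pairs List of exclusive pairs, see [gender_exclusive_pairs()].
#' @return Logical vector.
#' @export
check_gender_contradiction <- function(cohort,
                                       pairs = gender_exclusive_pairs()) {
  g <- selected_levels(cohort, "gender")
  out <- rep(FALSE, nrow(cohort))
  for (p in pairs) out <- out | (g[, p[1]] & g[, p[2]])
  out
}

#' Sex assigned at birth incompatible with cancer site
#'
#' `TRUE` where any reported cancer type is anatomically impossible for the
#' reported sex assigned at birth under the configured incompatibility map.
#'
#' @param cohort Cohort tibble.
#' @param map Incompatibility map, see [sex_site_map()].
#' @return Logical vector.
#' @export
check_sex_site_contradiction <- function(cohort, map = sex_site_map()) {
  types <- selected_levels(cohort, "cancer_type")
  sex <- cohort$sex_assigned_at_birth
  out <- rep(FALSE, nrow(cohort))
  for (s in names(map)) {
    bad <- intersect(map[[s]], colnames(types))
    if (!length(bad)) next
    hit <- rowSums(types[, bad, drop = FALSE]) > 0L
    out <- out | (!is.na(sex) & sex == s & hit)
  }
  out
}

#' Stage-1 eligibility screen over a cohort
#'
#' Applies the eligibility cascade in its fixed order and attributes each
#' failing record to the first stage it fails, producing disjoint per-stage
#' removal counts that sum to the total removed. The per-record verdict also
#' carries the full set of reasons that fired, independent of attribution.
#'
#' @param cohort Cohort tibble.
#' @param thresholds A [screening_thresholds()].
#' @param incompatibility_map A [sex_site_map()].
#' @param exclusive_pairs A [gender_exclusive_pairs()] list.
#' @param schema A [survey_schema()].
#' @return List of class `eligibility_screen` with elements `verdicts`
#'   (tibble: `respondent_id`, `eligible`, `removed_at` — `NA` when
#'   eligible — and list-column `reasons`) and `counts` (named integer
#'   vector of per-stage removals).
#' @export
screen_cohort <- function(cohort, thresholds = screening_thresholds(),
                          incompatibility_map = sex_site_map(),
                          exclusive_pairs = gender_exclusive_pairs(),
                          schema = survey_schema()) {
  core <- check_ineligible(cohort)
  miss <- missingness_fraction(cohort, schema)
  gender <- check_gender_contradiction(cohort, exclusive_pairs)
  site <- check_sex_site_contradiction(cohort, incompatibility_map)

  core_any <- core$non_us_resident | core$stage_0 | core$no_cancer_diagnosis
  excess <- miss >= thresholds$missingness_cutoff
  removed_at <- dplyr::case_when(
    core_any ~ "ineligible_core",
    core$nonmelanoma_only ~ "nonmelanoma_only",
    excess ~ "excess_missingness",
    gender ~ "discordant_gender",
    site ~ "discordant_sex_site",
    .default = NA_character_
  )
  reason_m <- cbind(as.matrix(core), excess_missingness = excess,
                    discordant_gender = gender, discordant_sex_site = site)
  reasons <- apply(reason_m, 1L, function(r) colnames(reason_m)[r],
                   simplify = FALSE)
  verdicts <- tibble::tibble(
    respondent_id = cohort$respondent_id,
    eligible = is.na(removed_at),
    removed_at = removed_at,
    reasons = reasons
  )
  counts <- vapply(STAGE1_STAGES,
                   function(s) sum(removed_at == s, na.rm = TRUE), integer(1))
  structure(list(verdicts = verdicts, counts = counts),
            class = "eligibility_screen")
}

#' @export
print.eligibility_screen <- function(x, ...) {
  cat("<eligibility_screen> ", nrow(x$verdicts), " responses, ",
      sum(!x$verdicts$eligible), " removed\n", sep = "")
  for (s in names(x$counts)) cat(sprintf("  %-22s %d\n", s, x$counts[[s]]))
  invisible(x)
}
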