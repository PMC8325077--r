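# Full screening cascade: stage-1 eligibility screen, indicator profiling
# of the stage-1 survivors only, elimination at >= 2 indicators, flow-chart
# accounting, and result export.

#' Screening configuration bundle
#'
#' Collects every configurable piece the pipeline needs: thresholds,
#' dissemination calendar, rare-cancer catalog, sex/site incompatibility
#' map, exclusive gender pairs, text lexicons, name lists and the schema.
#'
#' @param thresholds A [screening_thresholds()].
#' @param calendar A [dissemination_calendar()].
#' @param rare_catalog A [rare_cancer_catalog()].
#' @param incompatibility_map A [sex_site_map()].
#' @param exclusive_pairs A [gender_exclusive_pairs()] list.
#' @param lexicons See [default_lexicons()].
#' @param name_lists See [default_name_lists()].
#' @param schema A [survey_schema()].
#' @return A `screening_config` list.
#' @export
screening_config <- function(thresholds = screening_thresholds(),
                             calendar = dissemination_calendar(),
                             rare_catalog = rare_cancer_catalog(),
                             incompatibility_map = sex_site_map(),
                             exclusive_pairs = gender_exclusive_pairs(),
                             lexicons = default_lexicons(),
                             name_lists = default_name_lists(),
                             schema = survey_schema()) {
  cfg <- list(thresholds = thresholds, calendar = calendar,
              rare_catalog = rare_catalog,
              incompatibility_map = incompatibility_map,
              exclusive_pairs = exclusive_pairs, lexicons = lexicons,
              name_lists = name_lists, schema = schema)
  validate_screening_config(cfg)
  structure(cfg, class = "screening_config")
}

validate_screening_config <- function(cfg) {
  required <- c("thresholds", "calendar", "rare_catalog",
                "incompatibility_map", "exclusive_pairs", "lexicons",
                "name_lists", "schema")
  missing <- required[vapply(required, function(p) is.null(cfg[[p]]),
                             logical(1))]
  if (length(missing))
    stop("screening configuration is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Run the full screening pipeline
#'
#' Applies the stage-1 eligibility cascade, profiles the twelve suspicious
#' indicators over the stage-1 survivors only, and eliminates every
#' survivor with at least `indicator_elimination_count` (default two)
#' indicators. Produces one decision per respondent and flow-chart counts
#' that conserve the cohort size.
#'
#' @param cohort Cohort tibble.
#' @param config A [screening_config()].
#' @return List of class `screening_result`: `decisions` (tibble with
#'   `respondent_id`, `outcome`, `stage1_reasons`, `indicators`,
#'   `indicator_count`), `flow_counts` (class `flow_counts`), `profiles`
#'   (indicator profiles of stage-1 survivors) and `config`.
#' @export
run_pipeline <- function(cohort, config = screening_config()) {
  validate_screening_config(config)
  screen <- screen_cohort(cohort, config$thresholds,
                          config$incompatibility_map,
                          config$exclusive_pairs, config$schema)
  eligible <- screen$verdicts$eligible
  survivors <- cohort[eligible, , drop = FALSE]
  profiles <- profile_cohort(survivors, config)
  k <- config$thresholds$indicator_elimination_count
  removed_ind <- profiles$respondent_id[profiles$count >= k]

  outcome <- ifelse(!eligible, screen$verdicts$removed_at,
                    ifelse(cohort$respondent_id %in% removed_ind,
                           "suspicious_indicators", "retained"))
  prof_idx <- match(cohort$respondent_id, profiles$respondent_id)
  fired <- rep(list(character(0)), nrow(cohort))
  fired[!is.na(prof_idx)] <- profiles$fired[prof_idx[!is.na(prof_idx)]]
  decisions <- tibble::tibble(
    respondent_id = cohort$respondent_id,
    outcome = outcome,
    stage1_reasons = screen$verdicts$reasons,
    indicators = fired,
    indicator_count = ifelse(is.na(prof_idx), NA_integer_,
                             profiles$count[prof_idx])
  )
  fc <- structure(c(list(total = nrow(cohort)),
                    as.list(setNames(as.integer(screen$counts),
                                     paste0("removed_", names(screen$counts)))),
                    list(removed_indicators = length(removed_ind),
                         retained = sum(outcome == "retained"))),
                  class = "flow_counts")
  structure(list(decisions = decisions, flow_counts = fc,
                 profiles = profiles, config = config),
            class = "screening_result")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("<flow_counts>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.screening_result <- function(x, ...) {
  fc <- x$flow_counts
  cat("<screening_result> ", fc$total, " responses: ",
      fc$total - fc$retained - fc$removed_indicators,
      " removed at stage 1, ", fc$removed_indicators,
      " removed as suspicious, ", fc$retained, " retained\n", sep = "")
  invisible(x)
}

#' Indicator frequency summary among eliminated responses
#'
#' Tabulates, over the responses eliminated by the indicator rule, how often
#' each of the twelve indicators fired. Counts overlap (a response is
#' counted under every indicator it triggered) so they need not sum to the
#' number eliminated. The percentage denominator is, by default, all
#' excluded responses including the stage-1 removals; set
#' `denominator = "suspicious_only"` to use only indicator-based removals.
#'
#' @param result A `screening_result` from [run_pipeline()].
#' @param denominator `"all_excluded"` (default) or `"suspicious_only"`.
#' @return Tibble with `code`, `label`, `count`, `percentage` (numeric,
#'   rounded half-up to one decimal) and `display` (formatted, trailing
#'   ".0" dropped).
#' @export
indicator_summary <- function(result,
                              denominator = c("all_excluded",
                                              "suspicious_only")) {
  denominator <- match.arg(denominator)
  out_cnt <- table(factor(result$decisions$outcome,
                          levels = c(STAGE1_STAGES, "suspicious_indicators",
                                     "retained")))
  n_suspicious <- out_cnt[["suspicious_indicators"]]
  n_excluded <- result$flow_counts$total - result$flow_counts$retained
  denom <- if (denominator == "all_excluded") n_excluded else n_suspicious
  if (denom == 0L) stop("no excluded responses: denominator is zero",
                        call. = FALSE)
  removed <- result$decisions$respondent_id[
    result$decisions$outcome == "suspicious_indicators"]
  prof <- result$profiles[result$profiles$respondent_id %in% removed, ]
  counts <- vapply(INDICATOR_CODES, function(cd) sum(prof[[cd]]), integer(1))
  pct <- 100 * counts / denom
  tibble::tibble(code = INDICATOR_CODES,
                 label = unname(INDICATOR_LABELS[INDICATOR_CODES]),
                 count = unname(counts),
                 percentage = round_half_up(unname(pct), 1),
                 display = format_percent(unname(pct)))
}

#' Export screening results
#'
#' Writes the retained and excluded partitions of the cohort as CSV, the
#' flow-chart counts as JSON, and a machine-readable audit log listing each
#' respondent's outcome, stage-1 reasons and fired indicators.
#'
#' @param result A `screening_result` from [run_pipeline()].
#' @param cohort The cohort the result was computed from.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the four file paths.
#' @export
export_results <- function(result, cohort, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  d <- result$decisions
  if (!identical(sort(d$respondent_id), sort(cohort$respondent_id)))
    stop("decisions and cohort do not cover the same respondents",
         call. = FALSE)
  retained_ids <- d$respondent_id[d$outcome == "retained"]
  keep <- cohort$respondent_id %in% retained_ids
  paths <- list(retained = file.path(outdir, "retained.csv"),
                excluded = file.path(outdir, "excluded.csv"),
                flowchart = file.path(outdir, "flowchart.json"),
                audit = file.path(outdir, "audit.csv"))
  write_responses(cohort[keep, , drop = FALSE], paths$retained,
                  result$config$schema)
  write_responses(cohort[!keep, , drop = FALSE], paths$excluded,
                  result$config$schema)
  jsonlite::write_json(unclass(result$flow_counts), paths$flowchart,
                       auto_unbox = TRUE, pretty = TRUE)
  audit <- tibble::tibble(
    respondent_id = d$respondent_id,
    outcome = d$outcome,
    stage1_reasons = vapply(d$stage1_reasons, paste, character(1),
                            collapse = ";"),
    indicators = vapply(d$indicators, paste, character(1), collapse = ";"),
    indicator_count = d$indicator_count
  )
  readr::write_csv(audit, paths$audit, na = "", progress = FALSE)
  invisible(paths)
}
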