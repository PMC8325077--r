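# Retained-versus-excluded comparison statistics: contingency tables per
# characteristic, chi-square / Fisher exact tests, Welch t for numeric
# variables, and a formatted comparison table.
#
# Group definition: "retained" is the final analytic sample; "excluded" is
# the suspicious-indicator eliminations only (the stage-1 ineligible are
# not a comparison group, since they fall outside the cohort definition).
#
# Percentage conventions follow the reporting style of screening studies:
# single-select and binary variables use the per-variable answered count as
# the denominator (missing responses drop out), while multi-select
# (checkbox) levels use the full group size, because an unchecked box is
# indistinguishable from "not selected".

comparison_groups <- function(decisions) {
  list(retained = decisions$respondent_id[decisions$outcome == "retained"],
       excluded = decisions$respondent_id[
         decisions$outcome == "suspicious_indicators"])
}

#' Build contingency tables for a variable
#'
#' For a single-select variable, one levels-by-groups table (missing
#' responses excluded). For a multi-select (checkbox) variable, one 2x2
#' table per level with rows retained/excluded and columns
#' selected/not-selected, using the full group sizes. For a logical
#' variable, a single 2x2 of the same shape over answered responses.
#'
#' @param cohort Cohort tibble.
#' @param decisions Decision tibble from [run_pipeline()].
#' @param variable Column name (single-select or logical) or checkbox group
#'   name (multi-select).
#' @param mode `"single_select"` or `"per_level_binary"`; defaults to
#'   `"per_level_binary"` for checkbox groups and logical columns.
#' @return A single matrix (single-select) or a named list of 2x2 matrices
#'   (one per level).
#' @export
build_contingency <- function(cohort, decisions, variable,
                              mode = c("auto", "single_select",
                                       "per_level_binary")) {
  mode <- match.arg(mode)
  grp <- comparison_groups(decisions)
  in_ret <- cohort$respondent_id %in% grp$retained
  in_exc <- cohort$respondent_id %in% grp$excluded
  if (variable %in% names(CHECKBOX_GROUPS)) {
    if (mode == "single_select")
      stop("checkbox group '", variable,
           "' requires per-level binary tables", call. = FALSE)
    sel <- selected_levels(cohort, variable)
    out <- lapply(colnames(sel), function(lv) {
      matrix(c(sum(sel[in_ret, lv]), sum(in_ret) - sum(sel[in_ret, lv]),
               sum(sel[in_exc, lv]), sum(in_exc) - sum(sel[in_exc, lv])),
             nrow = 2, byrow = TRUE,
             dimnames = list(c("retained", "excluded"),
                             c("selected", "not_selected")))
    })
    return(setNames(out, colnames(sel)))
  }
  if (!variable %in% names(cohort))
    stop("unknown variable: ", variable, call. = FALSE)
  x <- cohort[[variable]]
  if (is.logical(x)) {
    ok <- !is.na(x)
    m <- matrix(c(sum(x[in_ret & ok]), sum(in_ret & ok) - sum(x[in_ret & ok]),
                  sum(x[in_exc & ok]), sum(in_exc & ok) - sum(x[in_exc & ok])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("retained", "excluded"),
                                c("selected", "not_selected")))
    return(m)
  }
  levels <- SINGLE_LEVELS[[variable]] %||% sort(unique(x[!is.na(x)]))
  present <- levels[levels %in% x]
  m <- matrix(unlist(lapply(list(in_ret, in_exc), function(g)
    vapply(present, function(lv) sum(!is.na(x) & x == lv & g),
           integer(1)))), nrow = length(present),
    dimnames = list(present, c("retained", "excluded")))
  m
}

#' Pearson chi-square test of association
#'
#' Pearson statistic without continuity correction by default (Yates
#' optionally for 2x2), degrees of freedom (r-1)(c-1), upper-tail P value.
#'
#' @param table Integer matrix with at least two rows and columns.
#' @param yates Logical; apply the continuity correction (2x2 only).
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  tibble::tibble(method = "chi_square",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided P value by summing the hypergeometric probabilities, with
#' margins fixed, of every table as or more extreme (probability ordering)
#' than the observed one.
#'
#' @param table 2x2 integer matrix.
#' @return Tibble with `method`, `statistic` (conditional odds-ratio
#'   estimate), `df` (`NA`), `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("fisher_exact_2x2 requires a 2x2 table", call. = FALSE)
  res <- stats::fisher.test(m)
  tibble::tibble(method = "fisher_exact",
                 statistic = unname(res$estimate),
                 df = NA_real_,
                 p_value = res$p.value)
}

#' Welch two-sample t test
#'
#' Compares group means without assuming equal variances, with
#' Satterthwaite degrees of freedom and a two-sided P value.
#'
#' @param sample_a,sample_b Numeric vectors; missing values dropped.
#' @param pooled Logical; use the pooled-variance (Student) form instead.
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b, pooled = FALSE) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two non-missing values", call. = FALSE)
  res <- stats::t.test(a, b, var.equal = pooled)
  tibble::tibble(method = if (pooled) "pooled_t" else "welch_t",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

# Chi-square with automatic Fisher fallback: Fisher when the table is 2x2
# and any expected count is below 5; larger sparse tables keep chi-square
# with a warning.
select_association_test <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  small <- any(expected < 5)
  if (small && all(dim(m) == c(2L, 2L))) return(fisher_exact_2x2(m))
  if (small)
    warning("expected count below 5 in an r x c table; ",
            "chi-square approximation may be poor", call. = FALSE)
  chi_square_test(m)
}

DEFAULT_COMPARISON_VARIABLES <- tibble::tribble(
  ~variable, ~mode, ~label,
  "reported_age", "numeric", "Current age (years)",
  "gender", "multi", "Gender",
  "sexual_orientation", "single", "Sexual orientation",
  "race", "multi", "Race/ethnicity",
  "marital_status", "single", "Partnership status",
  "household_size", "numeric", "Number of individuals in household",
  "education", "single", "Education",
  "income_bracket", "single", "Annual household income",
  "age_at_diagnosis", "numeric", "Age at cancer diagnosis (years)",
  "cancer_stage", "single", "Cancer stage",
  "cancer_type", "multi", "Cancer type",
  "time_since_treatment", "single", "Time since cancer treatment (years)",
  "care_status", "multi", "Cancer care status",
  "tribe_or_territory", "binary", "Part of a tribe or territory",
  "employment", "multi", "Employment status",
  "insurance", "multi", "Insurance type",
  "self_reported_health", "single", "Self-reported health"
)

group_pct <- function(n, denom) {
  if (isTRUE(denom > 0)) 100 * n / denom else rep(NA_real_, length(n))
}

#' Retained-versus-excluded comparison table
#'
#' Builds the demographic comparison between the retained sample and the
#' sample excluded for suspicious indicators: per-level counts and
#' percentages for categorical variables, mean (SD) for numeric variables,
#' and a P value per variable (single-select) or per level (multi-select),
#' using chi-square with automatic Fisher fallback for sparse 2x2 tables
#' and Welch t for means. P values below 0.001 are formatted `"<.001"`.
#'
#' @param cohort Cohort tibble.
#' @param decisions Decision tibble from [run_pipeline()].
#' @param variables Tibble with columns `variable`, `mode` (`"numeric"`,
#'   `"single"`, `"multi"`, `"binary"`) and `label`; defaults to the
#'   standard demographic set.
#' @param pooled Logical; pooled-variance t instead of Welch.
#' @return Tibble with one row per variable level: `variable`, `label`,
#'   `level`, `retained`, `excluded` (formatted "n (pct)" or "mean (SD)"),
#'   `p_value` (numeric) and `p_display`.
#' @export
comparison_table <- function(cohort, decisions,
                             variables = DEFAULT_COMPARISON_VARIABLES,
                             pooled = FALSE) {
  grp <- comparison_groups(decisions)
  in_ret <- cohort$respondent_id %in% grp$retained
  in_exc <- cohort$respondent_id %in% grp$excluded
  n_ret <- sum(in_ret); n_exc <- sum(in_exc)

  rows <- purrr::pmap(variables, function(variable, mode, label) {
    if (mode == "numeric") {
      x <- cohort[[variable]]
      test <- welch_t_test(x[in_ret], x[in_exc], pooled = pooled)
      fmt <- function(v) sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE),
                                 stats::sd(v, na.rm = TRUE))
      return(tibble::tibble(variable = variable, label = label,
                            level = "mean_sd",
                            retained = fmt(x[in_ret]),
                            excluded = fmt(x[in_exc]),
                            p_value = test$p_value,
                            p_display = format_p_value(test$p_value)))
    }
    if (mode %in% c("multi", "binary")) {
      tables <- build_contingency(cohort, decisions, variable)
      if (mode == "binary") tables <- list(selected = tables)
      purrr::imap(tables, function(m, lv) {
        test <- select_association_test(m)
        # binary single-select percentages use the answered denominator;
        # checkbox levels use the full group size (held in the table rows)
        denom_r <- if (mode == "binary") sum(m["retained", ]) else n_ret
        denom_e <- if (mode == "binary") sum(m["excluded", ]) else n_exc
        tibble::tibble(variable = variable, label = label, level = lv,
                       retained = sprintf("%d (%s)", m["retained", 1],
                                          format_percent(group_pct(
                                            m["retained", 1], denom_r))),
                       excluded = sprintf("%d (%s)", m["excluded", 1],
                                          format_percent(group_pct(
                                            m["excluded", 1], denom_e))),
                       p_value = test$p_value,
                       p_display = format_p_value(test$p_value))
      }) |> dplyr::bind_rows()
    } else {
      m <- build_contingency(cohort, decisions, variable,
                             mode = "single_select")
      test <- select_association_test(m)
      denom_r <- sum(m[, "retained"]); denom_e <- sum(m[, "excluded"])
      tibble::tibble(variable = variable, label = label,
                     level = rownames(m),
                     retained = sprintf("%d (%s)", m[, "retained"],
                                        format_percent(group_pct(
                                          m[, "retained"], denom_r))),
                     excluded = sprintf("%d (%s)", m[, "excluded"],
                                        format_percent(group_pct(
                                          m[, "excluded"], denom_e))),
                     p_value = test$p_value,
                     p_display = format_p_value(test$p_value))
    }
  })
  dplyr::bind_rows(rows)
}

#' Render a comparison table as Markdown
#'
#' @param table Output of [comparison_table()].
#' @param retained_n,excluded_n Group sizes for the header.
#' @return Character vector of Markdown lines.
#' @export
comparison_markdown <- function(table, retained_n = NA, excluded_n = NA) {
  hdr <- sprintf("| Characteristic | Retained (n=%s) | Excluded (n=%s) | P value |",
                 retained_n, excluded_n)
  c(hdr, "|---|---|---|---|",
    sprintf("| %s: %s | %s | %s | %s |", table$label, table$level,
            table$retained, table$excluded, table$p_display))
}
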