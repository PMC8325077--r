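test_that("chi-square matches the textbook formula and its invariances", {
  m <- matrix(c(93, 388, 60, 28, 152, 884, 37, 8), ncol = 2,
              dimnames = list(c("single", "married", "divorced", "widowed"),
                              c("retained", "excluded")))
  res <- chi_square_test(m)
  expect_equal(res$statistic, chisq_statistic_oracle(m), tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_lt(res$p_value, 0.001)
  # invariant under row and column permutation
  perm <- chi_square_test(m[c(3, 1, 4, 2), c(2, 1)])
  expect_equal(perm$statistic, res$statistic, tolerance = 1e-10)

  flat <- chi_square_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("degenerate and undersized tables are rejected", {
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_test(matrix(1:3, ncol = 1)), "2x2")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
})

test_that("fisher exact equals exhaustive enumeration (property)", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  withr::with_seed(7, {
    for (i in 1:60) {
      m <- random_2x2(30)
      expect_equal(fisher_exact_2x2(m)$p_value, fisher_enum_oracle(m),
                   tolerance = 1e-9)
    }
  })
})

test_that("fisher and chi-square agree on large balanced tables", {
  m <- matrix(c(120, 80, 100, 95), 2)
  pf <- fisher_exact_2x2(m)$p_value
  pc <- chi_square_test(m)$p_value
  expect_lt(abs(pf - pc) / pc, 0.10)
})

test_that("welch t matches the hand formula and its trivial cases", {
  same <- c(1, 2, 3, 4)
  res <- welch_t_test(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  a <- c(5.1, 6.3, 4.8, 7.0, 5.5)
  b <- c(3.2, 4.1, 2.9, 3.8)
  res <- welch_t_test(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(res$df, oracle$df, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)

  expect_error(welch_t_test(1, c(2, 3)), "two non-missing")
})

test_that("group mean separation at the observed scale is significant", {
  withr::with_seed(5, {
    scale_to <- function(n, m, s) {
      z <- rnorm(n)
      m + s * (z - mean(z)) / stats::sd(z)
    }
    a <- scale_to(569, 55.9, 13.1)
    b <- scale_to(1081, 41.4, 8.2)
    expect_lt(welch_t_test(a, b)$p_value, 0.001)
  })
})

test_that("contingency construction matches the decision partition", {
  sim <- generate_cohort(generator_config(
    seed = 13, n_legit = 25, n_fraud = 20, min_indicators_per_fraud = 2))
  res <- run_pipeline(sim$cohort)
  tabs <- build_contingency(sim$cohort, res$decisions, "care_status")
  hosp <- tabs$hospice
  expect_equal(dim(hosp), c(2L, 2L))
  expect_equal(sum(hosp["retained", ]), res$flow_counts$retained)
  expect_equal(sum(hosp["excluded", ]), res$flow_counts$removed_indicators)

  single <- build_contingency(sim$cohort, res$decisions, "education",
                              mode = "single_select")
  expect_equal(ncol(single), 2L)
  expect_lte(sum(single[, "retained"]), res$flow_counts$retained)
  expect_error(build_contingency(sim$cohort, res$decisions, "not_a_column"),
               "unknown")
})

test_that("comparison table reports per-level rows with sensible percentages", {
  sim <- generate_cohort(generator_config(
    seed = 19, n_legit = 40, n_fraud = 35, min_indicators_per_fraud = 2))
  res <- run_pipeline(sim$cohort)
  # at this cohort size some r x c tables are sparse, which warns by design
  tab <- suppressWarnings(comparison_table(sim$cohort, res$decisions))
  expect_true(all(c("reported_age", "gender", "marital_status",
                    "tribe_or_territory") %in% tab$variable))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  # single-select percentages sum to 100 within rounding
  edu <- tab[tab$variable == "education", ]
  pct <- as.numeric(sub(".*\\((.*)\\)", "\\1", edu$retained))
  expect_equal(sum(pct), 100, tolerance = 0.5)
  # multi-select rows carry one P value per level
  expect_gt(nrow(tab[tab$variable == "cancer_type", ]), 1L)
})

test_that("sparse tables fall back to fisher only when 2x2", {
  cohort <- cohort_template(9)
  cohort$education <- rep(c("some_college", "four_year_degree",
                            "graduate_school"), 3)
  cohort$tribe_or_territory <- rep(c(TRUE, FALSE, FALSE), 3)
  decisions <- tibble::tibble(
    respondent_id = cohort$respondent_id,
    outcome = rep(c("retained", "suspicious_indicators", "retained"), 3))
  vars <- tibble::tibble(variable = c("education", "tribe_or_territory"),
                         mode = c("single", "binary"),
                         label = c("Education", "Tribe"))
  # 3x2 with small expected counts: chi-square kept, with a warning
  expect_warning(tab <- comparison_table(cohort, decisions, vars),
                 "approximation")
  expect_equal(unique(tab$variable[grepl("edu", tab$variable)]), "education")
  # sparse 2x2: silent fisher fallback, exact P
  tribe_p <- tab$p_value[tab$variable == "tribe_or_territory"]
  m <- matrix(c(3, 3, 0, 3), nrow = 2, byrow = TRUE)
  expect_equal(unique(tribe_p), fisher_enum_oracle(m), tolerance = 1e-9)
})

test_that("P values are formatted in report style", {
  expect_equal(format_p_value(c(0.0004, 0.045, 0.0597, 0.5, 0.92, 1)),
               c("<.001", ".045", ".06", ".5", ".92", ">.99"))
})
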