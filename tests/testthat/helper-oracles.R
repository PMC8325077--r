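# Independent oracles used to check the package's statistics and detectors.
# They deliberately share no code with the implementation.

# Pearson chi-square statistic from the textbook formula.
chisq_statistic_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Two-sided Fisher exact P by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing hypergeometric probabilities no larger than
# the observed table's (probability ordering).
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Welch statistic, Satterthwaite df and two-sided P by hand.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Brute-force pairwise duplicate-text detection.
duplicate_oracle <- function(ids, texts, min_chars = 15) {
  norm <- trimws(gsub("\\s+", " ", gsub("[[:punct:]]", " ", tolower(texts))))
  keep <- !is.na(norm) & nchar(norm) >= min_chars
  flagged <- character(0)
  for (i in seq_along(ids)) {
    if (!keep[i]) next
    for (j in seq_along(ids)) {
      if (i != j && keep[j] && norm[i] == norm[j]) {
        flagged <- c(flagged, ids[i])
        break
      }
    }
  }
  flagged
}

# A random 2x2 table with total at most n_max and no zero margin.
random_2x2 <- function(n_max = 30) {
  repeat {
    n <- sample(4:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    m <- matrix(cells, 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
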