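#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif rbinom setNames
#' @importFrom utils head
NULL

# Canonical timezone for all timestamp comparisons (night window, source
# dates). Survey dissemination and the night rule are defined in US Eastern.
EASTERN_TZ <- "America/New_York"

#' Normalize free text for duplicate and lexicon matching
#'
#' Lower-cases, strips punctuation, collapses internal whitespace and trims.
#' This is the normalization applied before duplicate-text grouping and
#' off-topic lexicon matching, so that trivial formatting differences do not
#' hide duplicates.
#'
#' @param x Character vector.
#' @return Character vector of the same length; `NA` stays `NA`.
#' @export
#' @examples
#' normalize_text(c("  Great, CARE!!", NA))
normalize_text <- function(x) {
  out <- tolower(x)
  out <- gsub("[[:punct:]]", " ", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

# Round half away from zero (commercial rounding), as printed summary tables
# round 58.24 -> 58.2 and 70.03 -> 70.0 rather than using banker's rounding.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a percentage the way screening summary tables print it
#'
#' Rounds half-up to one decimal and drops a trailing ".0", so 58.24 becomes
#' `"58.2"` and 70.03 becomes `"70"`.
#'
#' @param x Numeric vector of percentages (on the 0-100 scale).
#' @return Character vector.
#' @export
format_percent <- function(x) {
  r <- round_half_up(x, 1)
  ifelse(is.na(r), NA_character_,
         ifelse(r == floor(r), sprintf("%d", as.integer(r)), sprintf("%.1f", r)))
}

#' Format a P value in report style
#'
#' Two significant digits with the leading zero stripped; values below 0.001
#' print as `"<.001"` and values above 0.99 as `">.99"`.
#'
#' @param p Numeric vector of P values in \[0, 1\].
#' @return Character vector.
#' @export
#' @examples
#' format_p_value(c(0.0004, 0.045, 0.0597, 0.53, 1))
format_p_value <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<.001")
    if (pi > 0.99) return(">.99")
    s <- format(signif(pi, 2), scientific = FALSE)
    sub("^0", "", s)
  }, character(1))
}

# Tokenize normalized text into words.
text_tokens <- function(x) {
  strsplit(normalize_text(x), " ", fixed = TRUE)
}

is_blank <- function(x) is.na(x) | (is.character(x) & !is.na(x) & trimws(x) == "")
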