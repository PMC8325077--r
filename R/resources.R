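# Bundled lexical resources: off-topic / on-topic term lists for the
# open-text indicator, business keywords for the address heuristic, and
# frequency-ranked given-name and surname lists for the name heuristics.
# Every list can be replaced by the user through screening_config().

read_term_file <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

pkg_resource <- function(file) {
  path <- system.file("extdata", file, package = "surveyscreen")
  if (path == "") stop("bundled resource not found: ", file, call. = FALSE)
  path
}

#' Bundled text lexicons for the open-text and address heuristics
#'
#' @return List with character vectors `offtopic` (information-technology
#'   jargon whose presence, absent any on-topic term, marks a comment as
#'   off-topic), `ontopic` (care-related vocabulary that anchors a comment
#'   as on-topic) and `business` (keywords marking a postal address as a
#'   business rather than a residence).
#' @export
default_lexicons <- function() {
  list(offtopic = read_term_file(pkg_resource("offtopic_terms.txt")),
       ontopic = read_term_file(pkg_resource("ontopic_terms.txt")),
       business = read_term_file(pkg_resource("business_terms.txt")))
}

#' Bundled name lists and suffix conventions for the name heuristic
#'
#' @return List with `female_given`, `male_given`, `given` (union),
#'   `surnames` (all lower-cased), `suffix_whitelist` (accepted generational
#'   and professional suffixes) and `male_suffixes` (generational suffixes
#'   conventionally male, used by the male-suffix/female-name rule).
#' @export
default_name_lists <- function() {
  female <- tolower(read_term_file(pkg_resource("given_names_female.txt")))
  male <- tolower(read_term_file(pkg_resource("given_names_male.txt")))
  surnames <- tolower(read_term_file(pkg_resource("surnames.txt")))
  list(female_given = female,
       male_given = male,
       given = union(female, male),
       surnames = surnames,
       suffix_whitelist = c("jr", "sr", "ii", "iii", "iv", "v",
                            "md", "phd", "esq", "dds", "rn"),
       male_suffixes = c("jr", "sr", "ii", "iii", "iv", "v"))
}

#' Rare-cancer catalog for the young-age indicator
#'
#' Cancer types considered rare below the young-age cutoff (40 years):
#' cancers overwhelmingly diagnosed at later ages, such as lung, kidney,
#' bladder and prostate cancers. A respondent under 40 reporting one of
#' these fires the rare-cancer indicator.
#'
#' @param types Character vector of cancer-type levels (see
#'   [survey_schema()]).
#' @return Character vector of class `rare_cancer_catalog`.
#' @export
rare_cancer_catalog <- function(types = c("lung", "kidney", "bladder",
                                          "prostate")) {
  unknown <- setdiff(types, CHECKBOX_GROUPS$cancer_type)
  if (length(unknown))
    stop("unknown cancer type(s) in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(types, class = "rare_cancer_catalog")
}

#' Sex / anatomic-site incompatibility map
#'
#' Cancer types anatomically impossible for a given sex assigned at birth,
#' used by the stage-1 contradiction rule (e.g. a respondent assigned male
#' at birth reporting uterine or cervical cancer).
#'
#' @param male,female Character vectors of cancer-type levels incompatible
#'   with each sex.
#' @return Named list.
#' @export
sex_site_map <- function(male = "uterine_cervical", female = "prostate") {
  list(male = male, female = female)
}

#' Mutually exclusive gender-identity pairs
#'
#' Pairs of gender-identity levels that cannot both be selected by one
#' respondent without contradiction. The defaults pair the two cisgender
#' identities with each other and each cisgender identity with the
#' same-axis transgender identity.
#'
#' @return List of length-2 character vectors of gender levels.
#' @export
gender_exclusive_pairs <- function() {
  list(c("cisgender_male", "cisgender_female"),
       c("cisgender_male", "transgender_male"),
       c("cisgender_female", "transgender_female"))
}
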