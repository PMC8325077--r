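Package: surveyscreen
Title: Rule-Based Fraud and Bot Screening for Web Survey Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens wide, one-row-per-respondent web survey exports for
    fraudulent and bot-generated responses. Implements an eligibility and
    contradiction cascade (residency, cancer stage, diagnosis, excess item
    missingness, discordant gender, discordant sex and anatomic site),
    twelve rule-based suspicious-response indicators (age discordance,
    implausibly young rare-cancer reports, dissemination-source
    incongruence, off-topic open text, duplicated open text and email
    addresses, treatment/diagnosis timeline contradictions,
    submission-time bursts and night-time submissions, and suspicious
    email, postal-address and name patterns), and a two-or-more-indicator
    elimination rule with full flow-chart accounting. Also provides
    retained-versus-excluded comparison statistics (chi-square, Fisher
    exact, Welch t) and a seeded synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
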