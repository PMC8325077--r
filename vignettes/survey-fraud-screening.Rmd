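---
title: "Rule-based screening of web survey responses for fraud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based screening of web survey responses for fraud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Web surveys that pay an incentive and circulate on social media attract
fraudulent and automated responses at scale. In the scenario this package
models — a survey of adult cancer survivors in the United States fielded in
late 2020 — the large majority of submissions arriving through the
public link were not from eligible respondents: they arrived in bursts,
at night, claimed dissemination channels that did not yet exist, reported
internally impossible cancer histories, and reused text and email
addresses. A CAPTCHA alone did not stop them.

`surveyscreen` implements the screening procedure for such data as a
reusable, tested pipeline: a stage-1 eligibility and contradiction
cascade, twelve rule-based suspicious-response indicators, elimination of
any response carrying two or more indicators, flow-chart accounting, and
retained-versus-excluded comparison statistics. A synthetic-cohort
generator with planted ground truth makes every stage testable without
any real respondent data.

```{r, eval = FALSE}
library(surveyscreen)
cohort <- read_responses("export.csv")
res <- run_pipeline(cohort)
res$flow_counts
indicator_summary(res)
```

## The screening model

### Stage 1: eligibility and contradictions

Five rules are applied in a fixed order, and each failing record is
attributed to the *first* stage it fails, so per-stage removal counts are
disjoint and sum to the total removed:

1. **Core ineligibility** — residence outside the United States, stage 0
   cancer, or no cancer diagnosis (no cancer type selected and stage
   reported "none").
2. **Nonmelanoma-only** — a cancer history consisting solely of
   nonmelanoma skin cancer, which falls outside the survivor cohort
   definition.
3. **Excess missingness** — at least 35% of the question inventory
   unanswered (`missingness_cutoff = 0.35`).
4. **Discordant gender** — a mutually exclusive pair of gender
   identities selected together (by default: both cisgender identities,
   or a cisgender identity with its same-axis transgender identity; the
   pair list is configurable through `gender_exclusive_pairs()`).
5. **Discordant sex and anatomic site** — a cancer site impossible for
   the reported sex assigned at birth (`sex_site_map()`; by default
   uterine/cervical for male, prostate for female).

The question inventory behind rule 3 is a genuine design choice: the
denominator counts all substantive survey items (24 by default —
demographics, cancer history, open text, survey source) and excludes
identity and anti-bot fields (name, email, postal address, honeypot,
retyped word, acknowledgement), because skipping those is a privacy
decision, not incomplete data. A "prefer not to answer" selection is an
answer. Both the inventory and the cutoff are configurable.

### Stage 2: the twelve suspicious indicators

Indicators are independent detectors; a respondent is counted under
every indicator their response triggers, and any response with
`indicator_elimination_count` (default **2**) or more is eliminated.
Profiling runs only on stage-1 survivors, matching the procedure's
sequence. One indicator alone never eliminates: the rules are
individually fallible (a night-shift nurse really may submit at 2 AM),
and requiring two independent irregularities trades a small loss of
sensitivity for protection of legitimate respondents.

| Code | Rule |
|---|---|
| `AGE_DISCORD` | year of birth equals the survey year, or reported age and age computed from date of birth differ by more than 1 year |
| `RARE_CANCER_YOUNG` | reported age under 40 with a cancer type rare at that age (default catalog: lung, kidney, bladder, prostate) |
| `SOURCE_INCONGRUENT` | claimed survey source predates that channel's dissemination date |
| `OFFTOPIC_TEXT` | open text contains information-technology jargon and no care-related term |
| `DUP_TELEHEALTH`, `DUP_SUGGESTION` | normalized open-text answer shared by two or more respondents |
| `DUP_EMAIL` | case-insensitive duplicate email address |
| `TIMELINE_DX_LT2_TX_2TO5` | diagnosed under 2 years ago but treated 2–5 years ago |
| `TIMELINE_DX_LE5_TX_GT5` | diagnosed 5 or fewer years ago but treated more than 5 years ago |
| `SUSPICIOUS_TIMING` | member of a run of ≥ 10 submissions with successive gaps ≤ 5 minutes, or submitted between midnight and 4 AM US Eastern |
| `SUSPICIOUS_EMAIL_ADDRESS` | random alphanumeric run in the email, anomalous punctuation/capitalization, or a structurally suspect postal address |
| `SUSPICIOUS_NAME` | first/last name flipped, one name contained in the other, a male generational suffix with a female-only name, or digits / unknown tokens in the suffix field |

A non-empty value in the hidden honeypot item is available as an
optional thirteenth indicator (`profile_cohort(include_honeypot = TRUE)`),
disabled by default so the standard twelve-code profile is unchanged.

### Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `missingness_cutoff` | 0.35 | fraction | removes shells of records with too little content to screen |
| `indicator_elimination_count` | 2 | indicators | single indicators are individually fallible |
| `age_discordance_years` | 1 | years | allows one birthday between DOB arithmetic and self-report |
| `young_age_cutoff` | 40 | years | age below which the catalog cancers are rare |
| `burst_min_run` / `burst_max_gap_minutes` | 10 / 5 | count / minutes | scripted submission leaves long tightly spaced runs |
| `night_window` | 00:00–04:00 | Eastern clock | overseas click-farms submit during the US night |
| `random_run_min_length` | 10 | characters | machine-generated email local parts |
| `duplicate_min_chars` | 15 | characters | keeps "none"/"n/a" from forming duplicate groups |
| `address_min_tokens` | 4 | tokens | a deliverable US address has at least number, street, city, state |

## Numerical and interpretation choices

Several rules are stated qualitatively in the procedure and had to be
made precise here:

- **Burst rule.** "In succession within 5 minutes of each other" is read
  as *successive gaps*: the cohort is sorted by timestamp and split into
  maximal runs whose successive gaps are at most 5 minutes; every member
  of a run of length ≥ 10 is flagged. The alternative any-10-in-a-window
  reading is not used; the chained-gap form is what scripted submission
  produces and is monotone in both thresholds.
- **"Random" email runs.** An alphanumeric run of ≥ 10 characters scores
  random when it mixes digits and letters or contains a five-character
  vowel-free window. This reproduces the machine-generated pattern class
  without a trained model; the punctuation/capitalization clauses are
  regular-expression sets that can be overridden.
- **Address checks.** "Address of a business" and "address is not real"
  cannot be decided offline; they are approximated by a business-keyword
  lexicon and structural checks (token count, quotation marks, internal
  capitalization and spacing anomalies). This is a documented
  approximation, not a postal validation.
- **Timeline codes.** The two timeline contradictions are mutually
  exclusive on one record (treatment time cannot be both 2–5 and > 5
  years), and the generator never plants both.
- **Timezone.** All timing rules operate in US Eastern time. Timestamps
  with explicit UTC offsets are converted; a configuration flag declares
  whether naive timestamps are Eastern.
- **Missing values.** A detector whose inputs are missing never fires;
  incomplete records are handled by the missingness rule, not by
  indicator side effects.
- **Table conventions.** Indicator percentages use all excluded
  responses (stage-1 plus indicator removals) as the denominator by
  default — the convention under which the published indicator table's
  percentages reproduce — with a switch for the suspicious-only
  denominator. Percentages are rounded half-up to one decimal and a
  trailing ".0" is dropped. P values print as "<.001" below 0.001.

## Comparison statistics

`comparison_table()` contrasts the retained sample with the responses
excluded as suspicious (the stage-1 ineligible are not a comparison
group, since they fall outside the cohort definition). Categorical
variables get Pearson chi-square without continuity correction; a 2x2
table with any expected count below 5 falls back to the Fisher exact
test; larger sparse tables keep chi-square with a warning. Means are
compared with the Welch t test by default — the group variances in this
setting are visibly unequal, so the unpooled form is the safer default —
with a pooled option. Single-select and binary percentages use the
per-variable answered count as denominator; multi-select (checkbox)
levels use the full group size, because an unchecked box is
indistinguishable from "not selected". No multiplicity adjustment is
applied; the P values are descriptive, as in the original reporting
style.

## The synthetic-cohort generator

`generate_cohort()` emits three record classes with known truth:
legitimate records that satisfy no rule, ineligible records that
instantiate exactly one planted stage-1 reason, and fraud records that
instantiate exactly their planted indicator set. Plantings are
constructive — a planted burst is a real arithmetic run of timestamps on
October 9–12 (before the email channel's October 13 dissemination
date), a planted duplicate group really shares one normalized text, a
planted random-run email really contains a 12-character mixed run — and
clean records are verified against the detectors at generation time, so
exact planting yields exact recovery by construction rather than by
tuning. Clean submissions sit on a daytime grid with gaps above the
burst threshold; night-window plantings use 00:06–03:54 Eastern slots.

Per-indicator planting is either exact (`indicator_counts`, with a
marginal-preserving repair that guarantees every fraud record at least
two indicators) or independent Bernoulli (`indicator_probs`), under
which the expected detection rate has the closed form
$P(X \ge 2)$, $X \sim \mathrm{Binomial}(k, p)$ — the property the test
suite checks. `fullscale_config()` ships the full-scale layout: 1977
responses, of which 569 legitimate, 1081 fraud with the published
per-indicator marginals, and 327 ineligible split 83 (core) / 46
(nonmelanoma-only) / 149 (missingness) / 12 (gender) / 37 (sex/site);
class demographics follow the published group profiles (retained older,
breast-cancer-heavy; excluded younger, with more lung, kidney and
bladder cancer, more hospice and palliative care). The published core
count of 83 is not broken down further in the source material; the
generator splits it 28/28/27 across non-US, stage 0 and no diagnosis.

What the generator does **not** emulate: real human open text (templates
plus unique suffixes stand in), adversarial detector-aware bots,
realistic postal addresses beyond the structural level, and item-level
missingness patterns of real respondents. Passing the recovery tests
therefore shows that the pipeline implements its rules exactly — not
that those rules would achieve any particular sensitivity on new real
data, where fraud need not instantiate the planted patterns.

All randomness derives from the single seed in `generator_config()`;
the same configuration reproduces the cohort byte for byte.

## Validation sizes

The test suite exercises the full-scale 1977-record cohort for
flow-chart accounting and exact recovery, an independent-planting
cohort of 1000 records (800 fraud) for the binomial detection law, 200
exhaustive-enumeration checks of the Fisher exact P value at totals up
to 30, and 100 randomly configured small cohorts for the conservation
and threshold-monotonicity invariants. These sizes were chosen so the
whole suite runs in well under a minute while keeping Monte-Carlo error
far below the tested tolerances.

## Known limitations

- The rule set is tuned to one survey's schema; new instruments need
  their own inventory, level sets and calendar.
- Duplicate detection is exact-match after normalization; paraphrased
  duplicates pass.
- The name heuristics depend on bundled US-centric name lists; names
  outside them can neither flip nor gender-mismatch, so the indicator
  under-fires for respondents the lists do not cover (it never
  over-fires for them).
- IP-based checks are out of scope: the screening operates on the
  exported response table only.
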