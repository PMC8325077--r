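# surveyscreen

Rule-based fraud and bot screening for incentivized web survey data.

When a paid survey circulates on social media, most of what arrives may
not come from eligible respondents: submissions land in tight bursts and
in the middle of the night, claim dissemination channels that did not
yet exist, report internally impossible health histories, and recycle
text and email addresses. `surveyscreen` implements the two-stage
screening procedure for such data — developed for a web survey of adult
cancer survivors in the United States — as a reusable, tested pipeline
for survey methodologists and epidemiologists cleaning REDCap-style
exports.

The procedure:

1. **Eligibility cascade.** Remove, in order and with first-failure
   attribution: non-US residents, stage 0, no cancer diagnosis;
   nonmelanoma-skin-only histories; records missing ≥ 35% of the
   question inventory; mutually contradictory gender identities; and a
   cancer site impossible for the reported sex assigned at birth.
2. **Indicator elimination.** Profile the survivors against twelve
   independent suspicious-response indicators (age discordance,
   rare-cancer-at-young-age, source incongruence, off-topic text,
   duplicated texts and emails, two treatment/diagnosis timeline
   contradictions, burst/night submission timing, suspicious
   email/address, suspicious name). A response with **two or more**
   indicators is eliminated; a single indicator is tolerated.
3. **Accounting and comparison.** Produce flow-chart counts that
   conserve the cohort, an indicator frequency table over the excluded
   responses, and a retained-versus-excluded demographic comparison
   (chi-square / Fisher exact for frequencies, Welch t for means).

A seeded synthetic-cohort generator plants each rule's defining pattern
into known records, so the whole cascade is validated by exact recovery
of ground truth — no real respondent data are needed or included.

## Worked example

```r
library(surveyscreen)

sim <- generate_cohort(fullscale_config(seed = 1))  # 1977 responses
res <- run_pipeline(sim$cohort)
res$flow_counts
#> <flow_counts>
#>   total                          1977
#>   removed_ineligible_core        83
#>   removed_nonmelanoma_only       46
#>   removed_excess_missingness     149
#>   removed_discordant_gender      12
#>   removed_discordant_sex_site    37
#>   removed_indicators             1081
#>   retained                       569
```

Of 1977 submissions, 327 fail stage 1 (83 ineligible at the core rules,
46 with only nonmelanoma skin cancer, 149 with excess missingness, 12
with contradictory gender identities, 37 with an impossible sex/site
combination), 1081 survivors carry two or more suspicious indicators,
and 569 are retained as the analytic sample.

```r
s <- indicator_summary(res)   # denominator: all 1408 excluded responses
s[s$code %in% c("AGE_DISCORD", "SOURCE_INCONGRUENT", "SUSPICIOUS_TIMING"),
  c("code", "count", "display")]
#>                code count display
#>         AGE_DISCORD   250    17.8
#>  SOURCE_INCONGRUENT   820    58.2
#>   SUSPICIOUS_TIMING   986      70
```

Indicators overlap (a response counts under every indicator it
triggers): 820 of the excluded responses (58.2%) claimed a survey
source before that channel existed, and 986 (70%) were submitted in a
burst or between midnight and 4 AM Eastern.

```r
ev <- evaluate_detection(res$decisions, sim$truth)
c(ev$sensitivity, ev$specificity)
#> [1] 1 1
```

Against the generator's planted ground truth, the pipeline excludes
every fraud record and retains every legitimate one.

Real exports enter through `read_responses("export.csv")`; results are
written with `export_results(res, cohort, "out/")` (retained/excluded
CSVs, flow-chart JSON, per-respondent audit log), and
`comparison_table(cohort, res$decisions)` builds the demographic
comparison with per-level counts, percentages and P values.

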