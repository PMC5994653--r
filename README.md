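# trialwaste

Auditing outcome-related research waste in randomized controlled trials
(RCTs) included in systematic reviews.

## The problem

The summary-of-findings (SoF) table of a systematic review lists the
outcomes its authors consider most important for patients and decision
makers. A trial included in the review still fails to contribute to the
meta-analysis of such an outcome whenever the outcome was never planned,
was planned but never reported, or was reported in a form that cannot be
pooled. Each such missing (trial, outcome) pair is lost evidence —
research waste — and much of it is avoidable.

`trialwaste` is for meta-researchers auditing this waste over a corpus of
review records. It implements the audit in three steps:

1. **Extraction** — per review, select the main comparison (author flag,
   then most SoF outcomes, then most trials, then list position) and build
   the trial-by-outcome **contribution matrix**: `cell(t, o)` is `TRUE` iff
   trial `t` contributes to the meta-analysis of outcome `o`. Pooled over
   reviews: the share of trials in all meta-analyses, the share excluded
   from at least one, and the mean per-trial contribution fraction.
2. **Classification** — a deterministic decision tree assigns each missing
   pair of each evaluable trial (recent, accessible, readable) one of five
   reasons, in order: zero events / reported-but-not-pooled → *other*;
   registered ∧ unplanned ∧ unreported → *inadequate planning*; planned
   (registry, protocol, or publication methods) ∧ unreported → *selective
   reporting*; reported ∧ not poolable → *incomplete reporting*;
   unregistered ∧ unreported ∧ no planning evidence → *indistinguishable*.
3. **Waste assessment** — a missing outcome is avoidable if selectively or
   incompletely reported, or (scenario `reporting_plus_planning`) if
   inadequately planned yet judged by experts easy to measure from both
   trialist and patient perspective, at no or minor cost, and of critical
   importance. Per trial: waste *partially* avoidable (≥ 1 avoidable
   missing outcome) or *totally* avoidable (all assessable missing
   outcomes avoidable).

Corpora are interchanged as nested JSON (authoritative) or a six-file CSV
bundle, can be read from a RevMan 5 XML subset with an SoF sidecar,
materialized deterministically from printed marginal counts
(`build_fixture_from_spec()`), or simulated with a calibrated generator
(`generate_corpus()`).

## Worked example

Build the deterministic corpus from the default marginal counts and run the
audit:

```r
library(trialwaste)

corp <- build_fixture_from_spec(fixture_counts())
corp <- filter_eligible_reviews(corp)$corpus

exclusion_stats(corp)
#> <tw_exclusion_stats> 2711 trial(s)
#>   included in all meta-analyses: 596 (22%)
#>   excluded from >= 1 meta-analysis: 2115 (78%)
#>   mean contribution fraction (trial-level): 0.550

tabulate_reasons(corp, "registered_only")
#> Reasons for missing outcomes - scope: registered_only
#>   missing outcomes N = 461, trials N = 156
#>   INADEQUATE_PLANNING     282 (61%) outcomes in  123 (79%) trials
#>   SELECTIVE_REPORTING      34 ( 7%) outcomes in   23 (15%) trials
#>   INCOMPLETE_REPORTING     98 (21%) outcomes in   64 (41%) trials
#>   INDISTINGUISHABLE         0 ( 0%) outcomes in    0 ( 0%) trials
#>   OTHER                    47 (10%) outcomes in   41 (26%) trials

assess_waste(corp, "reporting_plus_planning")
#> <tw_waste_summary> scenario: reporting_plus_planning (other-policy: exclude)
#>   evaluable trials: 291
#>   waste partially avoidable: 183 (63%)
#>   waste totally avoidable:   86 (30%)
```

Reading the output: of 2711 trials in the main comparisons, 78% are
excluded from at least one important-outcome meta-analysis, and an average
trial contributes to 55% of them. Among the 156 registered evaluable
trials, inadequate planning accounts for 61% of the 461 missing outcomes
(affecting 79% of those trials) — registered trials can never be
"indistinguishable", so that row is structurally zero. Counting both
reporting failures and easily-measurable unplanned outcomes, waste was
partially avoidable for 63% of the 291 evaluable trials and totally
avoidable for 30%.

`summarize_corpus()` bundles all of the above (plus Wilson/Wald confidence
intervals and median–IQR review characteristics), and
`export_waste_matrix()` emits the long-format outcome-status table
(`present` / `absent` / `absent_avoidable`) behind the usual heat-map
figure. A thin CLI over the same functions lives at
`inst/scripts/trialwaste` (subcommands `generate`, `extract`, `classify`,
`assess`, `summarize`).

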