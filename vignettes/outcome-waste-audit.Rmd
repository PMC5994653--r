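---
title: "Auditing outcome-related research waste in randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing outcome-related research waste in randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialwaste)
```

## The problem

Systematic reviews of randomized controlled trials (RCTs) pool results per
outcome. The summary-of-findings (SoF) table of a review lists the outcomes
its authors consider most important for patients and decision makers —
whether or not the included trials measured them. A trial that measured an
important outcome poorly, reported it incompletely, or never planned it at
all cannot contribute to that outcome's meta-analysis. Its evidence is lost,
and the loss is, in a precise sense, *research waste*: patients were
randomized, but part of the answer they helped produce never reaches the
evidence base.

`trialwaste` implements a three-step audit of this waste over a corpus of
review records:

1. **Extraction.** For each eligible review, select the main comparison and
   build the trial-by-outcome *contribution matrix*: cell $(t, o)$ is `TRUE`
   iff trial $t$ contributes to the meta-analysis of SoF outcome $o$.
   Pooled over reviews this yields the share of trials contributing to every
   meta-analysis, the share excluded from at least one, and the mean
   per-trial contribution fraction.
2. **Classification.** For each *missing* (trial, outcome) pair of each
   evaluable trial, a deterministic decision tree assigns one of five
   reasons: inadequate planning, selective reporting, incomplete reporting,
   indistinguishable, or another situation.
3. **Waste assessment.** Using expert feasibility/cost/importance judgments,
   each missing outcome is labelled avoidable or not under two scenarios,
   and each trial receives a verdict: waste *partially* avoidable (at least
   one avoidable missing outcome) or *totally* avoidable (all of them).

## The classification tree

Each annotation records, for one trial and one important outcome: whether a
registration or protocol was retrieved for the trial; whether the outcome
was planned according to it (`yes`/`no`, or `unknown` exactly when no
registration was found); whether the outcome was listed in the publication's
methods section without registry evidence; whether any result was reported;
whether a reported result was poolable; and two special flags (outcome
listed but zero events; reported in poolable form yet left out of the
meta-analysis).

The tree is evaluated in a fixed order:

1. zero events → **other** (`NO_EVENT`, or `NO_ADVERSE_EVENT` for an
   adverse-events outcome);
2. reported in poolable form but not pooled → **other**
   (`REPORTED_NOT_POOLED`);
3. registered, not planned, not reported → **inadequate planning**;
4. planned but not reported — per registry/protocol, or (for unregistered
   trials) per the publication's methods section → **selective reporting**;
5. reported but not poolable → **incomplete reporting**;
6. unregistered, unreported, no planning evidence → **indistinguishable**.

The special situations are checked first because they apply regardless of
planning evidence. Step 4's publication-methods branch is what lets an
unregistered trial be classified as selective reporting; without it the
all-trials selective counts could never exceed the registered-scope counts.
Registered trials can never reach step 6, so the indistinguishable row of a
registered-scope table is structurally zero. Any remaining combination —
e.g. registered, unplanned, yet fully reported and poolable without being
flagged as reported-not-pooled — is surfaced as an error
(`"inconsistent annotation"`) rather than silently filed, because no reason
category describes it; such a pair indicates an annotation mistake or a
reviewer-side exclusion the model does not cover. The tree's totality and
its agreement with an independent restatement of the six rules are verified
by exhaustive enumeration of the annotation truth table in the test suite.

## Avoidability

A missing outcome is avoidable waste if it was selectively or incompletely
reported, or — under the `reporting_plus_planning` scenario — if it was
inadequately planned *and* the expert panel judged it easy to measure from
both the trialist and the patient perspective, at no or minor additional
cost (at most about 5% of the trial's cost), and of major (critical)
importance. Indistinguishable and "other" outcomes are never avoidable.

At the trial level the *assessable set* is the trial's missing outcomes
without the "other" category: zero-event outcomes and results that were
already available do not represent trialist-attributable waste. This
exclusion is a design choice the source text does not settle, so it is
exposed as `other_policy`: the default `"exclude"` drops "other" outcomes
from the denominator; `"block"` keeps them as assessable-but-never-avoidable,
in which case their presence blocks a "totally avoidable" verdict.
Indistinguishable outcomes are assessable but never avoidable under either
policy, so they always block "total". A trial with an empty assessable set
has level `"none"`.

Avoidability is monotone in the scenario: everything avoidable under
`reporting_only` stays avoidable under `reporting_plus_planning`, so the
partial and total counts can only grow — a property the tests check on
random corpora.

## Parameters that matter

* `min_year` (default 2010): evaluable trials must be published in this
  year or later, a half-open bound chosen to make registrations findable.
  `eligibility_criteria()` separately drops reviews whose trials were all
  published before 2007.
* `scope`: reason tables are produced for all evaluable trials and for the
  registered subset; outcome-level counts partition the missing outcomes,
  trial-level counts are coverage counts and may exceed 100%.
* `other_policy` (above).
* `ci_method`: `"wilson"` (default) or `"wald"`. The audit's source does
  not name its interval; both round to the same integer percentages for the
  headline proportions, and the Wilson score interval is preferred as it
  stays inside $[0, 1]$.
* Quartiles: linear interpolation at positions $(n-1)\,p$ (the
  `stats::quantile` type-7 convention), fixed and documented so that
  medians and IQRs are reproducible.
* Display rounding is half-up to integer percent and applied only at
  display; exact fractions are kept in every table.

## The fixture builder

`build_fixture_from_spec()` materializes a complete corpus from printed
marginal counts, with no randomness. The published tables give only
marginals — per-category outcome counts, per-category affected-trial
counts, expert counts, and four trial-level waste counts — not the joint
(trial × reason) layout, so the builder derives one deterministically.
Trial-group sizes follow algebraically from the marginals (for registered
trials: all-avoidable planning-only, mixed, non-avoidable planning-only,
reporting-only, planning-plus-reporting, and other-only groups; analogous
groups for unregistered trials), and outcome counts are spread over each
group with a fixed rule: one per covering trial, extras to the trial with
the most remaining room. Inconsistent marginals (e.g. a category with more
affected trials than outcomes, or registered counts exceeding all-trials
counts) raise a `"specification error"` naming the violated sum.

All fixture reviews carry a five-outcome SoF table — the published median.
The pooled mean contribution fraction is controlled by padding the
non-evaluable excluded trials with extra missing cells: with
`mean_contribution_pct = 55`, the builder solves for the total number of
missing cells (`round(5 × 2711 × 0.45) = 6100`) and distributes the
remainder beyond the evaluable trials' 971 round-robin. Every derived
statistic of the default fixture — 22%/78% inclusion/exclusion, the 55%
mean, 54% registered, all Table-style percentages in both scopes, 78%/82%
expert shares, and 43/12/63/30% waste shares — is recomputed from the
corpus by the pipeline, not stored.

## The synthetic generator

`generate_corpus()` simulates corpora with the statistical structure the
audit assumes. Per review: a trial-bearing main comparison (always listed
first, so the size rule selects it when the author flag is absent, keeping
annotations and the analyzed comparison aligned), 1–12 SoF outcomes with
categories drawn from the published frequency weights, and trials with
year, accessibility, language, and registration flags. Per (trial, outcome)
the evidence chain is a directed Bernoulli factorization
planned → reported → poolable with independent zero-event and
reported-not-pooled overrides; a trial contributes to a meta-analysis
exactly when the outcome is reported, poolable, and neither override fires.
Expert judgments are drawn independently per inadequately planned pair.

The default configuration is calibrated so the implied marginals match the
published figures: registration 54%, pharmacological reviews 60%,
outcomes-per-SoF quartiles (3, 5, 7) on support 1–12, and conditional
probabilities solved in closed form so that the registered-scope reason
shares are approximately 61/7/21/10% with overall missingness near 45%
(`p_planned_given_registered = 0.60`, `p_reported_given_planned = 0.945`,
`p_reported_given_unplanned = 0.31`, `p_poolable_given_reported = 0.856`,
`p_zero_event = 0.04`, `p_reported_not_pooled = 0.032`). The closed-form
implications are exported (`expected_reason_shares()`,
`expected_expert_shares()`) and the test suite checks that empirical shares
from a 500-review corpus fall within three binomial standard errors of
them; the outcomes-per-SoF quartiles are checked on a 2000-review corpus of
single-trial reviews. These sizes are the package's chosen compromise
between sampling noise and test runtime.

What the generator does **not** emulate: effect sizes and pooled estimates
(only inclusion structure is modelled); any dependence between registration
and reporting quality (plausibly positively correlated in reality — the
chain assumes conditional independence); review-level heterogeneity in the
evidence probabilities; and outcomes measured at multiple time points (each
SoF row is an independent outcome). Passing tests therefore demonstrate
correctness of the audit logic under this generative model, not
distributional fidelity to any real review collection.

## Numerical and design choices

* **Main-comparison tie-break** is lexicographic: author flag, then number
  of SoF outcomes, then number of trials, then list position. Outcomes come
  before trials because the unit of analysis is the outcome.
* **Denominator of the contribution fraction** is all SoF outcomes of the
  main comparison, including outcomes with no meta-analysis at all (an
  empty all-`FALSE` column): an important outcome nobody pooled is missing
  for every trial. Trials listed for the comparison but contributing
  nowhere have fraction 0.
* The pooled mean contribution is an **unweighted trial-level mean**; a
  review-then-trial average is also computed
  (`mean_contribution_fraction_by_review`) since the source phrasing does
  not distinguish them.
* **Serialization** sorts reviews, trials, annotation keys, and judgment
  rows, and fixes the key order, so repeated writes are byte-identical;
  round-trip identity is property-tested. The nested JSON is authoritative;
  the six-file CSV bundle is an equivalent flat view.
* **SoF membership in RevMan XML** is not reliably machine-readable, so
  `read_revman_subset()` takes a sidecar naming the analysis outcomes that
  constitute the SoF set (optionally with categories) instead of guessing.
* Degenerate inputs fail loudly: empty corpora, zero denominators, missing
  judgments for planning-scenario assessment, and inconsistent fixture
  marginals all raise errors naming the offending record.

## Limitations

Annotations are inputs: the package classifies evidence, it does not read
registries or PDFs. The expert-elicitation process is likewise not
modelled; a judgment table supplies one consensus row per pair. Trials
excluded from reviews *before* data extraction are invisible to the audit,
which therefore underestimates outcome-related exclusion. All percentages
are recomputed from counts with half-up rounding rather than copied from
any printed table, so a displayed percentage always equals
`round_half_up(100 * count / denominator)` exactly.
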