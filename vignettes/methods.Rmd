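---
title: "Model and methods: CRC screening microsimulation under real-world adherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: CRC screening microsimulation under real-world adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`crcscreen` is an annual-cycle microsimulation of colorectal cancer (CRC)
screening in average-risk U.S. adults, stratified by race (Black, White) and
gender. Each simulated person occupies exactly one health state per year:

* no lesion;
* adenoma by size — diminutive (1–5 mm), small (6–9 mm), large (≥ 10 mm);
* preclinical (screen-detectable, undiagnosed) CRC, stages I–IV;
* clinical (diagnosed) CRC, stages I–IV;
* death from CRC or from other causes (absorbing).

Only the single most advanced lesion is tracked; multiple synchronous
adenomas are absorbed into the calibrated transition rates. Disease moves at
most one link forward along the chain per year (onset → growth by size →
malignant transformation → preclinical stage progression), preclinical
cancer presents clinically with a stage-specific annual detection
probability (a geometric sojourn model), and diagnosed cancer carries
stage-specific excess mortality for ten years (configurable) on top of a
gender-specific other-cause life table. People never return from clinical
states to preclinical or adenoma states; removing an adenoma at colonoscopy
returns the person to the no-lesion state while recording the adenoma
history tier used by surveillance.

A cohort enters at age 40. States at entry come from the model's own
accumulation: everyone starts lesion-free at a seeding age of 20 and the
progression chain runs forward to 40 with screening, symptomatic detection
and mortality disabled, so the cohort is alive and undiagnosed at entry with
a realistic lesion mix. Prevalent pre-40 clinical cancer is out of scope for
an average-risk screening cohort, and pre-45 screening history affects
initiation status only, not disease states — both are deliberate
simplifications.

### Within-cycle order and random numbers

Each year the engine applies, in this fixed order: (1) screening or
surveillance decision and testing, (2) treatment effects of polypectomy or
diagnosis, (3) disease progression, (4) mortality. The order is a modelling
choice the published state structure leaves open; fixing it is required for
bit-reproducibility.

Every stochastic decision consumes a uniform from a counter-based generator
(a splitmix64 hash of seed, person id, cycle and a draw-purpose channel,
implemented in C++). Draws therefore do not depend on cohort storage order
or on how many draws other persons consumed: permuting the cohort leaves
every trajectory unchanged, and two policies run on the same seed share
common random numbers, so strategy comparisons are paired rather than
independent. The QALY-gained outcome is computed as a paired subtraction
against a no-screening run of the same cohort and seed.

## Screening behaviour

Four modalities are modelled at guideline intervals: colonoscopy (10 y), CT
colonography (CTC, 5 y), FIT (1 y), and multitarget stool DNA (MT-sDNA,
3 y). Test performance is the packaged patient-level base case
(`default_test_performance()`); in the base case CTC has zero sensitivity
for diminutive adenomas because sub-6 mm lesions are not referred.
Colonoscopy and CTC specificity is imperfect; false positives incur the
procedure's cost and disutility but change no disease state.

Adherence has three components per person:

1. **Initial screening** — annual probability of first-ever screening, by
   age band (45–49 … 70–75) and by the modality the person would have
   chosen under the status quo (their *origin*: colonoscopy or FIT).
2. **Repeat screening** — annual probability of returning once the
   modality's interval has elapsed, by age band (< 65, ≥ 65) and current
   modality. A draw missed while overdue is retried every year.
3. **Switching** — under the status quo only, a probability of changing
   between colonoscopy and FIT at the due date (a calibrated parameter,
   default 0).

All screening — including surveillance — ends after age 75. A fraction of
each group is already screened before 45 (packaged per group and origin);
those people enter as initiated with a due date spread uniformly over one
interval. Never-screened people are assigned an origin using the pre-45
split ratio, exposed as `origin_frac_colonoscopy`.

Single-modality strategies are derived from the status quo
(`derive_strategy_profile()`): initial schedules are multiplied by
origin-specific relative risks (CTC: 1.80 from colonoscopy-origin, 0.53
from FIT-origin; colonoscopy-only: 1.00/0.29; FIT-only and MT-sDNA-only:
3.45/1.00), clipped at probability 1. Repeat schedules are sourced per
rule: colonoscopy-only uses colonoscopy repeat for everyone; FIT-only and
MT-sDNA-only use FIT repeat; CTC-only uses colonoscopy repeat, with Black
groups' values odds-adjusted upward by an odds ratio of 1.83
(`apply_repeat_odds_ratio()`, odds = p/(1−p) scaled then inverted).

Positive non-colonoscopy tests trigger a diagnostic colonoscopy with
modality-specific follow-up adherence (CTC 97.7%, FIT 48.7%, MT-sDNA
66.6%); a missed follow-up leaves the person untreated and back in routine
screening at the next due date. Adenoma removal assigns a history tier
(small → low risk, large → high risk, never downgraded) and moves the
person to surveillance colonoscopy — every 5 years (low) or 3 years (high),
attended with probability 44.7% / 54.6%, retried annually when missed. The
surveillance intervals are standard post-polypectomy guidance; they are
configurable because no single interval convention is universal.

## Health economics

Events are booked at cycle start with no half-cycle correction; a person
dying in a cycle accrues that year's utility. Costs and QALYs discount at
3%/year to age 40. Screening costs bundle procedure, bowel preparation and
patient/escort time (stool tests: kit plus one hour of patient time) —
a limited societal perspective with no productivity losses. Cancer care
follows the usual three phases by stage: initial year, continuing years,
terminal year before CRC death. Utilities are age-banded baselines with
per-event disutility decrements (magnitude × duration) and a stage-specific
annual decrement while living with diagnosed cancer.

The packaged dollar and disutility values are **illustrative placeholders,
not asserted estimates** — no literature cost or disutility table is
reproduced here. The placeholders were fixed once, on the scales published
per-1000 screening results imply
(≈ $96k discounted cancer-care cost per no-screening case; CTC procedure
$225 plus preparation and time; MT-sDNA kit ≈ $509 plus an hour of patient
time), and every schedule is editable through keyed text configs.

## Cost-effectiveness analysis

`build_icer_ladder()` ranks strategies by ascending cost, removes simply
dominated rows (no more QALYs gained than a cheaper alternative; exact ties
keep stable input order with the later row dominated), then removes
extended-dominated rows until ICERs between consecutive undominated rows
strictly increase — the convex frontier. The cost-effective strategy is the
undominated row with the largest ICER at or below the willingness-to-pay
threshold ($100,000/QALYG by default), and a strategy cheaper and more
effective than every alternative is flagged dominant. Both "dominated" and
"extended-dominated" are flagged distinctly so a published-style table can
print either label. Net monetary benefit (WTP × QALYG − cost) is the
decision-equivalent linear form used by the sensitivity analyses.

One-way sensitivity analysis re-evaluates the CTC-only versus status-quo
comparison at each parameter's range endpoints (all else at base case),
seed-aligned, and reports incremental NMB sorted by swing. The PSA samples
parameter sets from the published uncertainty distributions (Beta shape
pairs as printed; PERT with λ = 4 — the standard choice, since the source
names PERT without a λ — for multipliers published as ranges), averages
each draw's outcomes over the calibrated parameter sets, and reports the
cost-effectiveness acceptability curve and frontier over $10k–$500k.

## Calibration

Free parameters are five scales around the reference natural history:
adenoma onset, adenoma growth, the large-adenoma transformation rate, the
clinical-detection rates, and initial screening adherence. Candidates are
scored by weighted mean squared error with *relative* deviations (scaled by
the observed value) so incidence-per-100,000 and proportion targets are
commensurable; zero-valued targets contribute absolute deviations. Target
families: age-band clinical incidence (45–54 … 75–84, per 100,000
person-years), stage distribution in screening and non-screening eras (the
latter emulated by re-running the candidate with screening off), adenoma
prevalence at 50/60/70 — including large-adenoma prevalence, without which
the transformation rate is unidentified because the chain can compensate —
ever-screened proportions and test recency.

The adaptive sampler is in the tree-structured Parzen estimator family:
random startup (one fifth of the budget), then a split of observed scores
at the γ = 0.25 quantile, per-dimension Gaussian kernel densities for the
good and bad sets in the unit cube (log scale for rate parameters), and
the candidate maximizing the good-to-bad density ratio among 24 samples.
A pure-random sampler is the always-available fallback. Evaluations share
one common-random-number seed so candidate comparisons are not swamped by
Monte-Carlo noise; the full evaluation log is persisted and the 100
best-scoring sets (stable ties by evaluation index) feed the simulation
stage.

**Recovery tolerances.** On synthetic targets (5% multiplicative log-normal
noise, 500 evaluations, 20,000-person evaluations) the top-1 set is
expected within 25% relative error for the well-identified scales (onset,
clinical detection) and 35% for the scales with compensation along the
progression chain (growth, transformation rate, initial adherence). These
tolerances were set from the identifiability argument above, per parameter,
and are what the recovery tests assert.

## What the synthetic generator does and does not emulate

`make_truth()` draws a deterministic-per-seed truth around reference
parameters whose unjittered no-screening lifetime risk is anchored to the
published 67–84 cases/1000 band (groupwise onset scales chosen once for
that purpose); jittered truths stay inside a design band of 55–115
cases/1000. `make_targets()` simulates a 50,000-person cohort at truth and
perturbs every summary with independent multiplicative log-normal noise.
That emulates registry-like incidence curves, stage mixes, prevalence and
survey-like uptake proportions *in structure*, but not: real SEER age
curves or cohort effects, NHIS survey weighting, correlated target errors,
sessile-serrated biology, or post-2019 screening disruptions. Passing
recovery and dominance tests therefore demonstrates that the machinery is
correct and internally consistent at realistic magnitudes — not that the
packaged parameters reproduce U.S. surveillance data.

## Numerical choices and problem sizes

* Annual cycles, integer ages 20–100; cohort enters at 40, screening runs
  45–75.
* Probabilities are used as given (no rate-to-probability conversion);
  multiplier products clip at 1.
* Mortality order within a cycle: other-cause first, then CRC excess among
  survivors with diagnosed disease inside the ten-year window.
* Desk problem sizes, chosen as the package's defaults: 20,000 persons per
  strategy simulation, 20,000 per calibration evaluation with a budget of
  500, 200 PSA draws at 500 persons. The production scale — 500,000
  persons, the top 100 calibrated sets, 5,000 PSA draws — is configuration
  (`run_config()`), not a default.
* All tables are tab-delimited text with period decimals and no grouping,
  so reruns under one manifest are bit-identical.

## Known limitations

Single-lesion state machine (no synchronous adenomas or serrated pathway);
no flexible sigmoidoscopy or gFOBT; stage at diagnosis fixed after
diagnosis; CRC survival independent of age at diagnosis; illustrative life
table and economic placeholders; screening behaviour limited to the four
modelled modalities with colonoscopy/FIT as status-quo origins.
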