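# crcscreen

A race- and gender-stratified microsimulation of colorectal cancer (CRC)
screening under **real-world adherence**, with the full analysis pipeline
around it: natural-history calibration, discounted cost/QALY accounting,
ICER ladders with dominance, and one-way plus probabilistic sensitivity
analyses.

## The problem

Cost-effectiveness comparisons of CRC screening modalities — colonoscopy
every 10 years, CT colonography (CTC) every 5, annual FIT, multitarget
stool DNA (MT-sDNA) every 3 — usually assume perfect or uniform adherence.
Real screening behaviour differs by race and gender: who starts screening,
with which modality, whether they return at the recommended interval,
whether a positive stool test is followed by a diagnostic colonoscopy. This
package models that behaviour explicitly and asks how it changes the
ranking of strategies, for Black and White men and women.

## The model in brief

Each person moves through annual cycles of an adenoma–carcinoma natural
history — no lesion → adenoma (diminutive/small/large) → preclinical CRC
I–IV → clinical CRC I–IV → death — with other-cause mortality from a life
table. Screening behaviour has three components per person: *initial*
uptake (by age band and the modality the person would choose under the
status quo), *repeat* adherence (by age band and current modality, retried
annually while overdue), and modality *switching* at due dates under the
status quo. Single-modality strategies are derived from the status quo by
published relative-risk multipliers on initial adherence — for origin
modality colonoscopy / FIT respectively: CTC 1.80 / 0.53, colonoscopy-only
1.00 / 0.29, FIT-only and MT-sDNA-only 3.45 / 1.00 — and by repeat-rule
sourcing, with Black groups' CTC repeat adherence odds-adjusted by
OR 1.83: p' = OR·o/(1+OR·o), o = p/(1−p). Positive non-colonoscopy tests
reach diagnostic colonoscopy with modality-specific follow-up adherence
(CTC 97.7%, FIT 48.7%, MT-sDNA 66.6%); adenoma history sends people to
surveillance colonoscopy (44.7% / 54.6% adherence by risk tier).

Outcomes per 1000 40-year-olds, discounted at 3%: lifetime cost, QALYs
gained versus a seed-matched no-screening run, CRC cases, test and
colonoscopy counts, uptake by 75. Strategies are ranked on a cost-ascending
ICER ladder with simple and extended dominance; decision threshold
$100,000/QALYG. Free natural-history parameters are calibrated to weighted
summary targets by an adaptive (Parzen-estimator-type) search scored with
relative mean squared error, keeping the 100 best sets.

All stochastic decisions use a counter-based RNG keyed by (seed, person,
cycle, purpose), so cohorts are order-independent and strategy comparisons
share common random numbers. Every input the pipeline needs can be produced
by the synthetic-data module from a known-truth specification, so the whole
analysis runs end-to-end with zero downloads and calibration is testable by
parameter recovery.

## Worked example

```r
library(crcscreen)

truth <- make_truth(1, "Black men")      # known-truth disease + adherence
out <- simulate_strategies("Black men", truth$params, n = 20000, seed = 2,
                           sq_profile = truth$profile)
out[, c("strategy", "cost", "qalyg", "crc_cases")]
#>           strategy    cost qalyg crc_cases
#> 1     no_screening 6121297  0.00     65.45
#> 2       status_quo 4857639 39.55     36.30
#> 3         ctc_only 4565050 50.76     29.25
#> 4 colonoscopy_only 4843842 41.95     34.00
#> 5         fit_only 5057818 27.34     48.05
#> 6      mtsdna_only 6058466 33.61     42.50

build_icer_ladder(out[, c("strategy", "cost", "qalyg")], wtp = 1e5)
```

Reading: without screening this synthetic cohort develops 65 CRC cases per
1000 adults over their lifetimes; every screening strategy both costs less
(cancer care averted exceeds screening outlay) and adds QALYs, and the
CTC-only strategy — cheapest and most effective here — is dominant, the
qualitative pattern reported for Black adults. Costs are per 1000 persons
in (placeholder) 2024 USD; `qalyg` is QALYs gained per 1000 versus
no screening on the same cohort and seed.

The numbered scripts under `analysis/` run the full experiment at desk
scale and write tables under `results/`: `01_derive_adherence.R` (derived
strategy schedules), `02_calibrate.R` (synthetic-target calibration and
recovery summary), `03_simulate_strategies.R` (outcome tables),
`04_cea.R` (ICER ladders), `05_sensitivity.R` (tornado and CEAC).

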