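# flarecco

Case-crossover analysis of pain flares from daily symptom diaries.

People with rheumatoid arthritis log daily 1–5 ratings of pain and related
symptoms in mobile-health apps, alongside accelerometer-derived sleep and
activity. `flarecco` turns such diaries into an answer to a within-person
question: *do short-term changes in a symptom over the last 3 days make a
pain flare more likely the next day?* It is written for epidemiologists and
biostatisticians working with intensive longitudinal symptom data.

The package implements, as composable functions:

* **Flare detection** under three progressively stringent numeric rules on
  the 1–5 pain scale — above personal median (**AA**), above threshold 3
  (**AT**), and a move from 1–3 to 4–5 (**MAT**) — with the onset, end,
  run-collapsing, same-end deduplication and censoring conventions needed
  to make them exact on calendars with missing days, plus carry-on impact
  assessment and 30-day monthly rates.
* **Case-crossover window construction**: 3-day hazard windows
  `[onset-3, onset-1]` and full-stratum bidirectional or nonoverlapping
  control windows, each summarized per exposure by the 3-day mean and the
  intraindividual SD (iSD).
* **Exact conditional logistic regression** (`cclogit()`) for matched sets
  with several cases per stratum, via the subset-sum recursion
  `B(j,l) = B(j-1,l) + exp(x_j'β) B(j-1,l-1)` carried with exact
  derivatives, Newton–Raphson estimation, and cluster-robust sandwich
  standard errors `A⁻¹ (Σ_c U_c U_cᵀ) A⁻¹` over participants. Odds ratios
  are reported with robust 95% Wald CIs: `exp(β̂ ± 1.96·SE)`.
* **A synthetic cohort generator** with latent AR(1) ordinal symptoms and
  *planted* lagged exposure effects on next-day high pain, plus a 30-second
  actigraphy epoch simulator, so the whole pipeline can be validated
  against known truth (sedentary ≤ 178.5 counts/min, MVPA ≥ 562.5).

## Worked example

Simulate a 60-participant, 30-day cohort in which a one-unit increase in
the 3-day mean of anxiety raises the odds of next-day high pain by
`exp(0.7) ≈ 2`, then run the primary analysis for the AT definition:

```r
library(flarecco)

sim <- simulate_cohort(sim_config(
  n_participants = 60, n_days = 30,
  planted_effects = list(list(exposure = "anxiety", metric = "mean", beta = 0.7)),
  missing_rate = 0.05, seed = 42))

run <- run_primary(sim, definitions = "at")
run
#> Case-crossover pain-flare analysis (full_stratum)
#> 60 participants included, 0 excluded
#>   at: 83 flares in 39 participants; 447 risk-set windows
#> 48 coefficient rows, 5 significant at 95%
```

Flare characteristics (the detection layer's summary):

```r
run$flare_summaries[c("definition", "n_with_flare", "pct_with_flare",
                      "n_flares", "duration_median", "rate_median")]
#>  definition n_with_flare pct_with_flare n_flares duration_median rate_median
#>          at           39             65       83               2        2.07
```

65% of participants had at least one AT flare (83 episodes; median duration
2 days; median monthly rate ≈ 2). The model battery fits 24 univariable and
12 multivariable conditional-logit models; the planted signal is where it
should be:

```r
subset(run$results, exposure == "anxiety" & model_type == "univariable" &
                    metric == "mean")[c("or", "ci_low", "ci_high",
                                        "significant", "n_strata")]
#>    or ci_low ci_high significant n_strata
#>  1.98   1.26    3.12        TRUE       32
```

The estimated OR of 1.98 (95% CI 1.26–3.12) recovers the planted `exp(0.7)
≈ 2.01`: across the 32 risk sets, hazard windows had systematically higher
3-day anxiety means than that participant's control windows. A sensitivity
analysis with disjoint sequential controls is one call away:
`run_sensitivity(sim, definitions = "at")`.

The generator also plays the role of raw-data sources: `simulate_epochs()`
emits labelled 30-second actigraphy epochs that
`summarize_actigraphy_day()` reduces to sleep efficiency, time in bed and
sedentary %, and `select_daily_records()` / `apply_inclusion()` handle raw
timestamped app entries (post-noon final record per day; inclusion requires
≥7 consecutive pain days and ≥70% completion).

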