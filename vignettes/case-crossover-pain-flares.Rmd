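---
title: "Detecting pain flares and estimating their short-term correlates by case-crossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pain flares and estimating their short-term correlates by case-crossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People with rheumatoid arthritis experience day-to-day pain fluctuation, and
occasionally *pain flares*: short periods of markedly increased pain with
outsized impact on daily life. Daily mobile-health diaries (ordinal 1–5
symptom ratings) and wrist-worn accelerometers make it possible to detect
such flares numerically and to ask which short-term changes — in mood,
anxiety, fatigue, sleep, activity — precede them within a person.

`flarecco` implements that full analysis as reusable components: flare
detection under three progressively stringent rules, construction of 3-day
hazard (pre-flare) and control windows, exposure summaries by mean and
intraindividual standard deviation (iSD), and exact conditional logistic
regression over each participant's matched windows with cluster-robust
standard errors. A synthetic cohort generator with *planted* exposure
effects makes every stage testable against known truth, which matters
because real diary cohorts of this kind are rarely shareable.

## Flare definitions and detection conventions

Let $m_i$ be participant $i$'s personal median of all observed daily pain
scores. A candidate onset day $t$ must satisfy, by definition:

* **AA** (above average): $\text{pain}_t > m_i$;
* **AT** (above threshold): $\text{pain}_t > 3$;
* **MAT** (move above threshold): $\text{pain}_{t-1} \in \{1,2,3\}$ on the
  previous *observed calendar* day and $\text{pain}_t \in \{4,5\}$.

All onsets must additionally lie strictly above $m_i$ — this single rule
also removes onsets whose value equals the median and would conflict with
the end rule. Consecutive qualifying days collapse to the first day of the
run. The episode ends on the first later day with pain at or below $m_i$;
when several onsets share an end day only the first is kept.

Conventions the rules do not fully pin down, and how this package resolves
them:

* **Duration counts both endpoints** (`end - onset + 1`), making the minimum
  flare 2 days — the only convention compatible with a reported minimum
  duration of 2 when one-day spikes must be representable.
* **Flares never span missing pain days.** A missing day breaks a
  qualifying run and *censors* an open episode; censored episodes are
  excluded from counts and duration statistics by default
  (`include_censored = TRUE` reports them), but their observed
  above-median days still block hazard and control windows, since those
  days are in-flare regardless of whether the episode's end was observed.
  Censored episodes contribute no hazard window.
* **Medians are fixed per participant** over the whole observation period,
  using the standard even-count convention (so medians may be half-integers
  and all comparisons are on the real line).
* **MAT needs an observed yesterday**: day 1 of observation can never be a
  MAT onset.

A structural consequence worth knowing: every AT episode lies inside an AA
episode (same end rule, and AT-qualifying days are AA-qualifying). MAT and
AT onsets coincide exactly whenever their candidate days agree — the
personal median below 4 (so the threshold rule binds) and no AT-qualifying
pain on day 1 (a day-1 AT onset has no MAT counterpart, and its episode can
absorb later candidates through the same-end rule that MAT would keep).
Outside that domain the definitions genuinely diverge: at a median of 4–5 a
previous-day pain of 4 blocks a MAT onset without being AT-qualifying. The
test suite checks the exact equivalence on its domain of validity.

**Carry-on impact.** A completed flare has a carry-on effect when illness
impact on the flare's end day is still above the participant's personal
impact median; its duration counts days from the flare end (inclusive)
until impact first returns to the median or lower (exclusive). Missing
impact on the end day makes the assessment indeterminate; missing follow-up
leaves the duration indeterminate while the flare still counts as affected.

## Hazard and control windows

The case-crossover design compares each participant with themselves:
exposure in the 3 days before a flare onset (hazard window) versus 3-day
windows that did not precede a flare (controls), eliminating time-invariant
confounding. Windows require complete data on all 12 exposures.

A hazard window is exactly `[onset - 3, onset - 1]` and is dropped when any
of its days falls in another flare of the same definition (so not every
flare enters the analysis). Control windows, in the primary *full-stratum
bidirectional* mode, are all 3-day windows that (a) are not the pre-onset
window of any flare, (b) share no day with any flare, (c) share no day with
any hazard window, (d) are complete, and (e) are followed by an observed
pain day that is not an onset. Condition (e) is on by default
(`require_followup = FALSE` disables it): a control window must have an
evaluable following day, otherwise it could not "have been" a pre-flare
window. Controls may overlap each other and may cover post-flare days; the
sensitivity mode (`nonoverlap`) instead tiles the eligible candidates
greedily from the earliest start into pairwise disjoint windows.

Each window is summarized per exposure by the mean of its 3 values and the
iSD (sample SD, denominator 2) — level versus day-to-day variability.
Exposures enter the models on their recorded scale, so odds ratios are per
unit of the 1–5 scale, per percentage point, or per hour.

### A known property of full-stratum selection

Because windows that share days with a hazard window are excluded from the
control pool, the controls are systematically depleted of windows whose
exposure resembles the hazards'. When an exposure truly drives flares this
induces a small upward finite-sample bias in the full-stratum estimate; the
nonoverlap selection does not suffer from it, which is one reason a
sensitivity analysis with disjoint sequential controls accompanies the
primary analysis. The package's parameter-recovery validation therefore
evaluates the nonoverlap estimator against the planted truth and treats the
full-stratum estimate as the primary descriptive analysis.

## Exact conditional logistic regression

Each participant with at least one hazard and one control window forms a
risk set. By default the whole risk set is one stratum with possibly
several cases, handled by the *exact* multi-case conditional likelihood
(no Breslow/Efron tie approximation): for a stratum with windows
$x_1,\dots,x_m$ of which $k$ are hazards,

$$\ell = \sum_{\text{cases}} x_j^\top\beta \;-\; \log B(m,k),\qquad
B(j,l) = B(j-1,l) + e^{x_j^\top\beta} B(j-1,l-1),$$

where $B(m,k)$ sums $\exp(\sum x^\top\beta)$ over all $\binom{m}{k}$
size-$k$ subsets. The recursion carries first and second derivatives, so
score and observed information are exact; the linear predictor is shifted
by its stratum maximum before exponentiation, keeping every term in
$[0,1]$. With one case per stratum this reduces to the familiar softmax
conditional likelihood.

`cclogit()` maximizes the summed likelihood by Newton–Raphson from
$\beta = 0$ with step halving, stopping when the largest score component
falls below `1e-8` or the relative log-likelihood change below `1e-10`
(at most 100 iterations). Concordant strata (all-case or all-control)
carry no information and are dropped with a count; a design that is
collinear after within-stratum centring is refused; estimates diverging
past $|\beta| > 15$ are flagged as probable complete separation rather
than reported as estimates.

Standard errors are cluster-robust: $V = A^{-1} \left(\sum_c U_c
U_c^\top\right) A^{-1}$ with $A$ the total observed information and $U_c$
the summed score contributions of cluster $c$ (participants), accounting
for within-participant correlation when one person contributes several
hazard periods. Confidence intervals are Wald intervals on the log-odds
scale; a 95% CI excluding an OR of 1 is flagged significant, with no
multiplicity adjustment across the exploratory battery of 24 univariable
and 12 multivariable models per definition. An alternative stratification
(`stratum = "hazard"`: each hazard against all of the participant's
controls, clusters still participants) is exposed because the risk-set
construction does not by itself dictate the choice.

## The synthetic cohort generator

`simulate_cohort()` emulates a 30-day diary study:

* Nine ordinal symptoms from latent Gaussian AR(1) processes (unit
  stationary variance, default lag-1 autocorrelation 0.5 — a free
  parameter, since within-person symptom autocorrelations are not
  well-established) plus a persistent between-person intercept
  (SD 0.6), cut into five categories at equiprobable marginal quintiles.
* Three continuous exposures (sleep efficiency ~85%, sedentary time ~65%,
  time in bed ~8 h) as clamped AR(1) processes around person-level bases.
* Pain from a proportional-odds layer whose linear predictor adds a
  between-person intercept (SD 1.3), a persistent AR(1) component, and the
  planted effects: each planted `beta` multiplies the 3-day mean or iSD of
  the named exposure over days $t-3..t-1$ (days 1–3 use the baseline
  predictor only), so `beta` is the log-OR of next-day high pain (4–5
  versus 1–3) per unit of that summary — the quantity the downstream
  pipeline estimates. The pain cutpoints and AR component are calibrated so
  that a null cohort reproduces reported flare characteristics of daily RA
  diaries: roughly half to two-thirds of participants with at least one
  AT/MAT flare in 30 days, median monthly rate near 2, duration median 2
  (IQR 2–3) with occasional episodes near 10 days.
* Illness impact tracks pain tightly (within-person correlation around
  0.6) through a short-memory decaying latent, so most flares end with
  impact back at the personal median the same day while roughly a quarter
  retain a carry-on effect of about a day — the qualitative pattern
  reported for daily RA diaries, and enough signal to exercise carry-on
  detection. Whole days are removed completely at random at the
  configured `missing_rate` — mirroring an analysis that excludes
  incomplete days rather than imputing.

One integer seed governs everything; per-participant substreams are derived
from it by a fixed integer hash, so cohorts are bit-reproducible and
participant streams do not interact.

`simulate_epochs()` generates one day of 30-second actigraphy epochs with
sleep/wake labels: an in-bed interval whose endpoints are sleep-labelled
(so the labelled span equals the interval), interior sleep epochs allocated
to the target efficiency, and waking minutes assigned *exactly* (counts per
category, shuffled positions) with per-minute totals drawn inside the
MotionWatch class intervals — sedentary ≤ 178.5 counts/min, moderate-to-
vigorous ≥ 562.5 — and split across the minute's two epochs. Cut-point
classification of the generated stream therefore recovers the targeted
sedentary percentage to rounding accuracy.

What the generator does *not* emulate: informative missingness (drop-out,
symptom-dependent skipping), weather or medication dynamics, device
non-wear, or the proprietary sleep-scoring of raw counts (sleep/wake labels
are taken as given). Passing tests on these cohorts show the pipeline's
rules and estimators are correct and well-calibrated under MCAR
missingness and a correctly specified lagged-logit exposure effect; they do
not certify behaviour under informative missingness or model
misspecification on real data.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle: flare
detection against a naive day-by-day enumerator of the written rules on
thousands of random series (with and without missingness); the conditional
likelihood against direct subset enumeration and finite-difference
derivatives for all stratum shapes up to $m = 8$; matched-pairs fits
against the closed form $\hat\beta = \log(n_{10}/n_{01})$; the full fit
against the survival package's exact conditional logit; window construction
against the design constraints on hundreds of simulated cohorts. End-to-end
calibration uses 50 replicate cohorts of 300 participants for recovery of a
planted 0.7 log-OR and 200 null cohorts of 200 participants for the type-I
error of the CI-excludes-1 test at nominal 5% — sizes chosen to keep
Monte-Carlo error comfortably inside the assertion bands while the whole
suite stays minutes-scale.

## Limitations

* Numeric rules on a 5-point scale cannot represent flares in participants
  with constantly high (or constantly low) pain; they contribute no
  episodes.
* The full-stratum control pool's overlap bias (above) is inherent to the
  design, not to this implementation; compare with the nonoverlap
  sensitivity results.
* Carry-on assessment and monthly rates treat the personal median as fixed
  over the study; with strong trends a fixed median conflates level and
  change.
* The generator's planted effects act through a proportional-odds shift;
  effects that alter only the shape of the pain distribution are outside
  its truth model.
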