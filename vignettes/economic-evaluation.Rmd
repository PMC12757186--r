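---
title: "Methods: within-trial and model-based cost-effectiveness analysis"
author: "dupcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial and model-based cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcea)
```

## The problem

Moderate Dupuytren's contracture can be corrected surgically (limited
fasciectomy, LF) or pharmacologically (collagenase clostridium histolyticum
injection). The two pathways differ sharply in delivery cost (an operating
theatre and surgical staff versus an outpatient injection), in the shape of
the post-treatment quality-of-life trajectory (a deep two-week utility dip
after surgery versus a mild dip after injection), and in durability
(collagenase recurs more often). Which treatment is cost-effective therefore
depends on the horizon over which costs and benefits are accumulated.

`dupcea` implements both analytic layers used to answer that question:

1. a **within-trial cost-effectiveness analysis** of a two-arm randomized
   trial — micro-costing of resource use, area-under-the-curve (AUC)
   quality-adjusted life-years (QALYs), multiple imputation by chained
   equations, seemingly unrelated regression (SUR) of incremental cost and
   QALYs, a nested nonparametric bootstrap, ICER/NHB/CEAC reporting, and a
   vial-price threshold analysis; and
2. a **lifetime nine-state Markov cohort model** with age/sex background
   mortality and Monte-Carlo probabilistic sensitivity analysis (PSA).

Because patient-level trial data of this kind are confidential, the package
ships a seed-reproducible synthetic-data generator that emulates the
statistical structure the analyses must cope with. Every stage of the
pipeline runs, and is tested, against that generator.

## The synthetic trial generator

`trial_config()` / `generate_trial()` draw a two-arm dataset (default 336
patients per arm, follow-up at baseline, 2 and 6 weeks, 3 and 6 months, 1
and 2 years) with:

* **Utilities**: censored-normal draws in `[-0.594, 1]` around arm- and
  time-specific means. The location of each draw is solved numerically so
  that the *censored* mean equals the configured target; empirical means
  therefore converge to the configured trajectory despite the bounds, and
  the mass piling up at 1 produces the left skew typical of EQ-5D index
  values. Default trajectories encode the surgical dip (0.794 to 0.715 at
  two weeks) versus the injection dip (0.791 to 0.776), recovery by three
  months, and a slow late decline in the injection arm (about 0.044 lower at
  two years).
* **Resource use**: gamma-distributed quantities per cost category and year
  (right-skewed), plus deterministic delivery quantities (one theatre
  session, one vial, ...). Category means are calibrated once so that, at
  the default unit costs, expected intervention costs are £2166 (LF) and
  £984 (collagenase), year-one follow-up care ≈ £521 / £613, year-two
  increments ≈ £393 / £271, and productivity losses ≈ £487 / £138.
* **Cost–utility correlation**: a shared patient-level standard-normal
  frailty enters utility errors with a negative loading (`frailty_cor`,
  default 0.35) and scales stochastic resource quantities multiplicatively
  (mean-preserving, `cost_frailty` = 0.25 on the log scale). Sicker patients
  cost more and report lower utility — the cross-equation correlation that
  joint (SUR) estimation exists to exploit.
* **Deaths**: exponential with arm-specific annual probabilities (defaults
  0.15% vs 1.19%, reproducing the order of magnitude of 1 vs 8 deaths over
  two years). Utilities at follow-ups on/after death and resource use in
  periods starting after death are *structural zeros*, encoded as `0`, which
  is deliberately distinguishable from the masking sentinel `NA`.
* **Recurrence**: one-year recurrence flags with arm probabilities 13.8% /
  17.2%, defined only for patients alive at one year.
* **Missingness**: `apply_missingness()` masks post-baseline utilities,
  follow-up resource quantities (per year), the hand-outcome score and the
  recurrence flag with a per-patient logistic probability driven only by
  always-observed covariates (age, sex, arm, baseline utility) — a
  missing-at-random mechanism the imputation model can exploit. Structural
  zeros are never masked, and a specification that tries to drive
  missingness with a post-baseline outcome is rejected (it would be MNAR).

What the generator does **not** emulate: clinical hand-function endpoints
(the PEM score is a noise covariate only), within-trial care disruption,
item-level medication detail, or any real patient's joint distribution of
covariates. The trial's demographic margins are not public, so age
(Normal(66, 8) truncated to 18–84) and sex (80% male) are explicit
placeholders. A passing test suite therefore demonstrates that the
*methods* behave correctly under a realistic data-generating process, not
that the synthetic cohort reproduces any particular patient population.

## Costing

`cost_trial()` multiplies each `qty_<category>_<period>` by its
scenario-resolved unit cost (`resolve`d against a plain-text
`unit_cost_table`) and sums into intervention, per-year follow-up and
societal buckets. The scenario machinery mirrors the standard sensitivity
analyses:

* **HRG method**: intervention delivery is priced by per-episode reference
  tariffs (HN43B £2936 for fasciectomy, HN46Z £196 for wound-clinic and
  manipulation attendances, HN45A £1143 for the injection episode, drug
  included), replacing the micro decomposition entirely; the micro
  categories a tariff subsumes price at zero so the two methods never
  double-count.
* **Theatre setting**: the injection visit is re-priced as a minor theatre
  session (config entry, default £672) instead of an outpatient attendance.
* **Trainee staffing**: surgeon minutes are re-priced at the trainee rate —
  a pure staff-minute rate swap on the delivery line.
* **Societal perspective**: adds human-capital productivity loss
  (`absence_days × daily_wage`, default wage £100/day); zero under the
  NHS/PSS perspective, so societal totals always nest NHS/PSS totals.
* **Vial price**: the collagenase drug line is `vials × price`, overridable
  per scenario; this is the lever the threshold analysis moves.

All arithmetic is exact in pounds; rounding to whole pounds happens only at
the presentation layer (half away from zero, which matches how such tables
are conventionally printed). Two-year within-trial costs are left
undiscounted — discounting belongs to the decision model.

## Outcomes

`auc_qalys()` integrates the piecewise-linear utility curve over the
horizon. For a death between follow-ups, utility is interpolated linearly
from the last pre-death observation to zero at the death time and is exactly
zero afterwards. This is deliberately stricter than only zeroing scheduled
follow-ups after death: the trial convention within an interval is not
documented, the two conventions agree at every scheduled point, and the
linear-to-zero rule makes QALYs continuous in the death time. Horizons must
lie on the follow-up grid, and missing utilities are an error that points to
imputation — integration never silently skips gaps.

Descriptive-profile valuation is pluggable: `value_set()` holds a total
lookup on the 3125 five-level profiles. Published tariff coefficients are
licensed and are not embedded; the generator emits utilities directly, and
`linear_value_set()` provides a synthetic tariff for tests and examples. The
full-health anchor (`11111 → 1`) is enforced unless explicitly disabled for
deliberately non-anchored test sets.

## Missing data

`mice_impute()` is a chained-equations imputer specialised to this analysis
frame: variables are visited in order of increasing missingness, 10 sweeps
by default, with Bayesian-draw linear models, type-1 predictive mean
matching (default for continuous variables, 5 donors — it respects the
skewness of costs and the bounds of utilities) and logistic draws for the
recurrence flag. The predictor set is the one a trial analysis would use:
treatment allocation, age, sex, contracture severity (cord count), baseline
cost and utility, trial status, plus the other imputed outcomes.
Covariate-with-missingness association screening (`missingness_screen()`)
is provided as a diagnostic report only — it does not alter the model.

Structural zeros after death are fixed: excluded from every conditional
model fit and never imputed, so deceased patients keep zero utilities and
costs in all `m` completed datasets (the recurrence flag of a patient who
died before one year is carried as a structural zero in completed data).
Downstream estimates are pooled with Rubin's rules (`rubin_pool()`), with
the conventional small-sample degrees of freedom.

Costs are imputed at the aggregated category-per-year level, not
item-by-item — imputing dozens of sparse quantity columns would be noisier
than imputing their cost totals, and nothing downstream needs the items.
Costs are imputed on their raw scale (the original analysis does not state
its choice); predictive mean matching makes this safe because imputed values
are always observed donor values.

## Within-trial estimation

`fit_sur()` estimates the two-equation system (cost and QALY each regressed
on arm, baseline cost, baseline utility) by one feasible-GLS step after
OLS. With a common regressor set, SUR coefficients equal per-equation OLS
*exactly*; this algebraic identity is used as the estimator's oracle in the
tests, while the joint residual covariance still feeds net-benefit
inference. In the noiseless limit the residual covariance is singular; the
code detects this and returns the (exact) OLS solution rather than
weighting by a degenerate matrix.

Uncertainty comes from a patient-level nonparametric bootstrap, stratified
by arm, refitting the SUR system per resample, *within* each imputed
dataset ("impute, then bootstrap": the conventional 200 resamples × 25
imputations = 5000 draws). Percentile intervals and acceptability curves
are computed on the pooled draw set. Point estimates are Rubin-pooled
per-imputation SUR estimates — identical to the mean of the per-imputation
estimates, which the tests assert.

Decision metrics:

* **NHB** is computed in QALY units, `NHB = ΔE − ΔC/λ`, the form in which
  published tables print it to three decimals; the monetary form
  `NMB = λ·ΔE − ΔC` is exposed separately. The two have identical sign.
* **ICER** carries an explicit quadrant label. In the southwest quadrant
  (cheaper, less effective — the relevant case here) a ratio *above* the
  threshold favours the cheaper treatment, so the decision rule is encoded
  per quadrant and tested exhaustively against the NHB sign.
* **CEAC** values are computed on the monetary scale (`λ·ΔE − ΔC > 0`), so
  the curve is defined at λ = 0 where it equals the probability of cost
  saving; the comparator's curve is its complement.
* **Price threshold**: the largest vial price on a grid with pooled NHB ≥ 0;
  net benefit is strictly decreasing in price, so the search is monotone,
  and a grid-wide negative result is reported as "below grid" rather than
  extrapolated.

The incremental direction is collagenase − LF throughout. The complete-case
sensitivity analysis is listwise deletion on the analysis variables; its
smaller `n` is reported on the fitted object.

## The Markov model

Nine mutually exclusive states: recovery and recurrence after the initial
correction, a transient reintervention state, recovery and recurrence after
the first reintervention, a second transient reintervention state, recovery
and recurrence after the second reintervention, and death. The cohort
enters at one year post-treatment, split by the one-year recurrence
probability; cycles are annual and the model stops at age 85.

Design choices that the published description leaves open, and how they are
resolved here:

* **One-off 40% reintervention.** "One-off" is read as: applied once at
  first entry into each recurrence tier, never re-sampled in later cycles.
  A patient who declines stays recurrent (but for death) — so the decision
  cannot be expressed as a time-homogeneous matrix on the nine public
  states. Internally each of the first two recurrence tiers is split into
  *new* and *settled* compartments; the resulting 11-compartment chain is
  genuinely Markov (and time-homogeneous under constant mortality, which is
  what the matrix-power oracle verifies at 1e-12), and occupancies collapse
  onto the nine public states for reporting.
* **Recurrence rates by phase.** The first cycle after any (re)treatment
  uses the one-year rates (13.8% / 17.2%); all later cycles use the annual
  long-term rates (5.4% / 11.8%). Recovery after the second reintervention
  carries no further recurrence risk — the treatment cascade terminates
  there, a simplification the state layout makes explicit and configurable.
* **Mortality as a competing risk.** Every non-death transition is scaled by
  `1 − q(age, sex)`; row-stochasticity is asserted at 1e-9 on construction.
  The default life table is a synthetic Gompertz-like stand-in
  (`generate_life_table()`, q doubling roughly every 9 years, women scaled
  by 0.6); any registry table with the same three columns can be supplied.
* **Rewards and calibration.** Costs/utilities are per arm in two phases.
  Cycle 1 earns the arm's intervention cost plus year-1 phase rewards;
  reintervention occupancy earns the same bundle (reintervention is assumed
  to cost the same as the initial intervention); other alive states earn
  steady-state rewards. The defaults are *calibration* values: cycle-1
  totals equal observed first-year per-arm means (£3025/0.846 vs
  £1535/0.835) and steady-state values equal discount-corrected second-year
  increments (£470/0.8715 vs £314/0.826). Published per-arm totals constrain
  but do not identify per-state rewards; the defaults are therefore not
  estimates of state-specific values, and `recurrence_utility_decrement`
  exposes the first granularity a user may want to add.
* **Discount timing.** 3.5% per year with cycle 1 undiscounted and cycle *t*
  discounted by `1.035^−(t−1)`, so the model's one-year results coincide
  with trial-observed first-year values. No half-cycle correction is applied
  by default (none is part of the emulated analysis); it would enter as a
  reward-weighting switch, not a structural change.
* **Cohort heterogeneity.** A deterministic expectation over a discrete
  age/sex grid (default: age 66, 80% male), not microsimulation — matching
  the cohort-model language and keeping every run exactly reproducible.

```{r markov}
fit <- markov_cea()
fit$comparison[, c("horizon", "delta_cost", "delta_qaly")]
```

The deterministic defaults produce the characteristic time-dependence: the
injection saves about £1490 in year one at a negligible QALY loss, but its
higher recurrence and reintervention burden erode the saving's value, and
surgery accumulates a QALY advantage that grows with the horizon.

## Probabilistic sensitivity analysis

`run_psa()` draws every uncertain parameter jointly — beta distributions for
probabilities and utilities, gamma for costs, moment-matched from (mean,
se); `se = 0` passes a parameter through deterministically — and reruns the
full two-arm model per iteration (10,000 by default). Out-of-range draws
(possible only under the optional truncated-normal family) are rejected,
redrawn and counted. The acceptability probability at a threshold is the
fraction of iterations with positive collagenase net benefit. Default prior
dispersions reflect trial-scale binomial uncertainty on the recurrence
probabilities and 5–10% coefficients of variation on rewards; they are
illustrative settings, not elicited posteriors.

## Numerical conventions and problem sizes

* Tolerances: transition rows sum to 1 within 1e-9 (asserted); cohort mass
  conservation 1e-9 per cycle; matrix-power oracle agreement 1e-12; SUR–OLS
  identity 1e-8 (two different QR paths).
* Ties and degenerate inputs: zero incremental QALYs yield a label-only
  ICER; zero-noise data short-circuit the GLS weighting to exact OLS;
  `utility_sd = 0` bypasses the censored-mean solver; a singular bootstrap
  resample is redrawn and counted.
* Seeds: every stochastic entry point takes a seed and restores the
  caller's RNG state, so package calls never perturb a session's stream;
  equal config + seed means bit-identical output, which the suite asserts
  end-to-end through the pipeline's JSON artifacts.
* Test problem sizes were chosen to exercise asymptotics while keeping the
  suite fast: calibration checks at the trial's own 336/arm; recurrence
  convergence at 5000/arm; imputation recovery at 1000/arm with 20% MCAR
  masking (m = 5); bootstrap coverage over 200 replications of 336/arm with
  499 resamples each; PSA consistency at 1000 iterations against the
  deterministic run on a configuration that is linear in the drawn rewards.

## Known limitations

* The generator's covariate margins and the category-level composition of
  costs are synthetic placeholders; only the bucket-level means are
  calibrated to published values.
* Per-state Markov rewards are calibration targets, not identified
  estimates; alternative readings of the treatment-cascade figure (e.g.
  recurrence risk after the second reintervention) are config switches, and
  results at long horizons are sensitive to them.
* No MNAR sensitivity models; no Fieller intervals for ICERs; no
  EVPI/EVPPI; no needle-fasciotomy comparator; no per-digit analysis.
* The within-trial layer treats the two-year window as undiscounted, and
  the model applies a single national discount rate — both are conventions,
  exposed as arguments.
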