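# dupcea

Within-trial and model-based cost-effectiveness analysis for treatments of
moderate Dupuytren's contracture: collagenase clostridium histolyticum
injection versus limited fasciectomy (LF) surgery.

The package is for health economists and trial statisticians who need a
complete, reproducible, *testable* implementation of the standard two-layer
evaluation design:

* a **within-trial CEA** — micro-costing (or HRG tariff costing) of
  patient-level resource use, area-under-the-curve QALYs with explicit
  death handling, multiple imputation by chained equations, seemingly
  unrelated regression (SUR) of incremental costs and QALYs, a nested
  nonparametric bootstrap (resamples within each imputation), ICERs with
  dominance labelling, net health benefit, acceptability curves and a
  vial-price threshold analysis; and
* a **lifetime 9-state Markov cohort model** — annual cycles from one year
  post-treatment to age 85, one-off 40% reintervention after recurrence (up
  to two reinterventions), age/sex background mortality as a competing
  risk, 3.5% discounting, and Monte-Carlo probabilistic sensitivity
  analysis.

Raw trial data of this kind are confidential, so the package includes a
seed-reproducible synthetic generator (`generate_trial()`) that emulates
the statistical structure the methods must handle — right-skewed costs,
left-skewed bounded utilities with arm-specific trajectories, shared
cost–utility frailty, rare deaths with structural zeros, one-year
recurrence, and covariate-driven missing-at-random masking. Every analysis
stage runs end-to-end on synthetic data with no download.

## The core quantities

With incremental cost ΔC and incremental QALYs ΔE (collagenase − LF) and a
willingness-to-pay threshold λ:

* ICER = ΔC / ΔE, labelled by cost-effectiveness-plane quadrant (in the
  southwest quadrant — cheaper and less effective — a ratio *above* λ
  favours the cheaper treatment);
* net health benefit NHB = ΔE − ΔC/λ (QALY units; `nmb()` gives the
  monetary form λ·ΔE − ΔC);
* CEAC(λ) = P(λ·ΔE − ΔC > 0) over bootstrap or PSA draws.

ΔC and ΔE come from a two-equation SUR system (cost and QALY each regressed
on arm, baseline cost and baseline utility) fitted per imputed dataset and
pooled by Rubin's rules.

## Worked example

```r
library(dupcea)

cfg <- trial_config(seed = 2026)                    # 336 patients per arm
dat <- apply_missingness(generate_trial(cfg), cfg$missingness, seed = 2027)

fit <- cea_trial(dat, mi = mi_config(m = 5, iterations = 5),
                 boot = bootstrap_config(reps_per_imputation = 100),
                 seed = 2028)
print(fit)
```

```
Within-trial cost-effectiveness analysis (micro, nhs_pss)
 n = 672 patients, 5 imputations

1-year results
  Incremental cost  -£1087 (95% CI -£1160 to -£1020)
  Incremental QALYs -0.014 (95% CI -0.026 to -0.004)
  ICER              £76672/QALY (SW-quadrant)
  NHB at £20000/QALY: 0.040;  P(cost-effective) 100.0%
  NHB at £30000/QALY: 0.022;  P(cost-effective) 100.0%

2-year results
  Incremental cost  -£1242 (95% CI -£1325 to -£1159)
  Incremental QALYs -0.056 (95% CI -0.079 to -0.032)
  ICER              £22218/QALY (SW-quadrant)
  NHB at £20000/QALY: 0.006;  P(cost-effective) 71.2%
  NHB at £30000/QALY: -0.014;  P(cost-effective) 14.0%
```

Reading it: on this synthetic cohort the injection saves about £1090 per
patient in year one while losing a statistically uncertain sliver of QALYs,
so it is almost certainly cost-effective at conventional thresholds (NHB >
0, acceptability ≈ 100%). By two years the surgical arm has accumulated a
real QALY advantage; the saving still exists but buys less health, the ICER
(£22,218/QALY saved) sits inside the £20,000–£30,000 threshold band, and
the decision flips with λ — acceptability 71% at £20,000 but 14% at
£30,000. Cost-effectiveness is horizon- and threshold-dependent.

The lifetime decision model continues the story beyond the trial window:

```r
m <- markov_cea()
print(m)
```

```
Lifetime Markov cohort model (9 states, annual cycles, 3.5% discount, stop at age 85)
  1        LF £3025 / 0.846 QALY;  collagenase £1535 / 0.835 QALY;  dC -£1490, dE -0.011
  2        LF £3605 / 1.671 QALY;  collagenase £1913 / 1.619 QALY;  dC -£1692, dE -0.052
  3        LF £4069 / 2.454 QALY;  collagenase £2237 / 2.361 QALY;  dC -£1832, dE -0.092
  4        LF £4513 / 3.193 QALY;  collagenase £2545 / 3.063 QALY;  dC -£1969, dE -0.130
  lifetime LF £8431 / 9.895 QALY;  collagenase £5183 / 9.419 QALY;  dC -£3249, dE -0.476
```

The injection's higher recurrence and reintervention burden erodes its
early advantage: by the fourth year the incremental QALY loss outweighs the
saving at conventional thresholds, and over a lifetime surgery is the
cost-effective option. `run_psa()` wraps the same model in a Monte-Carlo
PSA; `run_pipeline()` orchestrates the whole sequence (simulate → mask →
impute → CEA per scenario → model → PSA) into stamped, reloadable tables.

Scenario machinery mirrors the usual sensitivity analyses:
`costing_scenario(method = "hrg")`, `collagenase_setting = "theatre"`,
`lf_staff = "trainee"`, `perspective = "societal"`, and a
`collagenase_vial_price` override used by `price_threshold()`.

See the methods vignette (`vignettes/economic-evaluation.Rmd`) for the
model assumptions, parameter meanings and defaults, numerical conventions,
and known limitations.

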