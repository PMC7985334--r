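---
title: "Methods: time-varying change-point AR modelling of wearable stress series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying change-point AR modelling of wearable stress series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvcpar)
```

## The model and its assumptions

The quantity of interest is the *inertia* of a digitally assessed stress
level: the lag-1 autoregressive coefficient of a series sampled every 3
minutes by a wrist-worn tracker. A constant-coefficient AR(1) assumes
stationarity, which is exactly what process research wants to interrogate —
inertia may drift slowly (e.g. across days of treatment) and may also shift
abruptly when dynamics reorganize. The TVCP-AR model accommodates both:

* **Gradual change.** `y_t = f0(t) + f1(t) y_{t-1} + e_t` with `f0`, `f1`
  penalized cubic regression splines of the epoch index (a
  varying-coefficient model in the generalized additive framework, fitted
  with `mgcv::gam`). Errors are Gaussian, i.i.d. given the lagged value.
* **Abrupt change.** A change point at epoch `c` augments the gradual model
  with constant shifts `d0`, `d1` in intercept *and* AR coefficient for
  `t >= c`. Regimes between accepted change points are refitted
  independently, so the final inertia curve is smooth within regimes with
  jump discontinuities at change points.

Assumptions worth keeping in mind: AR order 1 only; Gaussian residuals on a
bounded, integer-valued observable (reasonable mid-scale, coarser near 0 and
100); and missingness that is ignorable given the observed past. Lag pairs
are formed only from grid-adjacent observed epochs — a pair spanning any
missing epoch is dropped rather than bridged or imputed, because imputation
would manufacture precisely the autocorrelation being estimated.

## Model comparison and the change-point search

Both models are scored in one currency:
`AIC = -2 loglik + 2 edf`, with the Gaussian log-likelihood evaluated at the
MLE variance `RSS/n` and `edf` the trace of the penalized fit's influence
matrix. (`mgcv`'s own `logLik` bookkeeping differs slightly; using one
explicit definition for both models keeps differences interpretable.) The
decision statistic is `dAIC(c) = AIC(cp model at c) - AIC(gradual model)`;
negative values favour the change point, and a candidate is accepted when
`dAIC < threshold` with threshold −15 by default — intentionally far beyond
the conventional "2 units" so that scanning thousands of correlated
candidates does not flood the analysis with false positives. Simulations
under the null (see below) confirm the family-wise false-positive rate is
controlled well under 10% at this threshold.

Because the true location is unknown, the search is exploratory and, by
default, exhaustive: every epoch whose left and right parts would both
retain at least `min_segment` usable lag pairs, and which keeps
`boundary_margin` epochs of distance from the window edges, is evaluated
(`candidate_stride > 1` trades exhaustiveness for speed and is validated
against the exhaustive result in the tests). Detection is recursive binary
segmentation: accept the best sub-threshold candidate, split, and search
both sections again, to `max_depth`.

Two numerical choices make the exhaustive scan cheap. First, candidate
models condition on the gradual model's smoothing parameters instead of
re-selecting smoothness per candidate; the augmented model is then a
penalized least-squares problem. Second, all candidates share the gradual
design matrix and differ only in two step columns, so the needed
cross-products are suffix sums updated incrementally and each candidate
costs two small Schur-complement solves. `fit_cp_ar()`/`delta_aic()` solve
the augmented system directly and independently of that incremental path;
the test suite requires the two to agree to 1e-6, and the nesting invariant
(the change-point model can lose at most its two extra effective parameters)
to hold.

## Pruning

Change points too close together delimit regimes with too few measurements
for robust estimates — a regime cannot hold fewer than `min_segment` pairs,
let alone a single measurement — and shifts near the boundaries cannot be
estimated reliably. Pruning is greedy by evidence: candidates are processed
in ascending `dAIC` (most negative first) and accepted only if at least
`min_gap` epochs from every already-accepted change point and
`boundary_margin` epochs from the series ends; the rest are recorded with an
exclusion reason (`too_close`, `boundary`). Greedy-by-evidence is a
deliberate, reproducible tie-break; a recursion-order-dependent rule could
retain a weaker member of a cluster, and we prefer the defensible rule and
an explicit exclusion ledger.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold` | −15 | AIC units | conservative acceptance; controls false positives under multiplicity |
| `min_segment` | 50 | lag pairs | ≈ 5 × basis dimension, enough for a stable smooth per regime |
| `min_gap` | 50 | epochs | = `min_segment`; twin constraint on regime size |
| `boundary_margin` | 50 | epochs | changes at edges are unidentifiable |
| `candidate_stride` | 1 | epochs | exhaustive search by default |
| `basis_dim` | 10 | basis functions | day-scale flexibility over a 2-week window without chasing noise |
| `max_depth` | 12 | levels | 2^12 potential regimes far exceeds anything plausible at n = 6720 |
| `smoothing` | penalized ML | — | stable smoothness selection; GCV available |

All are exposed via `detector_config()`.

## What the synthetic generator emulates — and what it does not

`simulate_stress_series()` generates the structure the analysis assumes: a
regular 3-minute grid (6,720 epochs over 14 days), piecewise time-varying
AR(1) dynamics with sinusoidal within-regime drift (period one day by
default) and step jumps at regime boundaries, observations clipped to
[0, 100] and rounded to integers (device granularity), and three missingness
mechanisms — i.i.d. insufficient-data epochs (default probability 0.05),
episodic activity blocks (2 per day, mean 10 epochs = 30 min, geometric
lengths; exercise is episodic, so blocks, not i.i.d. dropout), and silently
absent rows (probability 0.02). The latent state evolves unclipped so
parameter-recovery targets stay analytically clean. Defaults were fixed
once: noise SD 8 stress units gives within-regime marginal SDs near 10 — a
visually plausible wearable stress trace — and jump sizes in the cohort
generator (AR 0.35 vs 0.7, level ±8) make detection non-trivial rather than
saturated.

What it deliberately does *not* emulate: circadian structure in the HRV
signal itself, posture/recovery artefacts, the device's proprietary stress
algorithm, or any dependence of missingness on the stress level
(missingness is ignorable by construction). Passing tests therefore show
that the estimator recovers the dynamics it models, under missingness of
the kind it assumes — not that real tracker data satisfy those assumptions.

`simulate_cohort()` links outcomes to dynamics: session-15 questionnaire
scores are the instrument's baseline mean plus a common slope per true
change point (scaled to each instrument's range, normalized to GAD-7's
21-point scale) plus noise, with a negative slope encoding "less change in
stress dynamics, more symptoms". Synthetic scores are continuous within the
instrument ranges so that the noiseless case is an exact linear map.

## Outcome statistics

Correlations use listwise complete cases per instrument — patients with both
the pre-treatment and session-15 score and a change-point count — and the
*same* subset is used at both occasions, so the two columns of the report
describe the same people (with the bundled seven-patient table, six complete
cases; recomputation matches the printed pre-treatment correlations only
under this rule). Partial correlations at session 15 adjust for the same
instrument's pre score via the first-order formula, which the tests pin to
the residual-on-residual oracle at 1e-10. SDs use the n−1 denominator.
Significance stars are two-sided t tests (df = n − 2) without multiplicity
correction — descriptive flags, not confirmatory inference, at n = 6. The
per-patient stress-level correlate is the mean of observed stress values
over the analyzed window; with cohort sizes this small it is reported but
carries no test targets. One ingestion caveat: published per-patient tables
can print a sum one point above an instrument's nominal maximum (a GAD-7 of
22 occurs in the bundled table), so range validation warns rather than
rejects.

## Degenerate inputs and numerical details

* Constant series (zero variance): no change points, degenerate-fit warning.
* Constant lagged values: the gradual fit falls back to an intercept-only
  smooth with a warning (`f1 = 0`).
* A candidate whose step columns are numerically collinear with the smooth
  basis is skipped (Cholesky failure), not force-fitted.
* Inertia estimates above 1 — locally explosive, typically near change
  points — are flagged, never clamped.
* Wear-time suitability is strict: a series worn exactly 50% of the time is
  not analyzed. Epochs coded −1/−2 count as worn (the device was on).
* The basis dimension is reduced automatically when a short segment has too
  few distinct epochs to support it.

## Problem sizes used in the checks

The simulation studies shipped with the package use series of 2,000 epochs
(null false-positive study, 100 replicates), 6,000 epochs with a shift at
midpoint (power and localization, 50 replicates), and 2,000–4,000 epochs for
parameter recovery — sizes at which spline AR estimation is stable and the
whole suite runs in minutes on one CPU. Grid arithmetic and the correlation
table are exact checks.

## Known limitations

* AR(1) only; no higher-order or multivariate dynamics.
* The AIC threshold −15 is calibrated for this scan procedure and this AIC
  definition; other edf conventions would shift the scale somewhat.
* The search conditions on the gradual model's smoothing parameters; if a
  shift is so large that it corrupts the gradual fit's smoothness selection,
  the recursion (which refits per window) compensates, but a single-pass
  `delta_aic` at a far-off epoch inherits that smoothing.
* Localization near boundaries is impossible by design (`boundary_margin`),
  so shifts in the first/last ~2.5 hours of a window are not detectable.
* Small-cohort correlations are descriptive; six patients cannot support
  inference beyond flagging.
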