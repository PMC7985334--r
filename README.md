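# tvcpar

Time-varying change-point autoregressive (TVCP-AR) modelling of wearable
stress series.

## The problem

Wrist-worn fitness trackers derive a stress index in [0, 100] from heart-rate
variability every 3 minutes — up to 6,720 measurements over a two-week
ecological momentary assessment (EMA) window. A clinically interesting
summary of such a series is its *inertia*: the lag-1 autoregressive
coefficient, i.e. how strongly the current stress level carries over from the
previous epoch. Inertia need not be constant: it can drift gradually over
days, and it can shift abruptly when a person's dynamics reorganize. Both
kinds of change are informative for psychotherapy process research, where
the number of abrupt shifts in physiological stress dynamics can be related
to self-reported symptom outcomes.

`tvcpar` provides the full chain: parsing and quality control of device
exports (with the -1 insufficient-data and -2 activity missing codes),
TVCP-AR estimation, change-point detection, a synthetic-data generator with
known ground truth, and outcome correlation.

## The model

The gradual model is a varying-coefficient AR(1), fitted to usable lag pairs
(consecutive observed epochs) by penalized cubic regression splines (mgcv):

    y_t = f0(t) + f1(t) * y_{t-1} + e_t,   e_t ~ N(0, sigma^2)

`f1(t)` is the time-varying inertia. A candidate change point at epoch `c`
adds constant regime shifts in both parameters:

    y_t = f0(t) + d0 * I(t >= c) + [f1(t) + d1 * I(t >= c)] * y_{t-1} + e_t

Both models are scored with AIC = -2 loglik + 2 edf (Gaussian likelihood at
the MLE variance; edf = trace of the penalized fit's influence matrix). The
AIC difference

    dAIC(c) = AIC(change-point model) - AIC(gradual model)

is computed at every admissible candidate epoch (an exploratory, exhaustive
search); the best candidate is accepted when `dAIC < -15`, a deliberately
conservative threshold against false positives. The series is then split at
the accepted change point and both sections are searched again, recursively.
Finally, change points too close to each other (regimes would be too small
for robust estimates) or too close to the series boundaries are pruned,
greedily keeping the strongest evidence. Each resulting regime gets an
independent gradual fit, yielding an inertia curve that varies smoothly
within regimes and jumps at change points.

## Worked example

Simulate two weeks of 3-minute stress data whose inertia jumps from 0.3 to
0.8 at epoch 3000, then detect the shift:

```r
library(tvcpar)
regs <- list(regime_spec(0, 40 * 0.7, 0.3),      # stationary mean 40, phi 0.3
             regime_spec(3000, 40 * 0.2, 0.8))   # stationary mean 40, phi 0.8
sim <- simulate_stress_series(regs, n_days = 12.5, noise_sd = 8, seed = 42)
cpset <- detect_change_points(sim$series)
cpset
#> <changepoint_set> patient sim: 1 accepted CP(s), 0 excluded, 2 regime(s)
#>  epoch               timestamp delta_aic
#>   2997 2020-01-12 05:51:00 UTC -43.04671
```

The detector locates the shift within 3 epochs (9 minutes) of the truth, and
the AIC difference of -43 is far below the -15 acceptance threshold. The
final per-regime inertia means recover the generating coefficients:

```r
fin <- final_inertia_model(sim$series, cpset)
round(tapply(inertia_curve(fin)$f1, inertia_curve(fin)$regime_id, mean), 2)
#>    1    2
#> 0.31 0.79
```

Relating change-point counts to questionnaire outcomes, using the bundled
seven-patient cohort table (six complete cases):

```r
om <- read_outcomes(example_outcomes_path())
correlation_table(om)
#> <correlation_report> change-point count vs outcomes (complete cases)
#>  instrument n   pre M (SD) r pre   s15 M (SD)  r s15 r partial
#>      hscl11 6  2.29 (0.53) -0.24  2.07 (0.44)  -0.18      0.08
#>        oq30 6  1.99 (0.45) -0.48  1.87 (0.37)  -0.19      0.24
#>        gad7 6 12.33 (3.27) -0.62 12.83 (5.95) -0.84*     -0.97
#>        phq9 6 14.17 (4.83) -0.58 16.00 (4.86)  -0.76     -0.64
#> * p < 0.05 (two-sided, uncorrected)
```

Fewer abrupt shifts in stress dynamics (higher inertia) go with more
self-reported symptoms; the association is strongest for anxiety (GAD-7),
and remains after adjusting for pre-treatment severity (partial r). The
whole chain — simulate, write/parse CSVs, wear-time QC, detection,
correlation, plots — is orchestrated by `run_pipeline()`.

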