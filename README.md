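# geovalid

Validity analysis of GPS-derived mobility measures in R.

`geovalid` implements a complete measurement-validation chain for the
*Number of Places Visited* (NPV), a behavioural outcome used in digital
phenotyping: raw 1 Hz GPS fix streams are reduced to stops (stay points),
stops are promoted to counted place visits by explicit classification
rules, and the resulting GPS NPV is validated against self-report
measures of the same construct — convergently (method-pair correlations)
and nomologically (does NPV relate to lifestyle constructs the way theory
predicts?). A fully seeded synthetic-data generator emulates every input
with known ground truth, so the whole chain is testable end to end.

## What it computes

**Stop detection.** A stop is a maximal episode of at least `min_dwell_s`
seconds (default 600 s) during which every fix lies within `eps_m`
(default 50 m) of the window's running centroid. Because the tracker
records only while moving, a recording gap bounded by near-identical
positions counts toward dwell. Fixes faster than 75 mph that also turn
more than 90° off the previous heading are screened out as anomalies
before the sweep.

**Place classification.** Consecutive stops with centroids ≤ 30 m apart
merge as one visit to an identical location; within 75 m, as one visit to
the same building; a short stop (≤ 15 min) whose inbound and outbound
travel bearings agree within 30° is dropped as an in-transit pause.
Revisits at different times count separately — NPV counts visit events,
not unique places. Counted visits aggregate by local arrival day into
weekday (2 days), weekend (2 days) and 4-day totals.

**Psychometrics.** Unit-weighted Active-Lifestyle (AL) and
Sedentary-Lifestyle (SL) factor scores: z-score the questionnaire totals
(PA, Mini-K, C, E, A for AL; BDI, CES-D, NA, SWL reversed, N for SL) and
average them. Cronbach's alpha and factor–indicator correlation tables
support the measurement model.

**Validity models.** Pairwise-complete Pearson panels with Fisher-z CIs;
a split-plot GLM with sequential (Type-I) sums of squares over the term
order

```
NPV = AL + SL + AL×SL + SID + Time + C2 + C1 + Time×C2 + Time×C1
      + Time×AL + Time×SL + Time×AL×SL + AL×C2 + SL×C2 + AL×SL×C2
      + AL×C1 + SL×C1 + AL×SL×C1 + Time×SID + C2×SID + C1×SID
```

where SID is the subject block factor, Time codes weekday/weekend as
−½/+½ and C1 = (Diary +1, Google −1, GPS 0), C2 = (Diary +½, Google +½,
GPS −1) are planned orthogonal method contrasts. Each term is tested
against its own error stratum (between-subjects terms against SID, Time
terms against Time×SID, each contrast family against its contrast×SID
interaction, the rest against the residual), with semi-partial R²
(SS / corrected total SS) and partial R² (semi-partial / stratum total)
effect sizes. The model is fit in both AL-first and SL-first orders —
sequential SS are order-dependent for correlated predictors, and the
joint SS and model R² are provably order-invariant. A final OLS of NPV on
AL and Time refines the unstandardized estimates.

## Worked example

Simulate a 96-subject study (2 weekday + 2 weekend days, three NPV
methods), then run the validity analyses:

```r
library(geovalid)

st <- simulate_study(sim_config(), seed = 42)

correlation_panel(st$reports, "total4day")
#>   period    method_a method_b     r        p     n ci_lo ci_hi
#> 1 total4day Diary    GPS      0.832 7.86e-26    96 0.758 0.885
#> 2 total4day Diary    Google   0.671 7.67e-14    96 0.543 0.768
#> 3 total4day GPS      Google   0.799 1.92e-22    96 0.712 0.861

fits <- fit_both_orders(st$long)
tidy(fits$al_first)[c(1, 2, 4, 5), ]
#>   term  type    ndf   ddf      f        p semi_partial_r2 partial_r2
#> 1 AL    BS        1    92 25.1   2.63e- 6        0.104       0.214
#> 2 SL    BS        1    92  0.119 7.31e- 1        0.000493    0.00101
#> 3 SID   BS       92   190  6.30  6.84e-27        0.382       0.784
#> 4 Time  WS        1    92 91.1   2.07e-15        0.143       0.368

glance(fits$al_first)[, 1:4]
#>   r_squared bs_r_squared ws_r_squared error_r_squared
#> 1     0.875        0.487        0.388           0.125

final_parameter_fit(st$long)
#>   term      estimate std_error
#> 1 Intercept    12.2      0.208
#> 2 AL            2.45     0.275
#> 3 Time         -4.33     0.415
```

Read: the three methods agree strongly on this synthetic cohort
(r = 0.67–0.83); AL predicts NPV (F(1, 92) = 25.1) while SL adds nothing
once AL is in the model; people visit about 4 fewer places per weekend
period than per weekday period (the `Time` estimate, weekend − weekday);
and the AL slope on the *estimated* factor score (2.45) exceeds the
generating latent slope because unit-weighted scores are attenuated
measurements of the latent — see the methods vignette.

GPS measurement itself runs through the same functions on fix tables:

```r
stgps <- simulate_study(
  sim_config(n_subjects = 6, render_gps = TRUE,
             gps = list(noise_sd_m = 10)),
  seed = 42
)
extract_npv(stgps$trajectories[["S001"]], stgps$config$calendar)$npv
#>   subject_id method period      npv
#> 1 S001       GPS    weekday      16
#> 2 S001       GPS    weekend      12
#> 3 S001       GPS    total4day    28
```

`read_fix_table()` / `read_gpx()` ingest real device exports through a
column-map dialect; `write_activity_report()` emits the per-stop audit
CSV; `run_pipeline()` chains everything from a single YAML config with a
reproducibility manifest.

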