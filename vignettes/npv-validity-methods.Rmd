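---
title: "Measuring and validating the Number of Places Visited: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and validating the Number of Places Visited: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model behind the Number of Places Visited (NPV), the statistical models
used to validate it, the synthetic-data generator that stands in for raw
participant data, and the numerical and design choices a maintainer
should know about.

## The measurement problem

Self-reported activity is cheap but fallible; a GPS tracker carried on
the person records where its bearer actually went. NPV — how many place
visits a person makes over a stated window, with revisits counted
separately — is a simple behavioural summary that all three measurement
methods considered here can produce: an end-of-day diary, a map-based
reconstruction of each day's movements, and the tracker itself. The
validation questions are the classical ones: do the three methods agree
(convergent validity), and does NPV relate to other constructs —
active-lifestyle (AL) and sedentary-lifestyle (SL) dispositions — the way
theory predicts (nomological validity)?

## From fixes to stops

A consumer tracker emits a fix about once a second *while moving*:
timestamp, latitude/longitude, speed, heading. `detect_stops()` reduces a
fix stream to stops with a stay-point sweep: grow a window while each new
fix lies within `eps_m` of the window's running centroid; emit a stop
when the window's elapsed time reaches `min_dwell_s`.

Parameters, defaults and reasons:

* `min_dwell_s = 600` s. Ten minutes is the dwell threshold that defines
  a stop; a dwell of exactly ten minutes counts (`>=`, not `>`).
* `eps_m = 50` m. "No detectable change in location" has to be given a
  radius; 50 m covers consumer-GPS scatter without swallowing adjacent
  buildings. The sweep checks each new fix against the *running*
  centroid and does not re-test earlier members as the centroid drifts;
  with a 50 m radius and places hundreds of metres apart the drift is
  centimetres in practice.
* `gap_dwell_eps_m = eps_m`, `gap_s = 10` s. Because recording is
  motion-triggered, silence is evidence of stillness: a gap whose
  bounding fixes are within `gap_dwell_eps_m` counts toward dwell
  (`gap_inferred` is set); a gap with a larger displacement breaks the
  window — the device was off or indoors while its bearer moved.
* `max_speed_mph = 75`, `turn_deg = 90`. A fix is anomalous only when it
  is impossibly fast (recorded or implied speed) *and* heads off in an
  apparently random direction (circular heading change above `turn_deg`).
  Fast fixes on a steady bearing are highway driving and are kept.
  Heading differences are circular (359° vs 1° differs by 2°). Flagged
  fixes are excluded before the sweep; a stop whose in-window flagged
  fixes outnumber its members inherits `anomalous = TRUE` and
  `remove_anomalous_stops()` drops it.

Distances are haversine on a 6,371,000 m sphere; the sub-0.5 %
sphere-vs-ellipsoid error is irrelevant at stop scale. Timestamps are
stored UTC and every calendar decision goes through the trajectory's IANA
timezone.

## From stops to counted visits

The original protocol promoted stops to places by manual map inspection.
`classify_stops()` replaces the human with auditable proxies, each stop
receiving exactly one `rule_applied` label:

* consecutive stops with centroids within `merge_identical_m = 30` m are
  one visit to an identical location;
* within `merge_building_m = 75` m, one visit to the same building or
  parcel (a distance proxy for "same estimated address / same yard" —
  parcel data would be needed to do better, and the audit label records
  that the proxy fired);
* a stop of at most `transit_max_dwell_s = 900` s whose inbound and
  outbound travel bearings agree within `transit_bearing_deg = 30°` is a
  pause in transit (a red light, a bus stop), not a place;
* everything else is counted. Non-consecutive returns to the same
  coordinates count again: NPV counts visit events.

Visits are credited to the local day of *arrival* (the protocol never
defines midnight-spanning stops; arrival-day is deterministic and is
applied consistently to both the pipeline and the generator's ground
truth). Saturday and Sunday are the weekend. `aggregate_npv()` sums
counted visits over a declared 2-weekday + 2-weekend calendar; days
outside the calendar (partial first/last days) are ignored, and
weekday + weekend = 4-day total holds by construction and is asserted on
every call.

## Factor scores

`score_factors()` builds unit-weighted composites: z-score each
questionnaire total over the analysis sample (denominator n − 1,
recomputed after any row filtering — no external norms), negate the
reverse-scored set (SWL, whose satisfaction scale runs against the SL
construct), and average what is available. A score requires at least
`min_present = 3` of 5 indicators; otherwise it is missing. Openness is
accepted in indicator tables but excluded from AL. `cronbach_alpha()`
implements the standard k/(k−1) · (1 − Σ item variances / total
variance) form for reliability reporting.

Unit-weighted scores are *attenuated* measurements of the latent
constructs: with the default loadings the score–latent correlation is
about 0.92, so a regression of NPV on the estimated score recovers an
inflated per-score-unit slope relative to the latent slope. Parameter
*recovery* experiments therefore fit on the generator's latent AL/SL;
analyses of "observed" data fit on the scores, as a real study must.

## The split-plot engine

Each subject contributes up to six NPV values: 2 periods × 3 methods.
Between-subjects variance (AL, SL, AL×SL, then the subject factor SID) is
partitioned before within-subjects variance (Time; the planned method
contrasts C1 = Diary vs Google and C2 = self-report mean vs GPS; their
theoretically motivated interactions; and the subject-interaction error
terms). Sums of squares are sequential (Type I): `sequential_anova()`
orthonormalizes each term's model-matrix block against the accumulated
basis (two-pass Gram–Schmidt against an intercept-seeded basis, then a
QR; columns whose residual norm falls below 1e-8 of their original norm
are rank-deficient and contribute no degrees of freedom), so NDF is the
realized column-rank increment on the possibly unbalanced design, and SS
conservation (terms + residual = corrected total) holds to machine
precision.

F ratios use stratum-specific denominators: {AL, SL, AL×SL} over SID;
SID over the residual; {Time, Time×AL, Time×SL, Time×AL×SL} over
Time×SID; each contrast family over its contrast×SID stratum;
{Time×C1, Time×C2} and the three error terms over the residual. A
stratum with no degrees of freedom raises an error naming it rather than
returning nonsense. Effect sizes: semi-partial R² = SS / corrected total
SS; partial R² = semi-partial / (its BS or WS stratum's semi-partial
total); model R² = BS total + WS total.

Design choices worth stating:

* **Time coding −½/+½** (weekday/weekend): the intercept of the final
  NPV ~ AL + Time regression is then the grand per-period mean and the
  Time coefficient the weekend-minus-weekday difference; a 0/1 coding
  would estimate neither directly. Configurable.
* **Contrast scaling** (+1, −1, 0) and (+½, +½, −1): F tests are
  scale-invariant; only parameter interpretation changes.
* **Both term orders are always available** (`fit_both_orders()`):
  sequential SS are order-dependent for correlated predictors, which is
  the point — neither construct gets causal priority by accident. The
  joint {AL, SL, AL×SL} SS and the model R² are algebraically
  order-invariant and are asserted so in the tests.
* **SID as a fixed block factor** (not subject-mean centering, not a
  REML mixed model): this reproduces the expected-mean-squares-style
  strata and realized degrees of freedom of the published analysis
  style. No Satterthwaite/Kenward–Roger approximations, by scope.
* **Missing data**: the GLM drops incomplete rows listwise; correlation
  panels use pairwise deletion with per-cell n; nothing is imputed.
  `missingness_screen()` reports completion rates and
  covariate-association tests (Welch t / chi-squared) and deliberately
  stops there.
* **CI for r**: Fisher z, atanh(r) ± z·(n−3)^(−1/2). No published
  alternative was specified; `cor.test` serves as the oracle in tests.
* p-values are two-sided; no multiplicity correction is applied.

## The synthetic-data generator

`simulate_study()` generates everything the pipeline consumes under one
seed, with ground truth retained:

* **Latents**: standard bivariate normal AL/SL, correlation −0.30.
* **Indicators**: z = λ·latent + √(1−λ²)·noise, rescaled to declared
  means/SDs and clipped to the possible score ranges
  (`indicator_metadata()`). Clipping censors boundary-adjacent scales —
  about 19 % of the BDI's Gaussian mass sits below its floor, which
  compresses its SD by roughly a sixth and attenuates composite–latent
  correlations to ≈ 0.90–0.94. The tests check moments against a
  closed-form censored-normal oracle rather than pretending the clip
  away.
* **True NPV**: per period, μ = 11.87 + 1.79·AL + 0·SL − 3.68·Time +
  subject effect (SD 3), realized as max(0, round(μ + N(0, 2)))
  (Poisson optional). The zero floor slightly inflates weekend means
  (≈ +0.07 at the defaults), a truncation artefact visible in
  recovery experiments as a small positive bias on the Time estimate.
* **Itineraries**: a pool of 40 places on a 1.5 km ring around a home
  location, spacing well above `merge_building_m` so true NPV is
  identifiable; dwells of 20 min + jitter (twice the stop threshold);
  travel at 25 mph; each day's visits drawn without consecutive
  repeats, overnighting at the day's last place so a consecutive-merge
  can never eat a true visit. The calendar defaults to Thursday–Sunday
  2010-11-04..07 in America/Phoenix (no daylight-saving edge cases).
* **Trajectories**: 1 Hz fixes along travel legs with recorded speed and
  bearing; dwells emit boundary fixes only when motion-triggered
  dropout is on (the default), otherwise dense jittered fixes; Gaussian
  positional noise `noise_sd_m`; `inject_anomalies()` inserts teleports
  10–20 km off-course (bearing turned 100–180°) after interior travel
  fixes, which the speed-plus-random-direction screen flags
  deterministically.
* **Self-reports**: binomial recall thinning (each true visit recalled
  with p) plus Poisson false reports plus an additive rounded-Gaussian
  reporting error, floored at zero. The *defaults* are p = 1, no false
  reports, noise SD 4: a mean-preserving error model, consistent with
  the absence of method mean differences that the validity analysis
  assumes; thinning with p < 1 would bias method means and is exercised
  explicitly in the recall-noise experiments.
* **Missingness**: MCAR deletion of whole subject × task cells, with
  the 0/1 completion matrix emitted for the screen.

What the generator does **not** emulate: road networks and realistic
routing, circadian variation in activity, unique-place (as opposed to
visit-event) counting, informative (MNAR) missingness, device-specific
binary formats, or the skewed empirical distributions of clinical scales
(a censored Gaussian is not a BDI). Passing recovery tests on this
generator therefore shows the *pipeline* is correct and calibrated under
its stated assumptions, not that any particular real cohort satisfies
them.

## Problem sizes and calibration choices

The validation experiments use: 50 rendered subjects per noise condition
for end-to-end recovery; 20 subjects for anomaly invariance; 200 random
small instances (5–6 subjects) against a nested-refit `lm()` oracle; 200
replicate studies of n = 96 for coefficient recovery (three Monte-Carlo
SEs as the agreement band, wide enough to contain the known truncation
bias); and 1000 replicates for the type-I calibration of the null SL
term, because resolving a [0.03, 0.07] acceptance band needs a binomial
standard error well under 0.01. Degenerate random instances whose
missingness empties an error stratum are redrawn — the oracle-equivalence
property concerns estimable models.

## Known limitations

* The in-transit and same-building rules are geometric proxies for human
  map inspection; their thresholds are declared, configurable and
  audited, but they are not ground truth.
* The stay-point sweep is greedy and windowed; it does not smooth
  (no Kalman filter, no map matching) and a pathological fix stream
  could in principle produce a window whose final radius slightly
  exceeds `eps_m`.
* Sequential SS answer order-dependent questions by design; anyone
  wanting order-free attribution should fit both orders and report
  both, which is what `fit_both_orders()` is for.
* The engine's F tests assume homoscedastic Gaussian errors within each
  stratum; counts are neither, and the calibration experiments quantify
  how little that matters at the study's scale rather than assuming it.
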