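# gaitscore

Instrumental orthopaedic outcome scores from 3D gait analysis.

After hip or knee arthroplasty, clinical outcome is routinely quantified with
the **Harris Hip Score (HHS)** and the **Knee Society knee score (KSS-ks)**,
both 0–100 point scales obtained by questionnaire and physical examination.
`gaitscore` computes *instrumental* versions of these scores from an
instrumented gait recording instead: it extracts a 744-feature description of
a patient's representative gait cycle and evaluates published linear
regression models of the form

```
score = c + Σ βᵢ · featureᵢ + pain
```

where `pain` is the patient-reported pain item of the respective clinical
score, entering as a fixed offset (coefficient 1). The packaged HHS model has
6 gait-feature predictors (intercept 25.786); the KSS-ks model has 4
(intercept 39.680). Most predictors are **normalised angular velocities
(NAVs)** — the slope of a joint angle against gait-cycle progress in °/%,
computed as the analytic derivative of a degree-5 interpolating B-spline of
the angle over the 0–100 % cycle.

The feature taxonomy, per body side (affected / contralateral):

| block | count | content |
|---|---|---|
| `std.*` | 14 | gait speed, cadence, stride/step/stance/swing/support times, support durations, step/stride length, step width, limp index |
| `phase.*` | 16 | start and duration of stance, swing and the seven Perry phases |
| `mc.*` | 342 | 19 physiological angles × {angle, NAV} × {stance, swing, cycle} × {min, median, max} |

372 features per side, **744 per subject**, named by a fixed grammar such as
`affected.mc.knee_flexion_extension.nav.stance.max`.

The package also ships the model-*building* pipeline used to derive such
scores on new cohorts — hierarchical stepwise regression (stages of
descending clinical relevance, `p_enter = 0.05`, `p_remove = 0.10`), a
cases-per-predictor cap, seeded 70/30 train/test splits, tenfold
cross-validation and regression diagnostics — plus a synthetic gait simulator
for end-to-end and parameter-recovery testing. See the methods vignette
(`vignettes/instrumental-gait-scores.Rmd`) for the science and the design
choices.

## Worked example

```r
library(gaitscore)

# a synthetic post-arthroplasty patient: moderate severity, asymmetric gait,
# pain item 30/44, sampled at 100 Hz over 5 gait cycles
trial <- generate_trial(
  pathology = pathology_params(severity = 0.5, asymmetry = 0.6),
  pain_subscore = 30, seed = 42)
trial
#> <gait_trial> subject synthetic | affected: left | target: HHS
#>   38 angle trajectories, 24 events, span 0.00-6.35 s

fv <- extract_features(trial)   # segment -> representative cycle -> 744 features
dplyr::filter(fv, grepl("std.gait_speed|std.limp_index|phase.stance.duration",
                        feature))[1:3, ]
#>   feature                         value
#> 1 affected.phase.stance.duration 58.8
#> 2 affected.std.gait_speed         3.09
#> 3 affected.std.limp_index         0.966

hhs <- score(fv, packaged_models()$HHS)
hhs
#> <instrumental_score> HHS = 56.12 points (raw 56.12)
tidy(hhs)
#> # A tibble: 8 x 4  -- per-term contributions summing to the raw score
#> 1 (intercept)                                        ...  25.8
#> 2 affected.mc.hip_flexion_extension.nav.swing.median ...   0.0564
#> ...
#> 8 pain                                               ...  30
```

The impaired gait is visible in the features (stance 58.8 % instead of 60 %,
limp index 0.97, speed 3.1 km/h instead of 4.1) and the instrumental HHS of
56 points sits in the "poor-to-fair" range, dominated by the intercept, the
pain item and small NAV contributions.

Deriving a new instrumental score from a cohort feature table:

```r
cohort <- generate_cohort(cohort_spec(
  n = 60, coefficients = c(affected.std.gait_speed = 5), intercept = 20,
  target_r2 = 0.9, seed = 7))
y   <- cohort$scores - cohort$pains          # pain is a fixed offset
sp  <- split_train_test(seq_len(60), 0.7, seed = 7)
fit <- hierarchical_stepwise(cohort$features[sp$train, -1], y[sp$train],
                             stage_grouping("HHS"),
                             max_predictors = max_predictors(length(sp$train)))
glance(fit); tidy(fit)
kfold_cv(cohort$features[, -1], y, fit$selected, k = 10, seed = 7)
diagnostics(fit)
model <- as_scoring_model(fit, "HHS", pain_item_max = 44)
```

A thin command-line front end (`inst/scripts/gaitscore`) wraps the same
functions: `gaitscore extract | score | simulate | train`.

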