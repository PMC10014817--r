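---
title: "Instrumental orthopaedic scores from 3D gait analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrumental orthopaedic scores from 3D gait analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clinical outcome scores after hip or knee arthroplasty — the Harris Hip
Score (HHS) and the Knee Society knee score (KSS-ks), both on a 0–100 point
scale — are ordinarily obtained by questionnaire and physical examination.
An *instrumental* score estimates the same quantity from an instrumented
3D gait analysis instead: a small linear combination of gait features plus
the patient-reported pain item, which enters as a fixed offset with
coefficient 1 because individual pain perception resists kinematic
modelling. This package implements the complete chain:

1. **Representative cycle** — segment a recorded trial into gait cycles
   (ipsilateral foot strike to next ipsilateral foot strike), select the
   cycle closest to the ensemble mean, and time-normalise it to 0–100 % of
   the gait cycle on a 101-point grid.
2. **744 features** — per side (affected / contralateral): 14 standard
   spatiotemporal parameters, 16 gait-phase parameters, and 18 movement
   characteristics for each of 19 physiological angles
   (14 + 16 + 342 = 372 per side).
3. **Scoring** — evaluate the packaged HHS (6 predictors) and KSS-ks
   (4 predictors) regression models, clamped to [0, 100].
4. **Model building** — hierarchical stepwise regression with p-value
   thresholds, a predictor cap, a 70/30 train/test split, tenfold
   cross-validation and regression diagnostics, for deriving new
   instrumental scores on new cohorts.

# Normalised angular velocities

The distinctive feature family is the *normalised angular velocity* (NAV):
the slope of a physiological angle plotted against gait-cycle progress, in
degrees per percent of cycle (°/%). Each trajectory restricted to the
representative cycle is interpolated by a **degree-5 B-spline** with the
cycle progress as parameter; the NAV is that spline's analytic first
derivative evaluated on the grid. The knot vector uses full-multiplicity end
knots with interior knots placed by de Boor averaging of the sample
parameters, which guarantees a well-posed interpolation problem; the
collocation system is solved exactly, so the spline reproduces every sample
(and any quintic polynomial) to machine precision.

Two NAV pathways exist and are cross-validated against each other in the
test suite:

* the *scalar* pathway (default): spline the angle itself, differentiate;
* the *orientation* pathway: spline the four components of a
  hemisphere-aligned, scalar-first unit quaternion trajectory and map the
  derivative to the space-frame angular velocity
  `omega = 2 * qdot * conj(q)` (vector part, renormalised interpolant).

For planar (single-axis) angles the two agree to well below 1e-3 °/%. The
scalar pathway is the default because angle trajectories are what standard
gait exports contain; the orientation pathway supports segment-orientation
data directly.

Endpoint behaviour: the cycle is treated as a clamped 0–100 % window, not a
periodic signal — no periodic boundary condition is imposed. Interpolation
uses two extra samples beyond each cycle boundary (the recording always
extends past a single cycle), so the grid endpoints are interior to the
fitted span and derivative estimates at 0 % and 100 % are stable.

# Phase model

Nine functional phases are computed per cycle: stance, swing and the seven
Perry phases. Boundaries are **event-anchored** where events exist:

| boundary | rule |
|---|---|
| loading response → mid stance | contralateral foot off |
| mid stance → terminal stance | midpoint of contralateral off and strike |
| terminal stance → pre-swing | contralateral foot strike |
| pre-swing → initial swing | ipsilateral foot off (toe-off) |
| swing thirds | equal thirds of swing |

The mid-/terminal-stance midpoint substitutes for a heel-rise event (not in
the data model), and equal swing thirds substitute for feet-adjacent /
tibia-vertical events. When contralateral events are missing, a normative
fallback (boundaries at 10/30/50 % and toe-off; configurable) is used.
Intervals are half-open `[start, end)` with the last interval closed at
100, so every grid sample belongs to exactly one phase; the seven Perry
durations always sum to 100 %. The 16 phase parameters are the starts of
swing and of the six Perry phases that do not start at 0 by definition,
plus the durations of stance, swing and all seven Perry phases.

# Spatiotemporal conventions

The 14 standard parameters are computed per side on one ipsilateral cycle.
Two definitions that the literature leaves loose are fixed here:

* **Double support time** (per side) is the initial (loading)
  double-support period: ipsilateral strike → next contralateral foot off.
  This is the unique per-side definition under which
  `ss(L) + ss(R) + ds(L) + ds(R) = stride time` holds exactly for
  consistent events; a "total double support" definition double-counts.
* **Limp index** is the ratio of ipsilateral to contralateral stance time
  (1 for symmetric gait; < 1 on an antalgic affected limb), configurable to
  a swing-time ratio.

Gait speed prefers the mean progression velocity of a pelvis-origin
trajectory when present, otherwise stride length / stride time; both are
reported in km/h, cadence in steps/min.

# One representative cycle per subject

All 744 features of a subject derive from a single cycle anchored on the
affected side. Contralateral movement characteristics are read from the
same window, using the contralateral limb's own stance/swing membership
within it (its stance is the union `[0, contra-off) U [contra-strike, 100]`
of the anchored grid, which covers exactly one full contralateral stance by
periodicity). Contralateral *event-based* parameters (phase parameters,
spatiotemporal parameters) anchor on the contralateral strike inside the
representative window, i.e. on the contralateral cycle that overlaps it.
Features whose source angle or event is unavailable are reported as `NA` —
explicitly absent, never silently zero — and the feature vector always
carries all 744 canonical names.

The representative cycle is the one minimising the mean z-normalised RMS
distance to the point-wise ensemble-mean curve: per trajectory, the RMS
deviation from the ensemble mean over the grid is divided by that
trajectory's ensemble SD (trajectories with SD below 1e-9 are skipped),
then averaged over trajectories; ties break to the earliest cycle. The rule
is scale-free across angles measured in different ranges, deterministic,
and permutation-invariant.

# Hierarchical stepwise selection

Candidate features are offered in five stages of descending clinical
relevance (for the HHS: hip; knee; pelvis + foot progression; ankle,
thorax, arm; gait parameters — the knee and hip swap for the KSS-ks).
Within the opened pool the procedure alternates entry of the candidate with
the smallest partial-test p-value (t test on its coefficient in the
augmented model, equivalent to the 1-df partial F test) while
`p < p_enter = 0.05`, and removal of the retained predictor with the
largest `p >= p_remove = 0.10`. Removal may evict predictors entered at
earlier stages. Entry stops at the predictor cap; the final model is the
history entry with the best adjusted R² among cap-compliant entries
(plain R² is monotone in predictor count, so "best fit within the cap"
is only meaningful on the adjusted scale). Pain is excluded from selection
and appended afterwards with coefficient 1; selection runs on
`score - pain`.

Two predictor-cap rules ship: cases-per-predictor (default ratio 5, e.g. 6
predictors at 31 training cases, 4 at 23) and the textbook `50 + 8m` rule.
The ratio rule is the default: it is the one compatible with the cohort
sizes this method targets, where the `50 + 8m` rule would allow no
predictors at all.

Numerical safeguards: zero-variance features are excluded up front;
candidates whose residual after projection onto the current model falls
below 1e-9 of their centred variance are skipped as collinear (gait
features are heavily duplicated — e.g. a cycle minimum often equals the
stance minimum); entry stops when the fit is numerically perfect
(RSS/TSS < 1e-12), which makes selection on noiseless responses
well-defined. Entry p-values are computed by a vectorised QR projection
that is algebraically identical to refitting each augmented model (verified
against `lm()` in the tests). Ties on entry p break by larger |t|, then
name, so the whole procedure is deterministic given the data.

## What exact-set recovery can and cannot show

With `p_enter = 0.05`, every entry opportunity carries a false-entry chance
of up to 5 % *per effectively independent candidate direction*. After the
true predictors of a planted model have entered, the remaining residual is
pure noise, so the probability that *no* spurious candidate ever clears the
threshold is roughly `0.95^m`, where `m` is the effective number of
independent residual directions in the candidate pool — and a spurious
entrant with `p < 0.05` has `t^2 > 3.9 > 1`, so it *always improves the
adjusted R²* and survives the final model choice. Exact predictor-set
recovery at a high rate is therefore only achievable when the candidate
pool is tiny and nearly orthogonal.

A second effect compounds this on gait cohorts: gait features are heavily
collinear. In the synthetic cohorts a single severity axis drives most
features (cross-correlations around 0.98), and many features have
near-duplicates by construction (a cycle maximum usually equals the stance
maximum). A near-twin of a planted predictor can then win the entry
tie-break, absorb the planted signal, and leave the planted feature itself
with no residual contribution — selection identifies the *signal direction*
faithfully while naming an exchangeable proxy for it. The acceptance script
therefore reports the exact recovery rate and the containment rate (all
planted predictors among the selected) separately, together with the
cross-validated R² of the true predictor set; on severity-dominated
cohorts both rates are low while the recovered fit quality matches the
planted population R². These are properties of stepwise selection at fixed
thresholds on collinear candidates, not of the implementation; they are the
statistical reason the method pairs selection with a predictor cap,
held-out testing and cross-validation rather than interpreting the selected
names as unique truths.

Cross-validation refits the fixed selected predictor set on each of ten
seeded, balanced folds and reports held-out R² (`1 - SSE/SST` about the
held-out mean; negative values are possible and meaningful when predictors
carry no signal). Diagnostics (VIF, standardised residuals, Shapiro–Wilk,
Breusch–Pagan) are reported with flags but never acted on automatically.
VIFs are computed directly from the auxiliary regressions so that perfect
collinearity yields an infinite, flagged VIF rather than an error.

# The synthetic gait generator

The generator exists so that the whole pipeline can be exercised and
calibrated without patient data; all its defaults were chosen once, for
plausibility, and the acceptance checks are generator-relative.

* Each angle is a truncated Fourier series (mean + up to 4 harmonics), so
  curves are smooth and exactly periodic. The knee uses the classic
  double-bump curve (stance flexion wave, ~60° swing peak) projected onto
  four harmonics; other angles are low-amplitude sinusoids around
  physiologically plausible means.
* The event template places toe-off at 60 %, the contralateral strike at
  50 % and the contralateral foot off at 10 % of the cycle; nominal stride
  time 1.1 s, stride length 1.24 m (hence 4.06 km/h), step width 0.10 m,
  sampled at 100 Hz over at least four cycles.
* Pathology scales range of motion (35 % loss at severity 1), inflates
  stride time (+30 %), shortens the stride (−25 %) and introduces timing
  asymmetry (shorter affected stance), all proportional to a severity in
  [0, 1]; severity 0 reproduces the template exactly.
* Angle noise is *smooth*: white noise convolved with a 50 ms Gaussian
  kernel, default SD 0.3° (the order of marker-based kinematics
  repeatability). White noise would make the derivative of an interpolating
  spline explode; real optical-capture curves are smooth.
* Cohorts draw severity ~ U(0.05, 0.95), asymmetry ~ U(0.2, 0.8), affected
  side at random and pain uniformly on 0..pain_max, extract features
  through the *real* pipeline, and plant
  `score = intercept + sum(beta * feature) + pain + N(0, sigma)`; sigma can
  be given directly or derived from a target population R².

What the generator does **not** emulate: marker artefacts and soft-tissue
noise, inter-subject template variability beyond the severity axis,
walking-aid kinematics, kinetic (force) data, and any validated
biomechanical pathology model. Passing tests therefore demonstrate
correctness of the computational pipeline and recoverability of planted
structure — not clinical validity on real patients.

# Problem sizes used in the checks

The test suite and the acceptance script run the planted-model experiments
on one 200-subject cohort (features extracted subject-by-subject through
the full pipeline), 100 replicate score draws for recovery, 200 replicates
for the pure-noise experiment (20 candidate features), and 1000 random
event sets for the phase-tiling property; spline and scoring checks use
closed-form fixtures on the 101-point grid. These sizes were chosen so the
statistical properties of interest (recovery, false-entry behaviour,
tiling) are measured with useful precision while the whole suite stays
comfortably runnable on a laptop.

# Known limitations

* Joint angles are taken as inputs; no marker processing, filtering or
  inverse kinematics (they belong upstream), and no C3D reader — the
  documented CSV/JSON dialects are the interface.
* Gait events are inputs, not detected from kinematics.
* The exact Perry boundary conventions and the limp-index operationalisation
  are this package's documented choices where the literature names but does
  not define them; both are configurable where reasonable.
* The packaged HHS/KSS-ks models were estimated on post-arthroplasty
  cohorts; applying them to other populations is extrapolation.
* The KSS-ks pain item is taken on its original 0–50 scale; the HHS pain
  item on 0–44. Values above the item maximum warn rather than error.
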