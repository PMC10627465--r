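---
title: "Measuring the quiet eye: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quiet eye: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In far-aiming skills such as golf putting, the *quiet eye* (QE) is the final
fixation directed at the action-relevant target (the ball) that begins before
the critical movement (the backswing). Its duration is the central measure of
this package. Scoring it automatically from a head-mounted eye tracker in VR
requires a chain of stages, each with its own parameters:

1. **Gaze geometry.** Each sample carries a head position, a head orientation
   (unit quaternion) and a gaze direction in the head frame. The world gaze
   direction is the head orientation applied to the gaze-in-head vector; the
   visual angle to the ball is the angle between that direction and the line
   from the eye to the ball. Tracks are expressed as azimuth/elevation in
   degrees, recentred on the ball direction so angles stay far from the
   wrap-around at +/-180 degrees.
2. **Denoising.** Gaze is low-pass filtered with a second-order 30 Hz
   Butterworth; clubhead positions with 10 Hz (for event detection) or a
   five-point moving average (for kinematic summaries). All filters are
   applied forward and backward (zero phase): event *timing* must not be
   lag-shifted, which a single-pass filter would do. The price is that the
   effective magnitude response is the square of the single-pass response —
   the test oracles use the squared response for exactly this reason.
3. **Fixation detection (I-DT).** A window covering at least 100 ms is grown
   while its spatial dispersion — the classic sum of azimuth range and
   elevation range — stays at or below 1 degree of visual angle, and emitted
   at the first violation. Invalid samples split windows; they are never
   interpolated, because interpolation would manufacture dispersion
   compliance.
4. **Swing events.** Backswing onset and ball contact are detected from the
   clubhead's x-velocity (the putt-line axis) by peak detection: onset is the
   start of the sustained movement episode (|v| > 0.05 m/s for at least 3
   samples) containing the dominant backswing velocity peak; contact is the
   first forward crossing of the ball plane after that peak. A trace with a
   second comparable movement episode far from the first is ambiguous and the
   trial is scored *missing*, mirroring how unreliable swings are excluded in
   practice.
5. **QE scoring.** The QE is the final on-target fixation (mean visual angle
   to the ball at most 3 degrees) beginning before swing onset. Its offset is
   the first deviation beyond 3 degrees lasting longer than 100 ms; on-target
   fixations separated by shorter excursions are merged into a single QE.
   Absence of a qualifying fixation scores zero. The QE is decomposed into
   *early* (before onset), *online* (onset to contact) and *dwell* (after
   contact) phases by interval arithmetic; the total is defined as the sum of
   the three phases so additivity is exact in floating point as well as on
   paper.
6. **Outcome and kinematics.** Performance is the radial error (cm) of the
   landing point from the hole centre; group landing scatter is summarized by
   a Hotelling-type 95% confidence ellipse for the *mean* landing position
   (covariance scaled by p(n-1)/(n(n-p)) times the F quantile). Swing quality
   is the mean *absolute* downswing acceleration in the putt-line and lateral
   planes plus the 3-D clubhead speed at contact.
7. **Inference.** Trial-level outcomes are Winsorized (|z| > 3 replaced by a
   value 1% beyond the next most extreme retained score, per variable within
   condition), then modelled as `outcome ~ condition` with participant random
   intercepts and slopes (and optionally a trial-index intercept) by REML.
   p-values and confidence intervals use Satterthwaite degrees of freedom;
   standardized betas are `beta * SD(x)/SD(y)`; marginal and conditional
   R-squared follow the variance-decomposition formulation for mixed models.
   Zero-QE trials are treated as missing when a QE measure is the outcome.

## The synthetic generator

Because the interesting properties of this chain (boundary accuracy, offset
rules, event timing, estimator calibration) cannot be verified on human data
— there is no ground truth — the package ships a generator that *plants* the
truth. It emulates a VR putting task sampled at 120 Hz (gaze, 0.5-degree
class accuracy) and 90 Hz (club, 1.5 cm accuracy): a scripted fixation
sequence (optional hole glance, an off-ball preparation fixation, the final
ball fixation spanning swing onset, a look-away), constant-velocity saccades
of 30 ms, isotropic fixational jitter, millimetre head sway, a half-cosine
backswing and sinusoidal downswing crossing the ball plane at a configured
contact speed, and trial outcomes drawn from a mixed model with participant
random intercepts and slopes. Scenario variants reproduce the two
experimental manipulations: *occlusion* (a 1.5 s preview, then a visibility
channel toggles off — and nothing else, which is what makes occlusion
invariance testable) and the *noisy dot* (the fixation target drifts at
1.5 degrees of visual angle per second in the sagittal plane, turning the
fixation into slow pursuit; QE is then scored against the instantaneous dot
direction, since the dot is the task's target).

What the generator does **not** emulate: blinks and tracker dropouts beyond a
validity flag, vergence, saccade dynamics (main-sequence velocity profiles),
ball roll, and any systematic eye-tracker bias. Passing recovery tests on
synthetic data therefore demonstrates the correctness of the *algorithms*
under the stated noise model, not the field accuracy of any particular
eye-tracking hardware.

### Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gaze_rate_hz` / `club_rate_hz` | 120 / 90 | Hz | native rates of the simulated hardware |
| `jitter_sd_deg` | 0.2 | deg RMS | fixational noise magnitude; see below |
| `idt_min_dur_ms` / `idt_dispersion_deg` | 100 / 1.0 | ms / deg | standard fixation criteria for this task class |
| `qe_on_target_deg` / `qe_offset_tol_ms` | 3.0 / 100 | deg / ms | on-ball criterion and sustained-deviation offset rule |
| `rest_threshold_mps` | 0.05 | m/s | rest/movement boundary for swing onset (sustained 3 samples) |
| `winsor_z` | 3 | SD | outlier threshold |
| `qe_mean_ms` | 460, 390 | ms | planted QE duration means per condition, novice-scale values |
| `drift_deg_per_s` | 1.5 | deg/s | noisy-dot drift rate |
| `preview_s` | 1.5 | s | preview before occlusion |

`jitter_sd_deg` is defined as the **total angular RMS deviation** from the
fixated target: the jitter is an isotropic bivariate Gaussian in the tangent
plane with per-component SD `jitter_sd_deg / sqrt(2)`. Defining it as the
per-component SD instead would nearly double the within-fixation spread and
make a 0.2-degree jitter fundamentally incompatible with a 1-degree
dispersion threshold on long fixations, which no plausible reading of the
task intends.

## Numerical and design choices

**Boundary post-processing after I-DT.** The textbook I-DT greedy window
growth occasionally splits one long noisy fixation in two (a transient
excursion of the running range past the threshold) and leaves
sub-minimum-duration tails undetected. The pipeline therefore applies a
two-step spatial post-processing pass, in the spirit of two-tolerance
dispersion algorithms: boundaries are extended over adjacent samples within
0.5 degrees of the fixation centroid, then adjacent fixations separated by
at most 50 ms with centroids within 0.5 degrees are merged. The 0.5-degree
tolerance is half the dispersion threshold: under slow pursuit at
1.5 degrees/s, consecutive detected segments sit ~1 degree apart, so the
merge can never fuse them and the geometric duration bound
(1 degree / 1.5 degrees/s = 667 ms) survives post-processing. The pass is
*off* by default in `idt_fixations()` so the core algorithm remains the
textbook one (and is what the brute-force oracle test checks); the pipeline
configuration enables it.

**Boundary accuracy scales with saccade amplitude.** A zero-phase 30 Hz
Butterworth at 120 Hz displaces about 1.8% of a step's amplitude two samples
beyond the transition, and 4.3% one sample beyond. For gaze shifts in the
5–10 degree range this is well inside the dispersion tolerance and fixation
boundaries are recovered to within two samples; around a ~60 degree shift
(ball to hole and back) the smear exceeds the tolerance for two to three
samples and that accuracy is *physically unavailable* to any detector
operating on the filtered signal. Recovery benchmarks therefore use layouts
whose saccades stay in the moderate-amplitude regime (`hole_look = FALSE`);
the default trial layout keeps the realistic hole glance, whose boundary
smear is irrelevant to QE scoring because the QE fixation is bracketed by
small gaze shifts.

**"Directed at the ball".** The 3-degree criterion is applied to the
fixation's *mean* angle to the ball rather than to every sample; a single
jittered sample should not disqualify an otherwise on-target fixation.

**Accelerations as magnitudes.** Downswing acceleration summaries average
|a|; signed accelerations over an oscillatory stroke cancel to near zero and
could not index stroke-path variability. The downswing window runs from the
extreme backswing displacement to contact.

**Winsorizing across zero.** "1% beyond" the next most extreme retained
value is implemented as `x + 0.01 |x|` upward and `x - 0.01 |x|` downward,
which handles negative retained extremes and leaves a retained extreme of
exactly zero unchanged.

**Model simplification.** If the requested random-effect structure yields a
singular fit, the trial intercept is dropped, then the random slopes; the
structure actually used is recorded in the result. This replaces
PCA-guided model selection, which is out of scope here. With no usable
random structure at all the model degrades to ordinary least squares,
flagged as `random_structure = "none"`.

**QE duration floor.** Planted QE durations are drawn from a normal
distribution and floored at 100 ms — the minimum-duration criterion makes
shorter QEs undetectable by definition, so the floor is a property of the
measurement, not of the eye.

**Problem sizes.** The verification suite uses sizes chosen to make Monte
Carlo error small relative to the tolerance being checked while keeping the
suite fast: 500 fuzzed tracks for the oracle-equivalence check, 200 trials
for fixation recovery, 1000 layouts for phase additivity, 1000 replicates
(n = 40) for ellipse coverage, 200 replicates of a 45-participant,
20-trials-per-condition design for effect recovery, 1000 null simulations
for test size and 200 per point for the power curve's monotonicity. The
power-curve target of the original design context (a 75 ms QE effect, 20
trials per participant) depends on pilot variance components that are not
public; the generator's defaults (SD 100 ms intercept, 50 ms slope, 150 ms
residual) are plausible novice-scale values, so power *curves* computed here
characterize this generator, not any empirical sample.

## Interfaces

All user-facing work goes through R functions: `simulate_study()` /
`generate_dataset()` (simulate), `write_dataset()` / `read_dataset()` (a
pinned CSV + JSON-manifest dialect with exact round-trips),
`analyze_trial()` / `run_pipeline()` (extract + analyze) and
`fit_condition_lmm()` / `mc_power()` (inference and power). These four
groups are the simulate/extract/analyze/power surface of the pipeline; as an
R analysis package there is deliberately no shell entry point.

## Known limitations

- The dispersion metric (sum of ranges) and the gap-handling of the original
  MATLAB tooling this workflow descends from are not documented publicly;
  other reasonable variants (max pairwise distance; interpolation across
  short dropouts) would shift absolute QE durations by tens of ms.
- QE scoring against a drifting dot assumes the analysis knows the drift
  (it is the experimental manipulation); real re-analyses would read it from
  the session configuration, as `run_pipeline()` does from the scenario.
- The generator's saccades are kinematically simple (constant angular
  velocity); detectors that exploit saccade velocity profiles cannot be
  validated against it.
- Radial errors below zero cannot exist, so the mixed-model draw is clamped
  at zero; with realistic defaults this affects ~2% of trials and biases the
  condition contrast by well under the reporting precision, but extreme
  variance configurations would make the clamp visible.
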