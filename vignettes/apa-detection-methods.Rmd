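---
title: "Detecting anticipatory postural adjustments from force plates and wearable sensors"
author: "apakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anticipatory postural adjustments from force plates and wearable sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apakit)
```

## The problem

Before a standing person takes a first step — onto level ground or up a
stair — the central nervous system produces *anticipatory postural
adjustments* (APAs): the center of pressure (COP) first shifts backward
and toward the stepping foot (the **imbalance** phase, APA onset to
leading-foot heel-off), then laterally toward the stance foot (the
**unloading** phase, heel-off to leading-foot toe-off), before the
leading foot swings to its contact. APAs are hypometric in Parkinson's
disease, which makes their quantification clinically interesting, but
the laboratory gold standard — force platforms — is rarely available in
rehabilitation settings.

`apakit` implements an instrumented alternative based on two wearable
inertial units (a lower-trunk accelerometer and a gyroscope on the
shank of the leading leg), the force-plate reference method it is
calibrated against, the grid-search calibration itself, the
spatio-temporal APA parameters, and the statistics used to validate the
wearable method and to compare groups. A synthetic-trial generator with
known ground-truth events serves as the test bed for every component.

## Event detection

**Force plates (gold standard).** COP trajectories are low-pass
filtered (zero-phase Butterworth, 4th order applied forward-backward,
10 Hz cutoff). Four instants of the leading foot plus the trailing-foot
toe-off are detected:

* *APA onset*: first sustained excursion of the ML COP beyond twice the
  quiet-standing SD;
* *trailing toe-off*: last frame at which plate 1's vertical force is
  above a noise floor of 6.5 % body weight;
* *leading toe-off*: the COP sample at maximal perpendicular distance
  (d1~max~) from the line **L1** joining the COP at APA onset and at
  trailing toe-off;
* *leading heel-off*: the sample at maximal distance (d2~max~) from the
  line **L2** joining the COP at APA onset and at leading toe-off;
* *foot contact*: first frame at which plate 2's vertical force exceeds
  6.5 % of body weight.

**Wearable system.** Trunk accelerations are rotated to a
horizontal-vertical frame using the quiet-standing gravity direction
(Moe-Nilssen correction, two inverse-trigonometric steps, g =
9.80665 m/s²) and filtered at 3.5 Hz; the same filter is applied to the
shank ML angular velocity after quiet-window mean removal. APA onset is
the first sustained excursion of trunk ML acceleration beyond **A**
times the quiet-standing SD. From the angular velocity, the first peak
Ω~pk~ is located; heel-off is the first instant after onset at which the
signal exceeds **H**·Ω~pk~, toe-off the first instant after the peak at
which it drops below **T**·Ω~pk~, and foot contact the median point
between the post-swing zero-crossing and the second peak. The
calibrated factors are A = 2, H = 0.07, T = 0.25 for gait initiation
and A = 2, H = 0.08, T = 1 for step climbing
(`default_thresholds()`).

### Numerical choices in the detectors

*Sustained crossings.* The onset threshold must be held for 25 ms
(force plate) or two samples (IMU), and the excursion must also climb
both to `confirm_mult` (default 5) times the threshold and to 6 % of
the post-quiet maximum deviation. The first condition is a standard
two-threshold guard: after low-pass filtering, noise is strongly
autocorrelated, so excursions beyond the detection threshold easily
outlast any fixed hold time, but they rarely climb much higher. The
second is scale-free: zero-phase filtering leaks oscillatory lobes of
1–3 % of a large excursion *ahead* of the true onset, which can exceed
any fixed multiple of a small noise SD, whereas even a strongly
hypometric imbalance phase reaches well above 13 % of the overall
excursion. The guards change which excursion is accepted, never the
reported crossing time.

*Sub-sample interpolation.* Event times are continuous seconds, not
frame indices, so 800 Hz and 50 Hz sources compare directly. Gyro
threshold crossings are linearly interpolated between the bracketing
samples by default (`interp = TRUE`): at 50 Hz one sample spans 20 ms,
whereas one step of the H grid moves the true crossing by only a few
milliseconds, so grid-time crossings would make the calibration surface
piecewise-flat. The zero-crossing before the second peak is
interpolated for the same reason. Plain first-sample semantics are
available via `interp = FALSE`.

*Onset refinement.* A threshold crossing lags the true movement onset
by the time the excursion needs to reach the threshold — for a smooth
start this is `sqrt(threshold / curvature)`, tens of milliseconds, and
it depends on the threshold, i.e. on the noise level. The pipeline
entry points (`detect_all_fp()`, `detect_all_imu()`) therefore refine
the crossing by extrapolating the initial rise back to baseline: for a
smooth-step excursion `dev(t) ≈ Amp·sin²(k(t−t₀))`, the transform
`asin(sqrt(dev/Amp))` is linear in `t`, so the x-intercept of a
straight-line fit estimates the onset without the latency bias. `Amp`
is measured as the first local maximum of the deviation after the
crossing that clears the 6 % floor (the imbalance extreme); the fit
uses the 4–75 % band of the rise, below which the deviation is noise
or filter ringing and above which the transform is ill-conditioned,
and the refined onset may move forward of a crossing that sat on a
ringing lobe. On the inertial side the fit runs on a 10 Hz-filtered copy of
the tilt-corrected acceleration, because the 3.5 Hz detection band
smears the onset over several 50 Hz samples. The refinement is an
addition to the published procedure; `refine_onset = FALSE` restores
plain crossings, and the low-level detectors default to them.

*Geometry.* The maximal point-to-line distances are exhaustive scans
over all samples in the respective windows (onset→trailing-toe-off for
L1, onset→toe-off for L2); ties break to the earliest sample and
collinear paths are flagged degenerate rather than guessed at.

## Calibration

A, H and T are calibrated against force-plate events on paired
recordings, over the grid A ∈ {1,…,5}, H ∈ {0, 0.01, …, 1},
T ∈ {0, 0.05, …, 1}. Absolute per-trial errors are averaged within
subjects and then across subjects. The three factors are minimized
sequentially — A on the onset MAE, then H (whose search window depends
on the selected onset) on the heel-off MAE, then T on the toe-off MAE —
because toe-off is independent of A and H by construction and no joint
objective is defined; ties break toward the smallest factor. Foot
contact has no free parameter; its MAE is reported but not optimized.
The full per-factor MAE surface is retained for audit and
`calibration_rescan()` re-derives the optima from it.

## Spatio-temporal parameters and statistics

Durations: imbalance = heel-off − onset, unloading = toe-off −
heel-off, APA = imbalance + unloading (exactly), swing = contact −
toe-off, step = APA + swing (exactly). Amplitudes are signal
differences at the event instants — COP positions (cm) for the force
plate, trunk accelerations (m/s²) for the wearable system — taken at
the sample nearest each event time, on the filtered signals used for
detection. With the ML axis positive toward the stepping side, the
imbalance ML amplitude is positive and the unloading ML amplitude
negative.

Parameters are averaged over the repetitions of each test per subject
(`average_trials()`). Concurrent validity is assessed by Pearson
correlation of paired per-subject parameters from the two systems
(`validate_against_fp()`); group differences use Student's t-tests,
unpaired between groups and paired between tasks
(`compare_groups()`), at α = 0.05 with no multiplicity correction.
Shapiro-Wilk and Bartlett screens are computed and reported but never
switch the test family.

## The synthetic test bed

`trial_blueprint()` / `generate_trial()` build paired force-plate and
IMU recordings of one trial with exactly known events: a 10 s
quiet-standing lead-in, then imbalance → unloading → swing with
defaults taken from the published healthy-adult values (imbalance
0.40/0.47 s, unloading 0.30 s, swing 0.50/0.65 s; COP imbalance ML
2.17/2.48 cm, unloading ML ≈ −9.4 cm; trunk gain 0.088 (m/s²)/cm;
Ω~pk~ ≈ 150 deg/s; body weight 700 N). The COP path is built from
raised-cosine segments whose vertices sit on the programmed events, so
the maximal line distances land exactly on toe-off and heel-off; plate
forces are complementary raised-cosine load transfers crossing 6.5 %
body weight exactly at contact and trailing toe-off; the gyro pulse
flanks are solved so that the H/T crossings sit exactly on heel-off and
toe-off; trunk ML acceleration is a single-gain image of the ML COP
(the mono-segmental coupling hypothesis made literal), while the AP
channel mixes a COP-driven and an independent component so that the
AP-vs-ML validity contrast is reproducible in kind.

Because the detection filters are not perfectly transparent to these
waveforms, the generator *pre-compensates* them: the gyro flanks, the
COP segment boundaries and (for calibration cohorts) the onset marker
are nudged by a few fixed-point iterations until the detectors, run on
the filtered clean signals, recover the programmed instants. Without
this, zero-phase filtering shifts the landmarks by 5–20 ms — the
detectors would still be correct, but the generator's ground truth
would not coincide with the features it claims to place.

For calibration cohorts the generator embeds a small smooth step
(height 2·A~true~·SD of the realized filtered noise) centred on the
onset and aligned on the realized first-passage crossing, so that
onset detection at exactly A = A~true~ reproduces the true onset; the
H/T alignment comes from the flank construction. Recovery cohorts draw
A~true~ from {2,…,5} and H, T from the interior of their grids: at
A = 1 the threshold equals one SD of the baseline noise, where first
crossings are noise excursions and the recovery property is undefined
for any generator.

`generate_cohort()` draws subject parameters from a population model:
a lognormal between-subject amplitude factor with CV ≈ 0.42 (matching
the printed between-subject spread of the imbalance ML amplitude),
normal phase-duration variation, and per-trial jitter. The hypometric
("PD-like") mode scales the ML imbalance excursion by 0.4 and the
unloading by 0.8, shortens swing by 12 %, and removes the
task-scaling of the imbalance amplitude (healthy subjects scale it by
≈ 1.3 when stepping up; the hypometric mode by 1.0) — the programmed
analogue of the published group contrasts.

### What the generator does and does not emulate

Channel noise is *instrument* noise (COP 0.01 cm, force 2 N,
acceleration 0.005 m/s², angular velocity 0.5 deg/s). Physiological
quiet-stance sway — which in real recordings inflates the quiet-window
SD and hence the onset threshold and latency — is deliberately not
modelled, nor are freezing episodes, multi-step corrections, arm
movements, or soft-tissue artifacts. Passing tests therefore
demonstrate the correctness of the detectors, the calibration and the
statistics on signals with the prescribed morphology; they do not
certify accuracy on real patient data, where onset errors of
0.05–0.09 s against force plates are the realistic scale.

### Problem sizes used by the tests

The test suite and the acceptance script run on cohorts of 6–12
subjects with 2–3 trials per task (the validation group of the original
study had 25 subjects), 20 randomized calibration cohorts, and 12
replicate group-contrast cohorts of 11 + 11 subjects; these sizes give
stable averages while keeping a full run in a few minutes.

## Known limitations

* The onset refinement assumes a smooth-step rise; abrupt or
  oscillatory onsets fall back to the plain crossing.
* At thresholds inside the noise band (A ≤ 1, H ≈ 0 with a noisy
  baseline) threshold detection is dominated by noise first passages;
  the package reports what it detects but no calibration can make such
  operating points reliable.
* The trailing-foot toe-off uses a force floor of 6.5 % body weight on
  plate 1; records in which the plate is never cleanly vacated raise a
  no-liftoff error instead of guessing.
* Stepping-side mirroring assumes the sidecar metadata is correct; no
  automatic side inference is attempted (the gyro sign normalization
  only corrects a mirror-mounted shank sensor).
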