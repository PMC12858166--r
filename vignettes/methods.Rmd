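---
title: "Methods: kinematics, photometry, avoidance simulation and windowed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, photometry, avoidance simulation and windowed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuttlebox)
```

`shuttlebox` implements the analysis chain used to relate subthalamic
nucleus (STN) population and single-cell calcium activity to head
movement and cued avoidance behavior: head-kinematic decomposition from
two tracking markers, isosbestic dF/F photometry processing, turn and
movement-peak detection, a discrete-event simulator of the four
shuttle-box avoidance procedures, event-triggered window measures,
k-means classification of neurons and trials, and windowed linear
mixed-effects models. A synthetic-data generator with stored ground
truth makes every stage testable end to end.

## Head-kinematic decomposition

Two markers — one over the nose, one between the ears — define the head
midline. Per frame pair, the decomposition computes:

* **rotational speed** = |change of midline angle| (radians) x radius x
  frame rate. The radius is not uniquely determined by the construction;
  we use the nose-to-ears midline length, averaged over the two frames
  of each difference, because that is the arc the nose traces when the
  head pivots about the ears marker. A half-midline option exists for
  the alternative reading (it exactly halves rotational speeds).
* **linear speed** = ears-marker displacement x cos(angle between the
  displacement and the midline) x frame rate, signed (forward
  positive); **sideways speed** uses the sine (leftward positive).
* **translational speed** combines linear and sideways components. The
  default is the Euclidean combination, which exactly equals
  |displacement| x frame rate; a signed-magnitude sum (|linear| +
  |sideways|) is selectable. **Overall speed** defaults to rotational +
  |translational| per frame, with a Euclidean option. Both combination
  rules are configurable because the construction only states a "sum".

Angles are computed in radians internally and reported in degrees,
unwrapped so there are no +-180° jumps. Image coordinates (y down) are
flipped to the mathematical convention at ingestion, so counter-clockwise
rotation is positive. A session-level `implant_side` maps signed rotation
to contraversive (+) versus ipsiversive (-): a counter-clockwise
(leftward) turn is contraversive for a right-hemisphere implant. First-
frame speeds are forward-filled from the second frame and flagged in a
`filled` column. The `head_angle_bias()` trace is the accumulated
per-frame angle change zeroed at the frame preceding the alignment time,
in degrees — degrees were chosen because the bias is compared against the
10° turn threshold.

These choices are pinned by oracle tests: trajectories built from exact
rigid geometry must decompose to the analytic component speeds within
1e-6 cm/s, rotating the whole coordinate frame must not change any speed
magnitude, and halving metric coordinates must halve every speed.

## Photometry processing

The inputs are per-pulse peak emissions from interleaved 465 nm
(calcium-sensitive) and 405 nm (isosbestic) excitation at 100 Hz. The
isosbestic channel is scaled to the signal channel by least squares;
`fit_isosbestic()` fits slope and intercept by default (robust to
additive offsets between detectors) with a slope-only option, since the
original description mentions only "the slope of the linear fit". The
fitted series is the baseline F0, dF/F = (F - F0)/F0, converted to
z-scores over the whole session (per-trial z-scoring is deliberately not
offered; session z-scores are what the windowed analyses consume). No
additional filtering is applied beyond the pulse-peak sampling the data
already embody.

Because both channels share the bleaching and movement artifacts, any
common multiplicative artifact cancels in dF/F (tested as a common-mode
rejection property). One subtlety the synthetic studies exposed: the
linear scaling absorbs the session-mean calcium level, so dF/F is
attenuated by 1/(1 + gain x mean drive) and can be tilted by a smooth
bleach-shaped residual when calcium covaries with bleach by chance over
a finite session. The coupling estimator `recover_coupling()` therefore
(a) matches the calcium decay kernel when scanning candidate delays — the
raw cross-correlation peak is biased late by the kernel — (b) includes a
slow quadratic time trend in the gain regression to absorb the baseline
residual, and (c) inverts the mean-calcium attenuation. With these
corrections the planted gain is recovered within 0.5% and the delay
exactly, across 100 seeded sessions.

`imaged_volume()` models the sampled tissue as a cylinder of the fiber
diameter extending the stated depth from the fiber ending
(pi (d/2)^2 h), reported at two significant figures; a 400 µm fiber
imaging 200 µm deep gives 2.5e7 µm³.

## Event detection and sampling categories

A sample is a detected event when it is the strict maximum or minimum
among all samples within ±0.5 s (ties broken to the earliest sample, so
plateaus are reproducible), excluding the first and last half-window.
The event magnitude is the signed change from the nearest preceding
opposite extremum (or the trace start); turns require a change > 10°,
in the direction of the sign. The 3-s-exclusion category considers
preceding events of either sign; this was an open choice and is
configurable. The ">5 s spacing" category is implemented as greedy
left-to-right selection (keep an event iff it is >= 5 s after the last
kept event). The detector is pinned to a brute-force O(n·w) scan on
1,000 random traces, and detection counts are monotone non-increasing in
the threshold.

## Avoidance-task simulation

`run_session()` is an event-driven simulator (no fixed tick; times at ms
resolution) of the four procedures: AA1 (CS1, 7 s avoidance interval,
10 s escape interval), AA2 (AA1 plus 0.2 s shock for intertrial
crossings), AA3 (randomized CS1 active / CS2 passive discrimination;
crossing during CS2 is a 0.5 s-shock passive error that ends the trial,
with no escape interval afterwards since none is described), and AA4
(CS1/CS2/CS3 signalling 4/7/15 s intervals). Intertrial intervals are
drawn uniformly on [25, 45] s — only the range is stated — and ITCs are a
Poisson process over the ITI. The escape delay after US onset defaults
to a constant 0.3 s ("escape occurs rapidly"). Agents are pluggable
latency samplers per CS plus an ITC rate; ITC-punishment adaptation is
off by default because learning is out of scope. Sessions are
byte-identical under identical seeds. Performance metrics follow the
standard definitions: % avoids per CS, response latency averaged over
successful avoids only, ITC counts.

## Event-triggered windows and coupling statistics

Snippets are linearly interpolated onto a common grid (20 Hz by default)
around each event; events whose span leaves the recording are dropped
and counted. Window measures use trapezoidal area divided by window
duration; the post-CS (orienting 0–0.5 s, avoid 0.5–7 s) and from-action
(−2–2 s; −3.5–3 s for single-cell work) windows are corrected by
subtracting the baseline-window (−0.5–0 s) rate, and the escape window
(0–4 s after US onset) ships as a preset. The peak is the extremum by
absolute value — an inhibited response reports its minimum — and
time-to-peak is its time from the alignment event. SEM across events
uses n−1.

Cross-correlation reports Pearson r at every integer-sample lag;
positive lags mean neural activity follows movement. The
200-ms-integrated linear fit averages both series over non-overlapping
centred bins before the least-squares fit; overlapping integration was
an open reading and the non-overlapping choice is flagged here. Shuffle
controls use circular shifts of one variable with an offset of at least
5 s rather than sample permutation, preserving autocorrelation — a
conservative null for autocorrelated signals. Its empirical type-I
error at nominal 5% is 5 ± 2% over 1,000 seeded independent pairs.

## Classification schemes

All schemes use k-means (`stats::kmeans`, 50 restarts under a fixed
seed) with canonical relabelling: classes are renamed by a per-class
ordering statistic so identical populations always get identical names,
regardless of k-means' arbitrary numbering or input order; ties break by
class size. k is fixed per scheme (3 for movement-onset, turn-bias,
avoidance-mode and within-mode types; 4 for cross-correlation classes).
Turn-bias classification orders by descending peak contraversive bias
("C, B, A"); avoidance modes order by ascending mean avoid latency
("Mode 1, 2, 3"); cross-correlation classes order by coupling strength,
and among the strongest two the positive-lag (following) class precedes
the negative-lag (preceding) class, with per-class mean peak lags
reported so lead/lag identity is explicit.

Two degenerate situations get explicit handling rather than arbitrary
splits: avoidance-mode clusters whose mean latencies lie within 0.75 s
of each other merge into one effective mode (a homogeneous session
yields a single mode), and cross-correlation classes below a
caller-supplied correlation noise floor collapse into one effective
class (`effective_k`). Identical items raise a degenerate-cluster error.
Within-mode type classification runs independently per mode; no
cross-mode identity is asserted.

## Windowed mixed-effects models

`build_model()` assembles `response ~ (factor interaction) + (factor
interaction) * covariate ... + (1 | subject/session)` — the nested
random-intercept structure (sessions in subjects, or neurons in
subjects) — and validates that baseline-window models exclude the
baseline-dF/F covariate. Covariates are z-scored within window;
the window-specific head-speed covariate can additionally be
standardized within outcome, and only that covariate, matching the
stated convention. Constant-within-stratum covariates are zero-filled
with a warning.

Fitting is delegated to `lmerTest::lmer` (REML, Satterthwaite degrees
of freedom); marginal means at covariate zero (the standardized mean)
and pairwise contrasts come from `emmeans`. The multiplicity correction
is Holm by default — the description "Tukey's correction
(Holm-adjusted)" is internally contradictory, and Holm is the one named
as applied — with Tukey HSD selectable; the method used is recorded in
the output. Fixed-effect chi-squared statistics come from
likelihood-ratio tests of nested ML refits (`lrt_fixed()`). Singular
fits are flagged, never silenced. With group variances at zero the
fixed-effect predictions agree with ordinary least squares, and over 100
seeded replicates the 95% Wald intervals cover the planted slope and
outcome effect at 95 ± 3%.

## What the synthetic generator does and does not emulate

The generator covers every input format the pipeline consumes, with the
ground truth serialized next to each dataset and bit-identical
regeneration from (config, seed) via a single hierarchical RNG stream.

* **Tracking** (`gen_tracking()`): heading is a turn-defined set point
  plus a mean-reverting (Ornstein–Uhlenbeck) jitter whose stationary sd
  is 1.2° — bounded wander that never constitutes a turn — with planted
  raised-cosine turn ramps of 15–40° over 0.4 s, about 8 s apart, and a
  rectified OU forward speed (base 3 cm/s) with Gaussian locomotor
  bouts. The default session is 300 s at 50 fps with a 1.5 cm midline.
  Real heads also pitch and roll, markers occlude, and turning statistics
  are richer; none of that is modelled, so detector performance here
  bounds only the planar-geometry behavior.
* **Photometry** (`gen_photometry()`): latent calcium = gain x delayed
  (300 ms), rectified translational/rotational drive mix (0.7/0.3)
  convolved with a 1 s exponential kernel (GCaMP-like; no claim of
  biophysical fidelity), riding on a shared exponential bleach
  (tau 20 min) with per-channel Gaussian noise at 0.2% of baseline —
  an SNR comfortably above 5, chosen so the stated recovery tolerances
  hold with margin, per the calibration runs reproduced in
  `scripts/acceptance.R`.
* **Population** (`gen_population()`): movement-locked (+200 ms),
  anticipatory (−500 ms), inhibited, unresponsive and nociceptive-only
  classes, with a turn-direction preference mixture (20% strong
  contraversive, 25% weak ipsiversive) on the movement-responsive
  classes. Single-cell traces use a light 100 ms kernel so planted
  leads/lags survive to the cross-correlation peak.
* **Behavior** (`gen_behavior()`): three avoidance modes with latency
  distributions N(1.5, 0.4), N(4, 0.7) and N(6, 0.6) s — rapid,
  delayed, and last-moment responding — mode-specific pre-CS baseline
  speeds (3/6/1 cm/s; the middle mode is the "distracted, already
  moving" one), orienting bumps at CS onset (large/large/minimal) and a
  locomotor burst at the response time. These separations make the
  planted modes genuinely distinct clusters, which is what the recovery
  tests quantify.

Because these are the study conditions for all automated checks, a
passing suite demonstrates internal consistency and recoverability under
realistic noise — not performance on recorded data, which carry
artifacts (marker dropouts, hemodynamic contamination, non-stationary
behavior) the generator deliberately omits.

## Problem sizes and numerical choices

The automated suites run at desk scale: 300 s sessions, 90-neuron
populations, 300-trial behavioral sessions, 100-replicate recovery
loops, 1,000-trajectory and 1,000-trace oracle comparisons, and
1,000-pair shuffle calibrations. Trapezoidal integration is used for all
window areas; linear interpolation for snippet resampling (gap-filling
beyond 3 frames is out of scope); k-means uses 50 restarts and up to
five reseeded retries before declaring a degenerate clustering;
empirical shuffle p-values use the (1 + count)/(n + 1) correction.
Seeds derive from a single master seed per run.
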