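# shuttlebox

Analysis pipeline for cued (signaled) active-avoidance experiments that
combine head tracking and calcium-imaging photometry of subthalamic
nucleus (STN) neurons. The package covers the full chain from raw
coordinate and emission streams to windowed mixed-effects statistics:

* **Kinematics** — two head markers (nose, between-the-ears) are
  decomposed per frame into rotational speed (midline angle change x
  midline radius x frame rate), signed linear and sideways speeds
  (ears displacement projected on / orthogonal to the midline), their
  translational combination, and an unwrapped head angle with a
  stimulus-zeroed bias trace mapped to contraversive/ipsiversive via
  the implant side.
* **Photometry** — the 405 nm isosbestic channel is scaled to the
  465 nm channel by a linear fit; dF/F = (F − F0)/F0 is z-scored over
  the session. Shared artifacts (bleaching, movement) cancel as common
  mode. A cylinder model estimates the imaged volume
  (π(d/2)²h; 400 µm fiber x 200 µm depth → 2.5x10⁷ µm³).
* **Events** — strict local extrema over ±0.5 s detect movement peaks
  and head turns (>10° change, direction from the sign), with the three
  sampling categories used for peri-event averages: all events, events
  with no event 3 s prior, and events spaced >5 s apart.
* **Task simulation** — an event-driven simulator of the AA1–AA4
  shuttle-box procedures (7 s avoidance / 10 s escape intervals,
  25–45 s ITIs, punished intertrial crossings in AA2, CS2 passive
  avoidance in AA3, 4/7/15 s signaled intervals in AA4) with pluggable
  agent latency policies and reproducible seeded sessions.
* **Triggered analysis** — event-aligned snippet matrices; baseline
  (−0.5–0 s), orienting (0–0.5 s), avoid (0.5–7 s), from-action
  (−2–2 s) and escape (0–4 s) window area-rates (baseline-corrected),
  peaks and times-to-peak; lagged cross-correlation;
  200-ms-integrated linear fits; circular-shift shuffle controls.
* **Classification** — k-means with canonical, deterministic labels:
  turn-bias classes C/B/A ordered by contraversive bias,
  cross-correlation coupling classes 1–4 ordered by strength and
  lead/lag, avoidance modes 1–3 ordered by latency.
* **Mixed models** — windowed `dF/F ~ (factors) * covariates +
  (1|subject/session)` fits via lme4/lmerTest with standardized
  covariates (per-outcome for the window speed), emmeans marginal means
  at covariate zero, Holm-adjusted pairwise contrasts, and
  likelihood-ratio χ² for fixed effects.
* **Synthetic data** — generators for every input with stored ground
  truth (planted turns, coupling gain/delay, neuron classes, avoidance
  modes), so each stage is tested end to end without recorded data.

## Worked example

Generate a synthetic session, decompose kinematics, process photometry
and quantify the movement/activity coupling:

```r
library(shuttlebox)

cfg <- synth_config()                       # 300 s, 50 fps, 20 planted turns
trk <- gen_tracking(cfg, seed = 2)
kin <- decompose_markers(trk$track)
pho <- gen_photometry(cfg, kin, seed = 3)
dff <- compute_dff(pho$raw, fit_isosbestic(pho$raw))

turns <- detect_peaks(kin$time, kin$head_angle, kind = "turn")
nrow(turns)                                 # 27 detected turns (20 planted)

rc <- recover_coupling(kin, dff, cfg)
rc$delay                                    # 0.3   (planted: 0.3 s)
rc$gain                                     # 0.0499 (planted: 0.05)

agent <- agent_policy(function(n) runif(n, 5, 9))
log <- run_session(trial_spec("AA1"), agent, 2000, seed = 3)
performance(log)$per_cs$pct_avoids          # 50.6  (closed form: 50)

summarize_proportions(c(C = 192, B = 256, A = 585))$pct
#> 18.6 24.8 56.6                            (turn-bias class percentages)
```

The detected turn count includes occasional split detections of one
planted turn; matched against the stored ground truth the detector's
recall is 1.00 with ≤1 false alarm per 300 s session. The recovered
coupling uses a kernel-matched delay scan and a trend-controlled gain
regression (see the methods vignette for why the raw cross-correlation
peak is biased late by the calcium decay kernel).

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (simulate → kinematics/photometry → events/windows →
neuron classes → behavior/modes → mixed models) and write their tables
under `results/`.

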