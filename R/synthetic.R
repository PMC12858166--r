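#' Default configuration for the synthetic study
#'
#' Central defaults for every generator. Values emulate a desk-scale
#' version of the study conditions: 30-100 fps two-marker head tracking in
#' a small arena, 100 Hz interleaved dual-excitation photometry with slow
#' bleaching and shared artifacts, movement-coupled calcium with a
#' GCaMP-like 1 s decay, and avoidance sessions with three response
#' modes.
#'
#' @param ... overrides merged over the defaults (unknown keys rejected).
#' @return Named list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    # tracking
    duration = 300, fps = 50, midline_cm = 1.5, pixels_per_cm = 20,
    implant_side = "right",
    heading_noise_deg = 1.2,     # stationary sd of the heading jitter, degrees
    heading_theta = 0.04,        # per-frame OU mean reversion of the jitter
    base_speed = 3,              # cm/s resting drift
    speed_noise = 1.0, speed_theta = 0.1,
    n_turns = 20, turn_amp_deg = c(15, 40), turn_duration = 0.4,
    turn_min_gap = 8,
    n_bouts = 15, bout_amp = c(8, 20), bout_duration = 0.6,
    # photometry
    pulse_rate = 100, gain = 0.05, delay = 0.3, kernel_tau = 1,
    w_translational = 0.7, w_rotational = 0.3,
    f465_base = 100, f405_base = 80, bleach_tau = 1200,
    photo_noise = 0.002,         # fraction of channel baseline
    transients = NULL,           # list(times =, amps =) fractional dff
    # population
    n_neurons = 90, neuron_rate = 20, neuron_noise = 0.35,
    class_weights = c(movement_locked = 0.25, anticipatory = 0.10,
                      inhibited = 0.15, unresponsive = 0.45,
                      nociceptive = 0.05),
    neuron_gain = c(0.8, 1.5), neuron_lag = 0.2, anticipatory_lead = 0.5,
    neuron_tau = 0.1,
    # turn-direction preference mixture (strong contra / weak ipsi / none)
    bias_weights = c(contra = 0.2, ipsi = 0.25, none = 0.55),
    bias_strength = c(contra = 1.2, ipsi = 0.4, none = 0),
    # behavior
    procedure = "AA1", n_trials = 60,
    mode_mixture = c(0.45, 0.35, 0.20),
    mode_latency_mean = c(1.5, 4, 6),
    mode_latency_sd = c(0.4, 0.7, 0.6),
    mode_baseline_speed = c(3, 6, 1),
    mode_orient_amp = c(8, 6, 1.5),
    response_burst_amp = 25,
    trial_rate = 20, trial_span = c(-2, 10), trial_noise = 1.0,
    itc_rate = 2)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("synth_config", "list"))
}

# raised-cosine ramp of unit area over n samples
.ramp <- function(n) {
  w <- (1 - cos(2 * pi * seq_len(n) / (n + 1))) / 2
  w / sum(w)
}

.ou <- function(n, theta, sd_innov, x0 = 0) {
  x <- numeric(n)
  x[1L] <- x0
  innov <- stats::rnorm(n, 0, sd_innov)
  for (i in 2:n) x[i] <- x[i - 1L] * (1 - theta) + innov[i]
  x
}

#' Generate a synthetic two-marker tracking session
#'
#' Ornstein-Uhlenbeck heading and speed processes with discrete head
#' turns (raised-cosine angle ramps above the detection threshold) and
#' locomotor bouts injected at logged times, rendered to nose and ears
#' marker trajectories at the configured frame rate and calibration.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical `(config, seed)` give identical
#'   output.
#' @return List: `track` (a [marker_track()]) and `truth` (turn times,
#'   signs and amplitudes; bout times and amplitudes; config and seed).
#' @export
gen_tracking <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  if (cfg$duration <= 0 || cfg$fps <= 0)
    stop("invalid config: duration and fps must be positive", call. = FALSE)
  set.seed(seed)
  n <- round(cfg$duration * cfg$fps) + 1L
  tm <- seq(0, by = 1 / cfg$fps, length.out = n)

  # heading = turn-defined set point + mean-reverting jitter: the jitter's
  # excursions stay bounded well below the turn threshold, so only the
  # planted ramps constitute turns
  jitter_sd <- cfg$heading_noise_deg * pi / 180
  jitter <- .ou(n, cfg$heading_theta,
                jitter_sd * sqrt(2 * cfg$heading_theta - cfg$heading_theta^2))
  dang <- c(0, diff(jitter))
  turn_times <- numeric(0); turn_signs <- integer(0); turn_amps <- numeric(0)
  if (cfg$n_turns > 0) {
    lo <- min(5, cfg$duration / 4); hi <- max(cfg$duration - 5, lo)
    cand <- seq(lo, hi, length.out = cfg$n_turns) +
      stats::runif(cfg$n_turns, -cfg$turn_min_gap / 4, cfg$turn_min_gap / 4)
    turn_times <- sort(pmin(pmax(cand, 0.5),
                            cfg$duration - cfg$turn_duration - 0.5))
    turn_signs <- ifelse(stats::runif(cfg$n_turns) < 0.5, -1L, 1L)
    turn_amps <- stats::runif(cfg$n_turns, cfg$turn_amp_deg[1L],
                              cfg$turn_amp_deg[2L])
    wlen <- max(2L, round(cfg$turn_duration * cfg$fps))
    for (k in seq_along(turn_times)) {
      i0 <- round(turn_times[k] * cfg$fps) + 1L
      idx <- i0:min(n, i0 + wlen - 1L)
      dang[idx] <- dang[idx] +
        turn_signs[k] * turn_amps[k] * (pi / 180) * .ramp(length(idx))
    }
  }
  heading <- cumsum(dang)

  # forward speed: rectified OU around base + bout bumps
  sp <- cfg$base_speed + .ou(n, cfg$speed_theta, cfg$speed_noise)
  bout_times <- numeric(0); bout_amps <- numeric(0)
  if (cfg$n_bouts > 0) {
    bout_times <- sort(stats::runif(cfg$n_bouts, min(2, cfg$duration / 4),
                                    max(cfg$duration - 2, cfg$duration / 2)))
    bout_amps <- stats::runif(cfg$n_bouts, cfg$bout_amp[1L], cfg$bout_amp[2L])
    for (k in seq_along(bout_times)) {
      bump <- bout_amps[k] *
        exp(-(tm - bout_times[k])^2 / (2 * (cfg$bout_duration / 2)^2))
      sp <- sp + bump
    }
  }
  sp <- pmax(sp, 0)

  # integrate ears path along heading; nose sits one midline ahead
  step <- sp / cfg$fps
  ears <- cbind(cumsum(c(0, step[-n] * cos(heading[-n]))),
                cumsum(c(0, step[-n] * sin(heading[-n]))))
  nose <- ears + cfg$midline_cm * cbind(cos(heading), sin(heading))

  track <- marker_track(tm, nose, ears, frame_rate = cfg$fps,
                        pixels_per_cm = cfg$pixels_per_cm,
                        implant_side = cfg$implant_side,
                        validate_rate = FALSE)
  list(track = track,
       truth = list(turn_times = turn_times, turn_signs = turn_signs,
                    turn_amps = turn_amps, bout_times = bout_times,
                    bout_amps = bout_amps, seed = seed, config = cfg))
}

.exp_kernel <- function(tau, rate, span = 5) {
  if (tau <= 0) return(1)
  tt <- seq(0, span * tau, by = 1 / rate)
  k <- exp(-tt / tau)
  k / sum(k)
}

.conv_causal <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  L <- length(kernel)
  xp <- c(rep(x[1L], L - 1L), x)       # pad so the filter warms up on x[1]
  y <- stats::filter(xp, kernel, method = "convolution", sides = 1)
  as.numeric(y[(L - 1L) + seq_along(x)])
}

#' Generate dual-channel photometry coupled to movement
#'
#' The latent calcium signal is a gain times the delayed, rectified mix
#' of the translational and rotational speed components, convolved with
#' an exponential decay kernel (GCaMP-like, 1 s by default), plus any
#' planted transients. Both channels share a slow exponential bleaching
#' artifact; only the 465 nm channel carries the calcium signal.
#'
#' @param config a [synth_config()] (`gain`, `delay`, `kernel_tau`,
#'   channel baselines, bleach and noise parameters).
#' @param kin a `kinematic_series` from [decompose_markers()], the shared
#'   movement drive.
#' @param seed integer seed.
#' @return List: `raw` (a [raw_photometry()]) and `truth` (gain, delay,
#'   kernel tau, component weights, planted transients, seed, config).
#' @export
gen_photometry <- function(config = synth_config(), kin, seed = 1L) {
  cfg <- config
  if (cfg$gain < 0) stop("invalid config: gain must be >= 0", call. = FALSE)
  set.seed(seed)
  t0 <- kin$time[1L]; t1 <- kin$time[nrow(kin)]
  tm <- seq(t0, t1, by = 1 / cfg$pulse_rate)
  drive <- cfg$w_translational * kin$translational +
           cfg$w_rotational * kin$rotational
  drive <- pmax(stats::approx(kin$time, drive, xout = tm, rule = 2)$y, 0)
  drive <- drive / max(mean(drive), 1e-12)        # unit-mean drive
  lag_n <- round(cfg$delay * cfg$pulse_rate)
  delayed <- c(rep(drive[1L], lag_n), drive)[seq_along(drive)]
  calcium <- cfg$gain * .conv_causal(delayed,
                                     .exp_kernel(cfg$kernel_tau,
                                                 cfg$pulse_rate))
  if (!is.null(cfg$transients)) {
    for (j in seq_along(cfg$transients$times)) {
      i0 <- which.min(abs(tm - cfg$transients$times[j]))
      kern <- .exp_kernel(max(cfg$kernel_tau, 0.2), cfg$pulse_rate)
      idx <- i0:min(length(tm), i0 + length(kern) - 1L)
      calcium[idx] <- calcium[idx] +
        cfg$transients$amps[j] * kern[seq_along(idx)] / max(kern)
    }
  }
  bleach <- exp(-(tm - t0) / cfg$bleach_tau)
  f465 <- cfg$f465_base * (1 + calcium) * bleach +
    stats::rnorm(length(tm), 0, cfg$photo_noise * cfg$f465_base)
  f405 <- cfg$f405_base * bleach +
    stats::rnorm(length(tm), 0, cfg$photo_noise * cfg$f405_base)
  raw <- raw_photometry(tm, pmax(f465, 1e-6), pmax(f405, 1e-6),
                        pulse_rate = cfg$pulse_rate)
  list(raw = raw,
       truth = list(gain = cfg$gain, delay = cfg$delay,
                    kernel_tau = cfg$kernel_tau,
                    w_translational = cfg$w_translational,
                    w_rotational = cfg$w_rotational,
                    transients = cfg$transients, seed = seed, config = cfg))
}

#' Recover the movement-to-calcium coupling gain and delay
#'
#' Matched-template estimator for the coupling planted by
#' [gen_photometry()]: the rectified movement drive is convolved with the
#' same decay-kernel family, shifted over a grid of candidate delays, and
#' the delay maximizing the correlation with dF/F is returned together
#' with the regression slope (gain) at that delay. A plain
#' cross-correlation peak would be biased late by the calcium kernel;
#' matching the kernel removes that bias.
#'
#' @param kin kinematic series providing the movement drive.
#' @param dff a `dff_trace` (uses the `dff` column).
#' @param config the [synth_config()] describing kernel tau and component
#'   weights (defaults match the generator defaults).
#' @param max_delay largest candidate delay in seconds (default 1).
#' @return List: `delay` (s), `gain` (dF/F per unit-mean drive), `r` at
#'   the best delay.
#' @export
recover_coupling <- function(kin, dff, config = synth_config(),
                             max_delay = 1) {
  cfg <- config
  rate <- cfg$pulse_rate
  drive <- cfg$w_translational * kin$translational +
           cfg$w_rotational * kin$rotational
  drive <- pmax(stats::approx(kin$time, drive, xout = dff$time,
                              rule = 2)$y, 0)
  drive <- drive / max(mean(drive), 1e-12)
  template <- .conv_causal(drive, .exp_kernel(cfg$kernel_tau, rate))
  lags <- 0:round(max_delay * rate)
  n <- length(template)
  rs <- vapply(lags, function(l) {
    if (l == 0) stats::cor(template, dff$dff)
    else stats::cor(template[1:(n - l)], dff$dff[(1 + l):n])
  }, numeric(1))
  best <- which.max(rs)
  l <- lags[best]
  xt <- if (l == 0) template else template[1:(n - l)]
  yt <- if (l == 0) dff$dff else dff$dff[(1 + l):n]
  tt <- if (l == 0) dff$time else dff$time[(1 + l):n]
  # a slow quadratic trend absorbs residual baseline misfit (the isosbestic
  # scaling can tilt dF/F by a smooth bleach-shaped factor); the fast
  # movement template then carries the coupling
  slope <- unname(stats::coef(stats::lm(yt ~ xt + stats::poly(tt, 2)))[2L])
  # dF/F is referenced to a baseline that absorbs the session-mean calcium,
  # attenuating the coupling by 1/(1 + gain * mean drive); invert that
  gain <- slope / max(1 - slope * mean(template), 0.1)
  list(delay = l / rate, gain = gain, r = rs[best])
}

#' Generate a neuron population with planted functional classes
#'
#' Each neuron is assigned a class and parameters sampled from the config
#' ranges, and its z-scored dF/F trace is generated against a shared
#' kinematic session: `movement_locked` neurons follow the movement drive
#' with a short positive lag, `anticipatory` neurons lead it,
#' `inhibited` neurons carry a negative gain, `unresponsive` neurons are
#' noise, and `nociceptive` neurons respond only to shock times. The
#' movement-responsive classes additionally carry a turn-direction
#' preference drawn from `bias_weights` (strong contraversive, weak
#' ipsiversive, or none), responding extra to rotation in their preferred
#' direction.
#'
#' @param config a [synth_config()] (`class_weights` must sum to 1).
#' @param kin shared `kinematic_series`.
#' @param seed integer seed.
#' @param shock_times times of nociceptive events (s), used by the
#'   nociceptive class (default none: those neurons stay silent).
#' @return List: `traces` (neurons x time matrix, z-scored), `time`
#'   (grid, `neuron_rate` Hz), `labels` (data frame: `neuron`, `class`,
#'   `gain`, `lag`), `truth` (config, seed).
#' @export
gen_population <- function(config = synth_config(), kin, seed = 1L,
                           shock_times = numeric(0)) {
  cfg <- config
  w <- cfg$class_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("invalid config: class_weights must be non-negative and sum to 1",
         call. = FALSE)
  set.seed(seed)
  rate <- cfg$neuron_rate
  tm <- seq(kin$time[1L], kin$time[nrow(kin)], by = 1 / rate)
  drive <- pmax(stats::approx(kin$time, kin$overall, xout = tm,
                              rule = 2)$y, 0)
  drive <- scale(drive)[, 1L]
  kern <- .exp_kernel(cfg$neuron_tau, rate)
  cls <- sample(names(w), cfg$n_neurons, replace = TRUE, prob = w)
  nt <- length(tm)
  shift <- function(x, lag_s) {                 # positive lag delays the trace
    l <- round(lag_s * rate)
    if (l > 0) c(rep(x[1L], l), x)[seq_len(nt)]
    else if (l < 0) c(x[(-l + 1L):nt], rep(x[nt], -l))
    else x
  }
  # signed rotation, contraversive-positive for the session's implant side
  dang <- c(0, diff(kin$head_angle))
  srot <- stats::approx(kin$time, dang * attr(kin, "frame_rate"), xout = tm,
                        rule = 2)$y
  if (identical(attr(kin, "implant_side"), "left")) srot <- -srot
  contra_drive <- scale(pmax(srot, 0))[, 1L]
  ipsi_drive <- scale(pmax(-srot, 0))[, 1L]
  bias_cls <- sample(names(cfg$bias_weights), cfg$n_neurons, replace = TRUE,
                     prob = cfg$bias_weights)
  gains <- stats::runif(cfg$n_neurons, cfg$neuron_gain[1L], cfg$neuron_gain[2L])
  lags <- numeric(cfg$n_neurons)
  traces <- matrix(0, cfg$n_neurons, nt)
  for (i in seq_len(cfg$n_neurons)) {
    sig <- switch(cls[i],
      movement_locked = { lags[i] <- cfg$neuron_lag
        gains[i] * .conv_causal(shift(drive, lags[i]), kern) },
      anticipatory = { lags[i] <- -cfg$anticipatory_lead
        gains[i] * .conv_causal(shift(drive, lags[i]), kern) },
      inhibited = { lags[i] <- cfg$neuron_lag
        -0.6 * gains[i] * .conv_causal(shift(drive, lags[i]), kern) },
      unresponsive = { gains[i] <- 0; numeric(nt) },
      nociceptive = {
        s <- numeric(nt)
        for (ts in shock_times) {
          i0 <- which.min(abs(tm - ts))
          kk <- .exp_kernel(0.5, rate)
          idx <- i0:min(nt, i0 + length(kk) - 1L)
          s[idx] <- s[idx] + gains[i] * 3 * kk[seq_along(idx)] / max(kk)
        }
        s
      })
    # turn-direction preference rides on top of the class response
    # (silent classes stay silent)
    if (cls[i] %in% c("movement_locked", "anticipatory", "inhibited")) {
      bdrive <- switch(bias_cls[i], contra = contra_drive,
                       ipsi = ipsi_drive, none = NULL)
      if (!is.null(bdrive))
        sig <- sig + cfg$bias_strength[[bias_cls[i]]] *
          .conv_causal(shift(bdrive, max(lags[i], 0)), kern)
    }
    traces[i, ] <- sig + stats::rnorm(nt, 0, cfg$neuron_noise)
  }
  traces <- t(apply(traces, 1L, function(v) (v - mean(v)) / stats::sd(v)))
  list(traces = traces, time = tm,
       labels = data.frame(neuron = seq_len(cfg$n_neurons), class = cls,
                           bias = ifelse(cls %in% c("movement_locked",
                                                    "anticipatory",
                                                    "inhibited"),
                                         bias_cls, "none"),
                           gain = gains, lag = lags,
                           stringsAsFactors = FALSE),
       truth = list(seed = seed, config = cfg, shock_times = shock_times))
}

.mode_latency_sampler <- function(cfg, modes) {
  pmax(stats::rnorm(length(modes),
                    cfg$mode_latency_mean[modes],
                    cfg$mode_latency_sd[modes]), 0.3)
}

#' Generate an avoidance session from mode-structured agents
#'
#' Draws a response mode (1-3) per trial from the configured mixture,
#' samples the crossing latency from that mode's distribution, runs the
#' session through [run_session()], and emits a CS-aligned speed trace
#' per trial: a mode-specific pre-CS baseline speed, an orienting bump at
#' CS onset scaled per mode (large for Modes 1-2, minimal for Mode 3),
#' and a locomotor burst at the response time.
#'
#' @param config a [synth_config()] (`procedure`, `n_trials`,
#'   `mode_mixture` and the per-mode latency/speed parameters).
#' @param seed integer seed.
#' @return List: `log` (a `session_log`), `speed` (trials x time matrix,
#'   cm/s), `time` (grid relative to CS onset), `truth` (per-trial mode,
#'   latencies, config, seed).
#' @export
gen_behavior <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  if (any(cfg$mode_mixture < 0) || abs(sum(cfg$mode_mixture) - 1) > 1e-8)
    stop("invalid config: mode_mixture must be non-negative and sum to 1",
         call. = FALSE)
  set.seed(seed)
  modes <- sample.int(3L, cfg$n_trials, replace = TRUE,
                      prob = cfg$mode_mixture)
  lat <- .mode_latency_sampler(cfg, modes)
  i_env <- new.env(); i_env$i <- 0L
  agent <- agent_policy(
    latency = function(n) {
      out <- lat[i_env$i + seq_len(n)]
      i_env$i <- i_env$i + n
      out
    },
    itc_rate = cfg$itc_rate)
  spec <- trial_spec(cfg$procedure)
  log <- run_session(spec, agent, cfg$n_trials, seed = seed + 1L)

  tt <- seq(cfg$trial_span[1L], cfg$trial_span[2L], by = 1 / cfg$trial_rate)
  speed <- matrix(0, cfg$n_trials, length(tt))
  for (i in seq_len(cfg$n_trials)) {
    m <- modes[i]
    resp_t <- if (log$response[i] == "avoid") log$latency[i]
              else spec$cs$avoidance_interval[1L] + 0.3
    tr <- cfg$mode_baseline_speed[m] +
      cfg$mode_orient_amp[m] * exp(-(tt - 0.25)^2 / (2 * 0.15^2)) +
      cfg$response_burst_amp * exp(-(tt - resp_t)^2 / (2 * 0.4^2)) +
      stats::rnorm(length(tt), 0, cfg$trial_noise)
    speed[i, ] <- pmax(tr, 0)
  }
  list(log = log, speed = speed, time = tt,
       truth = list(modes = modes, latencies = lat, seed = seed,
                    config = cfg))
}

#' Generate a trial table with planted mixed-model effects
#'
#' Builds the long-format table consumed by the windowed mixed-effects
#' analysis, with known ground truth: the response is
#' `slope * speed + outcome effect * [escape] + session intercept +
#' noise`, sessions nested within subjects. Used for parameter-recovery
#' and coverage tests of the modelling layer.
#'
#' @param n_subjects,sessions_per_subject,trials_per_session design size.
#' @param slope true speed coefficient (default 1).
#' @param outcome_effect true escape-minus-avoid effect (default 0.5).
#' @param subject_sd,session_sd,noise_sd variance components (defaults
#'   0.3, 0.3, 1).
#' @param seed integer seed.
#' @return List: `table` (data frame: `subject`, `session`, `outcome`,
#'   `speed`, `dff`), `truth` (the planted parameters).
#' @export
gen_trial_table <- function(n_subjects = 8, sessions_per_subject = 5,
                            trials_per_session = 20, slope = 1,
                            outcome_effect = 0.5, subject_sd = 0.3,
                            session_sd = 0.3, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  rows <- expand.grid(trial = seq_len(trials_per_session),
                      session = seq_len(sessions_per_subject),
                      subject = seq_len(n_subjects))
  n <- nrow(rows)
  subj_eff <- stats::rnorm(n_subjects, 0, subject_sd)
  ses_eff <- stats::rnorm(n_subjects * sessions_per_subject, 0, session_sd)
  ses_key <- (rows$subject - 1L) * sessions_per_subject + rows$session
  speed <- stats::rnorm(n, 0, 1)
  outcome <- ifelse(stats::runif(n) < 0.5, "avoid", "escape")
  dff <- slope * speed + outcome_effect * (outcome == "escape") +
    subj_eff[rows$subject] + ses_eff[ses_key] + stats::rnorm(n, 0, noise_sd)
  list(table = data.frame(subject = paste0("m", rows$subject),
                          session = paste0("s", rows$session),
                          outcome = outcome, speed = speed, dff = dff,
                          stringsAsFactors = FALSE),
       truth = list(slope = slope, outcome_effect = outcome_effect,
                    subject_sd = subject_sd, session_sd = session_sd,
                    noise_sd = noise_sd, seed = seed))
}
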