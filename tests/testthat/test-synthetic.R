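test_that("generators are deterministic in (config, seed) and validate configs", {
  cfg <- synth_config(duration = 30, n_turns = 4, n_bouts = 3)
  a <- gen_tracking(cfg, seed = 5)
  b <- gen_tracking(cfg, seed = 5)
  expect_identical(a, b)
  c <- gen_tracking(cfg, seed = 6)
  expect_false(identical(a$track$nose, c$track$nose))

  kin <- decompose_markers(a$track)
  p1 <- gen_photometry(cfg, kin, seed = 7)
  p2 <- gen_photometry(cfg, kin, seed = 7)
  expect_identical(p1, p2)

  expect_error(synth_config(not_a_key = 1), "unknown config key")
  expect_error(gen_tracking(synth_config(duration = -1)), "positive")
  expect_error(gen_photometry(synth_config(gain = -1), kin), "gain")
  expect_error(gen_population(synth_config(
    class_weights = c(movement_locked = 0.5, anticipatory = 0.2,
                      inhibited = 0, unresponsive = 0, nociceptive = 0)),
    kin), "sum to 1")
  expect_error(gen_behavior(synth_config(mode_mixture = c(0.5, 0.2, 0.1))),
               "sum to 1")
})

test_that("a zero-noise, zero-event config produces stationary markers", {
  cfg <- synth_config(duration = 10, n_turns = 0, n_bouts = 0,
                      heading_noise_deg = 0, base_speed = 0, speed_noise = 0)
  trk <- gen_tracking(cfg, seed = 1)
  kin <- decompose_markers(trk$track)
  expect_equal(max(kin$overall), 0, tolerance = 1e-12)
  expect_equal(max(abs(diff(kin$head_angle))), 0, tolerance = 1e-12)
})

test_that("planted turns are detected with high recall and few false alarms", {
  trk <- gen_tracking(synth_config(), seed = 2)
  kin <- decompose_markers(trk$track)
  turns <- detect_peaks(kin$time, kin$head_angle, kind = "turn")
  tt <- trk$truth$turn_times
  # the post-turn extremum settles within a few seconds of the ramp start
  recall <- mean(vapply(tt, function(x)
    any(turns$time >= x - 0.5 & turns$time <= x + 3), logical(1)))
  fp <- sum(!vapply(turns$time, function(dt)
    any(dt >= tt - 0.5 & dt <= tt + 3), logical(1)))
  expect_gte(recall, 0.95)
  expect_lte(fp, 1)
})

test_that("movement-coupled photometry carries the planted gain and delay", {
  cfg <- synth_config(duration = 120)
  trk <- gen_tracking(cfg, seed = 3)
  kin <- decompose_markers(trk$track)
  pho <- gen_photometry(cfg, kin, seed = 4)
  d <- compute_dff(pho$raw, fit_isosbestic(pho$raw))
  rc <- recover_coupling(kin, d, cfg)
  expect_equal(rc$delay, cfg$delay, tolerance = 1 / cfg$pulse_rate + 1e-9)
  expect_lt(abs(rc$gain - cfg$gain) / cfg$gain, 0.05)

  # gain zero: dF/F is pure noise, uncoupled to movement (full-length
  # session so slow baseline residuals average out)
  cfg0 <- synth_config(gain = 0)
  trk0 <- gen_tracking(cfg0, seed = 3)
  kin0 <- decompose_markers(trk0$track)
  pho0 <- gen_photometry(cfg0, kin0, seed = 5)
  d0 <- compute_dff(pho0$raw, fit_isosbestic(pho0$raw))
  sp <- approx(kin0$time, kin0$overall, xout = d0$time, rule = 2)$y
  fit0 <- integrated_linear_fit(sp, d0$dff, sample_rate = cfg0$pulse_rate)
  expect_lt(abs(fit0$r), 0.05)
})

test_that("planted neuron classes are recovered by the classification schemes", {
  cfg <- synth_config(duration = 180,
                      class_weights = c(movement_locked = 0.4,
                                        anticipatory = 0.3,
                                        inhibited = 0, unresponsive = 0.3,
                                        nociceptive = 0),
                      n_neurons = 60)
  trk <- gen_tracking(cfg, seed = 6)
  kin <- decompose_markers(trk$track)
  pop <- gen_population(cfg, kin, seed = 7)
  sp <- approx(kin$time, kin$overall, xout = pop$time, rule = 2)$y
  ccs <- lapply(seq_len(nrow(pop$traces)), function(i)
    cross_correlate(sp, pop$traces[i, ], max_lag = 2,
                    sample_rate = cfg$neuron_rate))
  asg <- classify_crosscorr(ccs, k = 3, seed = 8)
  expect_equal(ari(asg$labels, pop$labels$class), 1)
  # the anticipatory class leads: its mean peak lag matches the planted lead
  lead_class <- names(which.min(asg$class_mean_lag))
  lead_truth <- unique(pop$labels$class[asg$labels == lead_class])
  expect_equal(lead_truth, "anticipatory")
  expect_lt(abs(asg$class_mean_lag[[lead_class]] + cfg$anticipatory_lead),
            0.05)

  # a 100 % unresponsive population has no coupling structure at all
  cfg_u <- synth_config(duration = 60,
                        class_weights = c(movement_locked = 0,
                                          anticipatory = 0, inhibited = 0,
                                          unresponsive = 1, nociceptive = 0),
                        n_neurons = 30)
  pop_u <- gen_population(cfg_u, kin, seed = 9)
  sp_u <- approx(kin$time, kin$overall, xout = pop_u$time, rule = 2)$y
  ccs_u <- lapply(seq_len(nrow(pop_u$traces)), function(i)
    cross_correlate(sp_u, pop_u$traces[i, ], max_lag = 2,
                    sample_rate = cfg_u$neuron_rate))
  asg_u <- classify_crosscorr(ccs_u, k = 3, seed = 10,
                              noise_floor = 0.3)
  expect_equal(asg_u$effective_k, 1L)
})

test_that("planted turn-direction preferences surface in the bias traces", {
  cfg <- synth_config(duration = 240, n_turns = 24,
                      class_weights = c(movement_locked = 1,
                                        anticipatory = 0, inhibited = 0,
                                        unresponsive = 0, nociceptive = 0),
                      n_neurons = 45)
  trk <- gen_tracking(cfg, seed = 20)
  kin <- decompose_markers(trk$track)
  pop <- gen_population(cfg, kin, seed = 21)
  turns <- label_direction(detect_peaks(kin$time, kin$head_angle,
                                        kind = "turn"),
                           trk$track$implant_side)
  contra_t <- turns$time[turns$side_label == "contraversive"]
  ipsi_t <- turns$time[turns$side_label == "ipsiversive"]
  snips <- function(times) lapply(seq_len(nrow(pop$traces)), function(i)
    extract_snippets(pop$time, pop$traces[i, ], times, span = c(-2, 2),
                     sample_rate = cfg$neuron_rate))
  b <- turn_bias(snips(contra_t), snips(ipsi_t))
  mean_bias <- tapply(b$peak_bias, pop$labels$bias[b$neuron], mean)
  # contraversive-preferring neurons carry the largest positive bias
  expect_gt(mean_bias[["contra"]], mean_bias[["none"]])
  expect_gt(mean_bias[["contra"]], 0.3)
  expect_lt(mean_bias[["ipsi"]], mean_bias[["none"]])
})

test_that("mode-structured behavior reproduces its mixture and latency order", {
  cfg <- synth_config(n_trials = 300)
  beh <- gen_behavior(cfg, seed = 11)
  av <- beh$log$response == "avoid"
  asg <- classify_modes(beh$speed[av, ], beh$log$latency[av], k = 3, seed = 1)
  # recovered mixture weights within 5 points of the planted weights
  got <- as.numeric(table(asg$labels)) / sum(av)
  want <- as.numeric(table(beh$truth$modes[av])) / sum(av)
  expect_lt(max(abs(got - want)), 0.05)
  # latency ordering: Mode 1 earliest
  expect_true(all(diff(asg$mode_latency) > 0))
})
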