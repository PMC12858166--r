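test_that("snippet extraction resamples, averages and excludes edge events", {
  tm <- seq(0, 100, by = 0.05)
  # constant trace: every snippet constant, SEM zero
  m0 <- extract_snippets(tm, rep(2, length(tm)), c(10, 40, 70), span = c(-3, 3))
  expect_true(all(m0 == 2))
  expect_equal(snippet_mean(m0)$sem, rep(0, ncol(m0)))

  # planted Gaussian transient at each event reproduces the template
  template <- function(dt) exp(-dt^2 / (2 * 0.4^2))
  ev <- c(20, 50, 80)
  x <- rowSums(vapply(ev, function(e) template(tm - e), numeric(length(tm))))
  m1 <- extract_snippets(tm, x, ev, span = c(-3, 3), sample_rate = 20)
  avg <- snippet_mean(m1)
  expect_lt(max(abs(avg$mean - template(avg$time))), 1e-3)
  expect_equal(avg$time[which.max(avg$mean)], 0)

  # events too close to the record edge are dropped and counted
  ev2 <- c(1, 20, 50, 99.5)
  m2 <- extract_snippets(tm, x, ev2, span = c(-3, 3))
  expect_equal(nrow(m2), 2)
  expect_equal(attr(m2, "n_dropped"),
               sum(ev2 - 3 < tm[1] | ev2 + 3 > tm[length(tm)]))
  # zero usable events: empty result, not an error
  m3 <- extract_snippets(tm, x, numeric(0), span = c(-3, 3))
  expect_equal(nrow(m3), 0)
})

test_that("window measures give closed-form rates, corrections and extrema", {
  grid_rate <- 100
  tm <- seq(-1, 8, by = 1 / grid_rate)
  wins <- window_presets()

  # constant trace c: baseline rate c, all corrected rates 0
  mc <- extract_snippets(tm, rep(3.5, length(tm)), 0, span = c(-1, 8),
                         sample_rate = grid_rate)
  wm <- window_measures(mc, wins[c("baseline", "orienting", "avoid")])
  expect_equal(wm$area_rate[wm$window == "baseline"], 3.5, tolerance = 1e-9)
  expect_equal(wm$area_rate[wm$window == "orienting"], 0, tolerance = 1e-9)
  expect_equal(wm$area_rate[wm$window == "avoid"], 0, tolerance = 1e-9)

  # unit ramp from CS onset: orienting rate = mean of ramp = 0.25
  ramp <- pmax(tm, 0)
  mr <- extract_snippets(tm, ramp, 0, span = c(-1, 8), sample_rate = grid_rate)
  wr <- window_measures(mr, wins[c("baseline", "orienting")])
  expect_equal(wr$area_rate[wr$window == "orienting"], 0.25, tolerance = 1e-6)
  expect_false(wr$baseline_corrected[wr$window == "baseline"])
  expect_true(wr$baseline_corrected[wr$window == "orienting"])

  # negative deflection: the extremum is the minimum
  dip <- -exp(-(tm - 1)^2 / (2 * 0.2^2))
  md <- extract_snippets(tm, dip, 0, span = c(-1, 8), sample_rate = grid_rate)
  wd <- window_measures(md, wins[c("baseline", "avoid")])
  expect_lt(wd$peak[wd$window == "avoid"], 0)
  expect_equal(wd$time_to_peak[wd$window == "avoid"], 1, tolerance = 0.02)

  expect_error(window_measures(mc, list(baseline = c(-0.5, 0),
                                        far = c(20, 30))), "outside")
})

test_that("adjacent window areas combine as duration-weighted means", {
  set.seed(21)
  tm <- seq(-1, 8, by = 0.01)
  x <- cumsum(rnorm(length(tm), 0, 0.1))
  m <- extract_snippets(tm, x, 0, span = c(-1, 8), sample_rate = 100)
  parts <- window_measures(m, list(a = c(0, 2), b = c(2, 5), ab = c(0, 5)),
                           baseline_correct = FALSE)
  a <- parts$area_rate[parts$window == "a"]
  b <- parts$area_rate[parts$window == "b"]
  ab <- parts$area_rate[parts$window == "ab"]
  expect_equal(ab, (2 * a + 3 * b) / 5, tolerance = 1e-9)
})

test_that("cross-correlation finds planted lags and satisfies symmetry", {
  set.seed(22)
  n <- 4000; rate <- 20
  x <- as.numeric(stats::filter(rnorm(n), rep(1, 8) / 8, sides = 1))
  x[is.na(x)] <- 0
  expect_equal(cross_correlate(x, x, 2, rate)$peak_lag, 0)
  expect_equal(max(cross_correlate(x, x, 2, rate)$r), 1, tolerance = 1e-9)

  # dff delayed 300 ms behind speed: peak lag +0.30 within one sample
  shift <- round(0.3 * rate)
  y <- c(rep(0, shift), x[1:(n - shift)]) + rnorm(n, 0, 0.05)
  cc <- cross_correlate(x, y, 2, rate)
  expect_lte(abs(cc$peak_lag - 0.3), 1 / rate + 1e-9)

  # symmetry: r_xy(l) == r_yx(-l)
  cc_xy <- cross_correlate(x, y, 1, rate)
  cc_yx <- cross_correlate(y, x, 1, rate)
  expect_equal(cc_xy$r, rev(cc_yx$r), tolerance = 1e-12)

  # independent white noise stays inside the sampling bound
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(max(abs(cross_correlate(a, b, 1, rate)$r)), 0.05)
  expect_error(cross_correlate(rep(1, 100), rnorm(100), 1, rate), "constant")
})

test_that("200-ms-integrated linear fits recover exact and noisy couplings", {
  set.seed(23)
  rate <- 20
  x <- abs(rnorm(1000, 5, 2))
  exact <- integrated_linear_fit(x, 2 * x, sample_rate = rate)
  expect_equal(exact$slope, 2, tolerance = 1e-9)
  expect_equal(exact$r, 1, tolerance = 1e-9)

  n <- 5000 * round(0.2 * rate)            # 5000 bins
  xs <- rnorm(n)
  ys <- 1.5 * xs + rnorm(n)
  fit <- integrated_linear_fit(xs, ys, sample_rate = rate)
  expect_equal(fit$n_bins, 5000)
  expect_lt(abs(fit$slope - 1.5) / 1.5, 0.05)
})

test_that("circular-shift shuffles separate coupled from independent pairs", {
  set.seed(24)
  n <- 2400; rate <- 20
  x <- as.numeric(stats::filter(rnorm(n), rep(1, 10) / 10, sides = 1))
  x[is.na(x)] <- 0
  y_coupled <- x + rnorm(n, 0, 0.3)
  sc <- shuffle_control(x, y_coupled, n_shuffles = 200, seed = 1,
                        sample_rate = rate)
  expect_gt(sc$observed, sc$q975)
  expect_lt(sc$p, 0.05)

  y_indep <- as.numeric(stats::filter(rnorm(n), rep(1, 10) / 10, sides = 1))
  y_indep[is.na(y_indep)] <- 0
  sc0 <- shuffle_control(x, y_indep, n_shuffles = 200, seed = 2,
                         sample_rate = rate)
  expect_lt(abs(sc0$observed), max(abs(sc0$null)))
  expect_gt(sc0$p, 0.05)

  expect_error(shuffle_control(x, y_indep, n_shuffles = 0), ">= 100")
  expect_error(shuffle_control(x[1:100], y_indep[1:100], n_shuffles = 100,
                               sample_rate = rate), "too short")
  # reproducible per seed
  sc1 <- shuffle_control(x, y_coupled, n_shuffles = 100, seed = 5,
                         sample_rate = rate)
  sc2 <- shuffle_control(x, y_coupled, n_shuffles = 100, seed = 5,
                         sample_rate = rate)
  expect_identical(sc1$null, sc2$null)
})
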