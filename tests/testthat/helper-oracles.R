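# Independent oracles used across the suite. Each re-derives its answer
# from first principles (exact geometry, naive scans, direct recounts)
# rather than calling the code path under test.

# Build a marker_track from known per-frame geometry: heading angles
# (radians), ears displacement magnitudes and displacement-vs-midline
# angles. Returns the track plus the analytic speeds it must decompose to.
rigid_trajectory <- function(dtheta, disp_len, disp_phi, midline = 1.5,
                             fps = 50, theta0 = 0) {
  n <- length(dtheta) + 1L
  heading <- theta0 + cumsum(c(0, dtheta))
  ears <- matrix(0, n, 2)
  for (i in 2:n) {
    # displacement makes angle disp_phi with the midline of frame i-1
    phi <- heading[i - 1L] + disp_phi[i - 1L]
    ears[i, ] <- ears[i - 1L, ] +
      disp_len[i - 1L] * c(cos(phi), sin(phi))
  }
  nose <- ears + midline * cbind(cos(heading), sin(heading))
  tm <- seq(0, by = 1 / fps, length.out = n)
  list(track = marker_track(tm, nose, ears, frame_rate = fps),
       rotational = abs(dtheta) * midline * fps,
       linear = disp_len * cos(disp_phi) * fps,
       sideways = disp_len * sin(disp_phi) * fps)
}

# Naive O(n*w) extremum scan implementing the detection definition
# directly: strict extremum over +-w samples (ties to earliest), edge
# regions excluded, magnitude referenced to the nearest preceding
# opposite-sign candidate (or the first sample).
brute_force_peaks <- function(time, x, half_window = 0.5, min_delta = 10) {
  dt <- median(diff(time))
  w <- max(1L, round(half_window / dt))
  n <- length(x)
  idx <- integer(0); sgn <- integer(0)
  for (i in seq_along(x)) {
    if (i <= w || i > n - w) next
    lo <- i - w; hi <- i + w
    is_max <- TRUE; is_min <- TRUE
    for (j in lo:hi) {
      if (j == i) next
      if (x[j] > x[i] || (x[j] == x[i] && j < i)) is_max <- FALSE
      if (x[j] < x[i] || (x[j] == x[i] && j < i)) is_min <- FALSE
    }
    if (is_max) { idx <- c(idx, i); sgn <- c(sgn, 1L) }
    else if (is_min) { idx <- c(idx, i); sgn <- c(sgn, -1L) }
  }
  keep_t <- numeric(0); keep_m <- numeric(0)
  for (j in seq_along(idx)) {
    ref <- x[1L]
    for (q in rev(seq_len(j - 1L)))
      if (sgn[q] != sgn[j]) { ref <- x[idx[q]]; break }
    m <- x[idx[j]] - ref
    if (abs(m) > min_delta) {
      keep_t <- c(keep_t, time[idx[j]]); keep_m <- c(keep_m, m)
    }
  }
  data.frame(time = keep_t, magnitude = keep_m)
}

# Angle trace with planted step-like turns on a flat baseline.
planted_turn_trace <- function(turn_times, amps, duration = 30, fps = 40) {
  tm <- seq(0, duration, by = 1 / fps)
  x <- numeric(length(tm))
  for (k in seq_along(turn_times)) {
    ramp <- pmin(pmax((tm - turn_times[k]) / 0.2, 0), 1)
    x <- x + amps[k] * ramp
  }
  list(time = tm, x = x)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Three well-separated Gaussian feature blobs with known labels.
blob_features <- function(n_per = 30, sep = 12, d = 4, sd = 0.5) {
  centers <- rbind(rep(0, d), c(sep, rep(0, d - 1)), c(0, sep, rep(0, d - 2)))
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * d, mean = rep(centers[k, ], each = n_per), sd = sd),
           n_per, d)))
  list(x = x, labels = rep(1:3, each = n_per))
}
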