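#' Analysis-window presets
#'
#' The windows used throughout the windowed analyses, in seconds relative
#' to the alignment event: `baseline` (-0.5-0 s pre-CS), `orienting`
#' (0-0.5 s post-CS), `avoid` (0.5-7 s post-CS), `from_action` (-2-2 s
#' around the action; the single-cell miniscope variant spans -3.5-3 s)
#' and `escape` (0-4 s after US onset).
#'
#' @param miniscope logical; use the wider from-action window.
#' @return Named list of `c(start, end)` windows (s).
#' @export
window_presets <- function(miniscope = FALSE) {
  list(baseline = c(-0.5, 0),
       orienting = c(0, 0.5),
       avoid = c(0.5, 7),
       from_action = if (miniscope) c(-3.5, 3) else c(-2, 2),
       escape = c(0, 4))
}

#' Extract event-aligned snippets from a continuous trace
#'
#' Resamples a trace onto a common time grid around each event (linear
#' interpolation) and stacks the segments into an events-by-time matrix.
#' Events whose full span does not fit inside the recording are dropped
#' and counted, not errors.
#'
#' @param time sample times of the trace (s).
#' @param x trace values (z-scored dF/F, speed in cm/s, ...).
#' @param event_times alignment times (s); time 0 of each snippet.
#' @param span `c(before, after)` in seconds (before negative), or a
#'   single positive number for a symmetric span.
#' @param sample_rate output grid rate in Hz (default 20).
#' @param alignment label recorded on the result (`"cs_onset"`,
#'   `"action"`, `"us_onset"`, ...).
#' @return A `snippet_matrix`: numeric matrix (events x time) with
#'   attributes `grid` (relative times, 0 at alignment), `alignment`,
#'   `sample_rate`, `event_times` (the retained events) and `n_dropped`.
#'   Zero usable events yield a 0-row matrix, not an error.
#' @export
extract_snippets <- function(time, x, event_times, span = c(-3, 3),
                             sample_rate = 20, alignment = "event") {
  if (length(span) == 1L) span <- c(-abs(span), abs(span))
  grid <- seq(span[1L], span[2L], by = 1 / sample_rate)
  ok <- event_times + span[1L] >= time[1L] &
        event_times + span[2L] <= time[length(time)]
  kept <- event_times[ok]
  mat <- if (length(kept)) {
    t(vapply(kept, function(t0)
      stats::approx(time, x, xout = t0 + grid)$y, numeric(length(grid))))
  } else {
    matrix(numeric(0), nrow = 0, ncol = length(grid))
  }
  structure(mat, grid = grid, alignment = alignment,
            sample_rate = sample_rate, event_times = kept,
            n_dropped = sum(!ok), class = c("snippet_matrix", "matrix"))
}

#' Mean and SEM across events of a snippet matrix
#'
#' @param mat a `snippet_matrix`.
#' @return Data frame with `time`, `mean`, `sem` (SEM uses n-1).
#' @export
snippet_mean <- function(mat) {
  n <- nrow(mat)
  data.frame(time = attr(mat, "grid"),
             mean = colMeans(mat),
             sem = if (n > 1) apply(mat, 2, stats::sd) / sqrt(n)
                   else rep(NA_real_, ncol(mat)))
}

.trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

#' Windowed area-rate, peak and time-to-peak measures
#'
#' For each event (row) of a snippet matrix and each named analysis
#' window, computes the trapezoidal area divided by the window duration
#' (an area rate in trace units), the extremum within the window (the
#' peak, by largest absolute value, so inhibitory deflections report their
#' minimum) and its time relative to the alignment. Windows other than
#' the baseline are corrected by subtracting the baseline-window rate; the
#' baseline window itself is never corrected.
#'
#' @param mat a `snippet_matrix`.
#' @param windows named list of `c(start, end)` windows (s), e.g.
#'   [window_presets()]; must include `"baseline"` when
#'   `baseline_correct = TRUE`.
#' @param baseline_correct logical (default `TRUE`).
#' @return Long data frame: `event`, `window`, `area_rate`,
#'   `baseline_corrected`, `peak`, `time_to_peak`.
#' @export
window_measures <- function(mat, windows = window_presets(),
                            baseline_correct = TRUE) {
  grid <- attr(mat, "grid")
  for (w in windows)
    if (w[1L] < grid[1L] - 1e-9 || w[2L] > grid[length(grid)] + 1e-9)
      stop("window outside the snippet span", call. = FALSE)
  if (baseline_correct && !"baseline" %in% names(windows))
    stop("baseline correction requested but no 'baseline' window given",
         call. = FALSE)

  one <- function(ev) {
    y <- mat[ev, ]
    base_rate <- if (baseline_correct) {
      w <- windows[["baseline"]]
      sel <- grid >= w[1L] - 1e-9 & grid <= w[2L] + 1e-9
      .trapz(grid[sel], y[sel]) / (w[2L] - w[1L])
    } else 0
    do.call(rbind, lapply(names(windows), function(nm) {
      w <- windows[[nm]]
      sel <- grid >= w[1L] - 1e-9 & grid <= w[2L] + 1e-9
      rate <- .trapz(grid[sel], y[sel]) / (w[2L] - w[1L])
      corrected <- baseline_correct && nm != "baseline"
      v <- y[sel] - if (corrected) base_rate else 0
      pk <- which.max(abs(v))
      data.frame(event = ev, window = nm,
                 area_rate = rate - if (corrected) base_rate else 0,
                 baseline_corrected = corrected,
                 peak = v[pk],
                 time_to_peak = grid[sel][pk],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(mat)), one))
  rownames(out) <- NULL
  out
}

#' Lagged Pearson cross-correlation between movement and neural activity
#'
#' Pearson correlation of two equal-rate series at every integer-sample
#' lag up to `max_lag` seconds. Positive lags mean the second series
#' (e.g. dF/F) follows the first (e.g. speed).
#'
#' @param x reference series (movement speed).
#' @param y comparison series (dF/F).
#' @param max_lag maximum lag in seconds.
#' @param sample_rate common sampling rate in Hz.
#' @return A `crosscorr_result` list: `lags` (s), `r`, `peak_lag` (lag of
#'   the largest |r|), `peak_r`.
#' @export
cross_correlate <- function(x, y, max_lag = 2, sample_rate = 20) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length", call. = FALSE)
  L <- round(max_lag * sample_rate)
  if (n <= 2L * L) stop("series shorter than twice the maximum lag", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  lags <- seq.int(-L, L)
  r <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(x[1:(n - l)], y[(1 + l):n])
    else stats::cor(x[(1 - l):n], y[1:(n + l)])
  }, numeric(1))
  pk <- which.max(abs(r))
  structure(list(lags = lags / sample_rate, r = r,
                 peak_lag = lags[pk] / sample_rate, peak_r = r[pk]),
            class = "crosscorr_result")
}

#' Linear fit between series integrated over 200-ms bins
#'
#' Both series are boxcar-averaged over non-overlapping bins (200 ms by
#' default) and a least-squares line of the second on the first is fit;
#' the correlation of the binned pairs is reported.
#'
#' @param x,y equal-length, equal-rate series.
#' @param window integration window in seconds (default 0.2).
#' @param sample_rate sampling rate in Hz.
#' @return List: `slope`, `intercept`, `r`, `n_bins`.
#' @export
integrated_linear_fit <- function(x, y, window = 0.2, sample_rate = 20) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length", call. = FALSE)
  w <- max(1L, round(window * sample_rate))
  nb <- n %/% w
  if (nb < 3L) stop("too few bins for a linear fit", call. = FALSE)
  idx <- rep(seq_len(nb), each = w)
  xb <- tapply(x[seq_len(nb * w)], idx, mean)
  yb <- tapply(y[seq_len(nb * w)], idx, mean)
  if (stats::sd(xb) == 0 || stats::sd(yb) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  fit <- stats::lm(yb ~ xb)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(xb, yb), n_bins = nb)
}

#' Circular-shift shuffle control for a paired-series statistic
#'
#' Builds a null distribution for the coupling between two series by
#' circularly shifting one of them by a random offset of at least
#' `min_offset` seconds and recomputing the statistic. The circular shift
#' preserves each series' autocorrelation, giving a conservative null for
#' autocorrelated signals.
#'
#' @param x,y equal-length series.
#' @param n_shuffles number of shuffles (>= 100).
#' @param seed integer seed.
#' @param statistic function `(x, y) -> scalar`; defaults to the
#'   correlation of the 200-ms-integrated pairs.
#' @param min_offset minimum circular offset in seconds (default 5).
#' @param sample_rate sampling rate in Hz.
#' @return List: `observed`, `null` (length `n_shuffles`), `p` (two-sided
#'   empirical, with the +1 correction), `q975` (97.5th null percentile).
#' @export
shuffle_control <- function(x, y, n_shuffles = 200, seed = 1L,
                            statistic = NULL, min_offset = 5,
                            sample_rate = 20) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100", call. = FALSE)
  n <- length(x)
  off_min <- round(min_offset * sample_rate)
  if (n <= 2L * off_min)
    stop("series too short for the minimum circular offset", call. = FALSE)
  if (is.null(statistic))
    statistic <- function(x, y)
      integrated_linear_fit(x, y, sample_rate = sample_rate)$r
  set.seed(seed)
  observed <- statistic(x, y)
  offsets <- sample.int(n - 2L * off_min, n_shuffles, replace = TRUE) + off_min
  null <- vapply(offsets, function(k) {
    ys <- c(y[(k + 1L):n], y[1:k])
    statistic(x, ys)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_shuffles + 1)
  list(observed = observed, null = null, p = p,
       q975 = stats::quantile(null, 0.975, names = FALSE))
}
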