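#' Construct a dual-excitation raw photometry object
#'
#' Holds per-pulse peak emissions evoked by alternating 465 nm
#' (calcium-sensitive) and 405 nm (isosbestic, calcium-insensitive)
#' excitation pulses, as produced by an interleaved fiber-photometry
#' system.
#'
#' @param time sample times in seconds, strictly increasing.
#' @param f465 peak emission per 465 nm pulse (arbitrary units, > 0).
#' @param f405 peak emission per 405 nm pulse (a.u., > 0).
#' @param pulse_rate pulse-pair rate in Hz (default 100).
#'
#' @return An object of class `raw_photometry`.
#' @export
raw_photometry <- function(time, f465, f405, pulse_rate = 100) {
  n <- length(time)
  if (length(f465) != n || length(f405) != n)
    stop("time, f465 and f405 must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(f465 <= 0) || any(f405 <= 0))
    stop("emissions must be positive", call. = FALSE)
  structure(list(time = time, f465 = f465, f405 = f405,
                 pulse_rate = pulse_rate),
            class = "raw_photometry")
}

#' Scale the isosbestic channel to the calcium channel
#'
#' Least-squares fit of the 465 nm emissions on the 405 nm emissions; the
#' fitted values provide the movement/bleaching baseline F0 used for dF/F.
#' By default the fit includes an intercept (robust to additive offsets
#' between channels); a slope-only fit through the origin is available.
#'
#' @param raw a [raw_photometry()].
#' @param intercept logical; fit an intercept (default `TRUE`) or force it
#'   to zero.
#'
#' @return An object of class `baseline_fit` with elements `slope`,
#'   `intercept`, `f0` (fitted control series, same length as the input)
#'   and `r2`.
#' @export
fit_isosbestic <- function(raw, intercept = TRUE) {
  stopifnot(inherits(raw, "raw_photometry"))
  if (length(raw$f465) < 10L)
    stop("need at least 10 samples to fit the isosbestic baseline", call. = FALSE)
  if (stats::sd(raw$f405) == 0)
    stop("degenerate fit: f405 is constant", call. = FALSE)
  fit <- if (intercept) stats::lm(raw$f465 ~ raw$f405)
         else stats::lm(raw$f465 ~ 0 + raw$f405)
  cf <- stats::coef(fit)
  slope <- unname(if (intercept) cf[2L] else cf[1L])
  b0 <- unname(if (intercept) cf[1L] else 0)
  f0 <- b0 + slope * raw$f405
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((raw$f465 - mean(raw$f465))^2)
  structure(list(slope = slope, intercept = b0, f0 = f0,
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "baseline_fit")
}

#' Compute z-scored dF/F from a fitted isosbestic baseline
#'
#' dF/F is `(F - F0) / F0` where `F` is the 465 nm emission and `F0` the
#' scaled isosbestic fit; the trace is then converted to z-scores over the
#' whole session.
#'
#' @param raw a [raw_photometry()].
#' @param fit a [fit_isosbestic()] result derived from the same series.
#'
#' @return An object of class `dff_trace`: data frame with columns `time`,
#'   `dff` (unitless) and `z`, with attributes `session_mean`,
#'   `session_sd` and `pulse_rate`.
#' @export
compute_dff <- function(raw, fit) {
  stopifnot(inherits(raw, "raw_photometry"), inherits(fit, "baseline_fit"))
  if (length(fit$f0) != length(raw$f465))
    stop("baseline fit length does not match the photometry series", call. = FALSE)
  bad <- which(fit$f0 <= 0)
  if (length(bad))
    stop(sprintf("fitted F0 non-positive at %d sample(s), e.g. indices %s",
                 length(bad),
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  dff <- (raw$f465 - fit$f0) / fit$f0
  m <- mean(dff)
  s <- stats::sd(dff)
  z <- if (s > 0) (dff - m) / s else dff * 0
  structure(data.frame(time = raw$time, dff = dff, z = z),
            session_mean = m, session_sd = s, pulse_rate = raw$pulse_rate,
            class = c("dff_trace", "data.frame"))
}

#' Round to a number of significant figures
#'
#' Thin wrapper used when reporting estimates such as the imaged volume at
#' two significant figures.
#'
#' @param x numeric.
#' @param digits significant figures (default 2).
#' @return `x` rounded to `digits` significant figures.
#' @export
round_sig <- function(x, digits = 2) signif(x, digits)

#' Imaged-volume estimate for a fiber-photometry recording
#'
#' The tissue volume sampled by an optical fiber, modelled as a cylinder
#' of the fiber diameter extending a given depth from the fiber ending:
#' `pi * (diameter/2)^2 * depth`.
#'
#' @param fiber_diameter fiber core diameter in micrometres (> 0).
#' @param depth imaged depth from the fiber ending in micrometres (>= 0).
#' @return Volume in cubic micrometres. Pair with [round_sig()] for a
#'   two-significant-figure report.
#' @export
imaged_volume <- function(fiber_diameter, depth) {
  if (fiber_diameter <= 0 || depth < 0)
    stop("fiber_diameter must be > 0 and depth >= 0", call. = FALSE)
  pi * (fiber_diameter / 2)^2 * depth
}
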