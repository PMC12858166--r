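#' Detect local-extremum events in a kinematic or angle trace
#'
#' Scans a regularly sampled trace for strict local extrema: a sample is an
#' event when it is the maximum or the minimum among all samples within
#' `half_window` seconds before and after it. Plateau ties are broken to
#' the earliest sample. The event magnitude is the signed change from the
#' nearest preceding opposite extremum (or from the trace start), and only
#' events whose absolute magnitude exceeds `min_delta` are kept — for head
#' turns the field threshold is a change in angle > 10 degrees. Samples
#' within `half_window` of either edge are never reported.
#'
#' @param time sample times in seconds (regular grid assumed).
#' @param x trace values: head angle in degrees for turn detection, speed
#'   in cm/s for movement-peak detection.
#' @param half_window half-width of the extremum window in seconds
#'   (default 0.5).
#' @param min_delta detection threshold on the local change (default 10,
#'   the turn threshold in degrees; use a speed threshold for movement
#'   peaks).
#' @param kind `"turn"` or `"movement-peak"`; turns carry a signed
#'   direction, movement peaks do not.
#'
#' @return A data frame of class `detected_events` with columns `time`,
#'   `index`, `kind`, `magnitude` (signed change for turns, peak value
#'   change for movement peaks) and `direction` (`+1`/`-1` sign of the
#'   change for turns, `NA` otherwise; see [label_direction()]).
#' @export
detect_peaks <- function(time, x, half_window = 0.5, min_delta = 10,
                         kind = c("turn", "movement-peak")) {
  kind <- match.arg(kind)
  if (half_window <= 0) stop("half_window must be > 0", call. = FALSE)
  n <- length(x)
  dt <- stats::median(diff(time))
  w <- max(1L, round(half_window / dt))
  if (n <= 2L * w)
    stop("trace shorter than twice the half window", call. = FALSE)

  # candidate strict extrema (ties to earliest) over +-w samples, edges excluded
  cand_idx <- integer(0)
  cand_sign <- integer(0)
  for (i in seq.int(w + 1L, n - w)) {
    win <- x[(i - w):(i + w)]
    xi <- x[i]
    if (xi == max(win) && which.max(win) == w + 1L) {
      cand_idx <- c(cand_idx, i); cand_sign <- c(cand_sign, 1L)
    } else if (xi == min(win) && which.min(win) == w + 1L) {
      cand_idx <- c(cand_idx, i); cand_sign <- c(cand_sign, -1L)
    }
  }

  if (!length(cand_idx)) {
    return(.empty_events())
  }

  # magnitude: change from the nearest preceding opposite-sign extremum,
  # or from the first sample if none precedes
  mag <- numeric(length(cand_idx))
  for (j in seq_along(cand_idx)) {
    prev_opp <- rev(which(cand_sign[seq_len(j - 1L)] != cand_sign[j]))
    ref <- if (length(prev_opp)) x[cand_idx[prev_opp[1L]]] else x[1L]
    mag[j] <- x[cand_idx[j]] - ref
  }

  keep <- abs(mag) > min_delta
  out <- data.frame(
    time = time[cand_idx[keep]],
    index = cand_idx[keep],
    kind = rep(kind, sum(keep)),
    magnitude = mag[keep],
    direction = if (kind == "turn") sign(mag[keep]) else rep(NA_real_, sum(keep)))
  class(out) <- c("detected_events", "data.frame")
  out
}

.empty_events <- function() {
  out <- data.frame(time = numeric(0), index = integer(0),
                    kind = character(0), magnitude = numeric(0),
                    direction = numeric(0))
  class(out) <- c("detected_events", "data.frame")
  out
}

#' Label turn events as ipsiversive or contraversive
#'
#' Maps the signed turn direction to ipsiversive (toward the implanted
#' hemisphere) or contraversive (away from it). The sign convention
#' follows the kinematics module: counter-clockwise (leftward) rotation is
#' positive, so a positive turn is contraversive for a right implant and
#' ipsiversive for a left implant. Swapping `implant_side` swaps every
#' label.
#'
#' @param events a `detected_events` data frame with signed `direction`.
#' @param implant_side `"left"` or `"right"`.
#' @return `events` with an added `side_label` factor
#'   (`"ipsiversive"`/`"contraversive"`).
#' @export
label_direction <- function(events, implant_side = c("left", "right")) {
  implant_side <- match.arg(implant_side)
  if (!nrow(events)) {
    events$side_label <- factor(character(0),
                                levels = c("ipsiversive", "contraversive"))
    return(events)
  }
  if (any(is.na(events$direction)))
    stop("events lack a signed direction; label_direction applies to turns",
         call. = FALSE)
  contra_sign <- if (implant_side == "right") 1 else -1
  events$side_label <- factor(
    ifelse(sign(events$direction) == contra_sign, "contraversive", "ipsiversive"),
    levels = c("ipsiversive", "contraversive"))
  events
}

#' Select detected events by sampling category
#'
#' The three event-sampling categories used for peri-event averaging:
#' `"all"` keeps every event; `"no_prior_3s"` keeps events with no other
#' event in the 3 s before them (movement onsets from immobility);
#' `"spaced_gt5s"` greedily keeps events at least 5 s after the last kept
#' event (peaks sampled at a fixed interval > 5 s).
#'
#' @param events a time-sorted `detected_events` data frame.
#' @param category `"all"`, `"no_prior_3s"` or `"spaced_gt5s"`.
#' @param prior_gap exclusion lookback for `no_prior_3s` (s, default 3).
#' @param spacing minimum spacing for `spaced_gt5s` (s, default 5).
#' @return The selected subset, same columns.
#' @export
select_category <- function(events,
                            category = c("all", "no_prior_3s", "spaced_gt5s"),
                            prior_gap = 3, spacing = 5) {
  category <- match.arg(category)
  if (is.unsorted(events$time))
    stop("events must be time-sorted", call. = FALSE)
  if (!nrow(events) || category == "all") return(events)
  t <- events$time
  keep <- switch(category,
    no_prior_3s = vapply(seq_along(t), function(i) {
      !any(t > t[i] - prior_gap & t < t[i])
    }, logical(1)),
    spaced_gt5s = {
      k <- logical(length(t))
      last <- -Inf
      for (i in seq_along(t)) {
        if (t[i] - last >= spacing) { k[i] <- TRUE; last <- t[i] }
      }
      k
    })
  events[keep, , drop = FALSE]
}
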