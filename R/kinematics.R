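#' Construct a two-marker head-tracking object
#'
#' Container for timestamped nose and between-the-ears marker coordinates
#' recorded by overhead video tracking. Coordinates are stored in metric
#' units (cm) in a y-up mathematical frame so that counter-clockwise head
#' rotation is positive; use [read_tracking_csv()] to ingest pixel
#' coordinates (y-down image convention) with calibration.
#'
#' @param time numeric vector of frame times in seconds, strictly increasing.
#' @param nose two-column matrix of nose-marker positions (cm).
#' @param ears two-column matrix of ears-marker positions (cm).
#' @param frame_rate frames per second. Validated against `[30, 100]` Hz
#'   unless `validate_rate = FALSE`.
#' @param pixels_per_cm calibration used at ingestion (recorded for
#'   provenance; coordinates are already metric).
#' @param implant_side `"left"` or `"right"`: hemisphere of the recording
#'   implant, used downstream to map signed rotation to
#'   ipsiversive/contraversive.
#' @param validate_rate logical; set `FALSE` to accept frame rates outside
#'   the default validation range.
#'
#' @return An object of class `marker_track`.
#' @export
marker_track <- function(time, nose, ears, frame_rate,
                         pixels_per_cm = NA_real_,
                         implant_side = c("left", "right"),
                         validate_rate = TRUE) {
  implant_side <- match.arg(implant_side)
  nose <- as.matrix(nose)
  ears <- as.matrix(ears)
  n <- length(time)
  if (n < 2L)
    stop("marker_track needs at least 2 frames", call. = FALSE)
  if (!all(dim(nose) == c(n, 2L)) || !all(dim(ears) == c(n, 2L)))
    stop("nose and ears must be n x 2 matrices matching time", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (validate_rate && (frame_rate < 30 || frame_rate > 100))
    stop("frame_rate outside [30, 100] Hz; pass validate_rate = FALSE to override",
         call. = FALSE)
  mid <- sqrt(rowSums((nose - ears)^2))
  if (any(mid <= 0)) {
    bad <- which(mid <= 0)[1L]
    stop(sprintf("degenerate geometry: zero-length head midline at frame %d", bad),
         call. = FALSE)
  }
  structure(
    list(time = time, nose = unname(nose), ears = unname(ears),
         frame_rate = frame_rate, pixels_per_cm = pixels_per_cm,
         implant_side = implant_side),
    class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track> %d frames @ %g fps (%.1f s), implant side: %s\n",
              length(x$time), x$frame_rate, diff(range(x$time)), x$implant_side))
  invisible(x)
}

# wrap successive angle differences into (-pi, pi]
.wrap_pi <- function(d) {
  ((d + pi) %% (2 * pi)) - pi
}

#' Decompose two-marker head tracking into movement-speed components
#'
#' Converts nose/ears marker trajectories into per-frame rotational and
#' translational head-speed components. Rotational speed is the inter-frame
#' change of the head-midline angle (radians) multiplied by a radius and by
#' the frame rate, giving an arc-length speed in cm/s. Linear speed is the
#' inter-frame displacement of the ears marker projected on the head
#' midline (cosine of the angle between displacement and midline);
#' sideways speed uses the sine. Translational speed combines linear and
#' sideways components; overall speed combines rotational and translational
#' speed per frame.
#'
#' @param track a [marker_track()].
#' @param radius how the rotational-arc radius is measured:
#'   `"midline"` (nose-to-ears length, averaged over the two frames of
#'   each difference; the default) or `"half_midline"`.
#' @param translational how linear and sideways combine:
#'   `"euclidean"` (default; equals ears displacement magnitude times
#'   frame rate exactly) or `"abs_sum"` (sum of absolute components).
#' @param overall how rotational and translational combine into overall
#'   speed: `"sum"` (default; rotational + |translational| per frame) or
#'   `"euclidean"`.
#'
#' @return A `kinematic_series`: data frame with columns `time`, `overall`,
#'   `rotational`, `translational`, `linear`, `sideways` (cm/s; linear and
#'   sideways signed, forward/leftward positive), `head_angle` (degrees,
#'   unwrapped, counter-clockwise positive), `midline_length` (cm) and
#'   `filled` (logical: first frame carries the second frame's speeds).
#'   Attributes `frame_rate` and `implant_side` are carried along.
#' @export
decompose_markers <- function(track,
                              radius = c("midline", "half_midline"),
                              translational = c("euclidean", "abs_sum"),
                              overall = c("sum", "euclidean")) {
  stopifnot(inherits(track, "marker_track"))
  radius <- match.arg(radius)
  translational <- match.arg(translational)
  overall <- match.arg(overall)

  fps <- track$frame_rate
  n <- length(track$time)
  mlvec <- track$nose - track$ears
  mid_len <- sqrt(rowSums(mlvec^2))
  ang <- atan2(mlvec[, 2L], mlvec[, 1L])          # radians, CCW positive
  dang <- .wrap_pi(diff(ang))
  ang_unwrap <- ang[1L] + c(0, cumsum(dang))      # continuous, no +-180 jumps

  r <- (mid_len[-n] + mid_len[-1L]) / 2
  if (radius == "half_midline") r <- r / 2
  rot <- abs(dang) * r * fps                      # arc-length speed, cm/s

  disp <- diff(track$ears)                        # ears displacement per frame
  disp_len <- sqrt(rowSums(disp^2))
  # angle between displacement and the head midline of the earlier frame
  mid_u <- mlvec[-n, , drop = FALSE] / mid_len[-n]
  lin <- (disp[, 1L] * mid_u[, 1L] + disp[, 2L] * mid_u[, 2L]) * fps
  # leftward of the midline positive (perp = midline rotated +90 deg)
  sid <- (disp[, 1L] * (-mid_u[, 2L]) + disp[, 2L] * mid_u[, 1L]) * fps
  lin[disp_len == 0] <- 0
  sid[disp_len == 0] <- 0

  trans <- switch(translational,
                  euclidean = sqrt(lin^2 + sid^2),
                  abs_sum   = abs(lin) + abs(sid))
  ov <- switch(overall,
               sum       = rot + abs(trans),
               euclidean = sqrt(rot^2 + trans^2))

  # first frame forward-filled from the second difference, flagged
  pad <- function(v) c(v[1L], v)
  out <- data.frame(
    time = track$time,
    overall = pad(ov), rotational = pad(rot), translational = pad(trans),
    linear = pad(lin), sideways = pad(sid),
    head_angle = ang_unwrap * 180 / pi,
    midline_length = mid_len,
    filled = c(TRUE, rep(FALSE, n - 1L)))
  structure(out,
            frame_rate = fps,
            implant_side = track$implant_side,
            class = c("kinematic_series", "data.frame"))
}

#' Cumulative head-angle bias around a reference time
#'
#' Accumulated per-frame change of the head angle, zeroed at the frame
#' preceding `t0` (e.g. stimulus onset), expressed in degrees. With a
#' declared implant side the sign is mapped so that positive values are
#' contraversive (turning away from the implanted hemisphere).
#'
#' @param series a `kinematic_series` from [decompose_markers()].
#' @param t0 reference time in seconds; must lie within the time range.
#' @param implant_side `"left"`, `"right"`, or `NULL` to use the side
#'   recorded on `series`. With a left implant a clockwise (rightward) turn
#'   is contraversive; with a right implant a counter-clockwise turn is.
#'
#' @return Data frame with columns `time` and `bias` (degrees; positive =
#'   contraversive). The bias is exactly 0 at the last frame before `t0`.
#' @export
head_angle_bias <- function(series, t0, implant_side = NULL) {
  stopifnot(inherits(series, "kinematic_series"))
  if (is.null(implant_side)) implant_side <- attr(series, "implant_side")
  implant_side <- match.arg(implant_side, c("left", "right"))
  tm <- series$time
  if (t0 < tm[1L] || t0 > tm[length(tm)])
    stop("t0 outside the recorded time range", call. = FALSE)
  idx <- which(tm < t0)
  i0 <- if (length(idx)) max(idx) else 1L
  dang <- c(0, diff(series$head_angle))          # per-frame change, degrees
  bias <- cumsum(dang) - sum(dang[seq_len(i0)])
  sgn <- if (implant_side == "right") 1 else -1  # CCW(+) is contra for right implant
  data.frame(time = tm, bias = sgn * bias)
}
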