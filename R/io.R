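#' Read and write the pipeline's plain-text formats
#'
#' All on-disk formats are diff-able plain text: UTF-8, `.` decimal,
#' seconds for every time column. Each reader validates structure and
#' reports offending line numbers instead of coercing silently; each
#' `read(write(x))` round-trips the in-memory object.
#'
#' @name shuttlebox-io
NULL

#' @describeIn shuttlebox-io Write a `marker_track` to a tracking CSV
#'   (columns `time_s, nose_x_px, nose_y_px, ears_x_px, ears_y_px`; pixel
#'   coordinates, y-down image convention) plus a sidecar YAML
#'   (`<path>.yaml`) holding `frame_rate`, `pixels_per_cm` and
#'   `implant_side`.
#' @param track a [marker_track()].
#' @param path file path.
#' @export
write_tracking_csv <- function(track, path) {
  ppc <- track$pixels_per_cm
  if (is.na(ppc)) ppc <- 1
  to_px <- function(m) cbind(m[, 1L] * ppc, -m[, 2L] * ppc)  # y-down
  nose <- to_px(track$nose); ears <- to_px(track$ears)
  df <- data.frame(time_s = track$time,
                   nose_x_px = nose[, 1L], nose_y_px = nose[, 2L],
                   ears_x_px = ears[, 1L], ears_y_px = ears[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(frame_rate = track$frame_rate,
                        pixels_per_cm = ppc,
                        implant_side = track$implant_side),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @describeIn shuttlebox-io Read a tracking CSV and its sidecar YAML
#'   back into a [marker_track()] (pixels converted to cm, y flipped to
#'   the y-up mathematical convention).
#' @export
read_tracking_csv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.csv(path)
  need <- c("time_s", "nose_x_px", "nose_y_px", "ears_x_px", "ears_y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tracking CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ppc <- meta$pixels_per_cm
  to_cm <- function(x, y) cbind(x / ppc, -y / ppc)
  marker_track(df$time_s,
               to_cm(df$nose_x_px, df$nose_y_px),
               to_cm(df$ears_x_px, df$ears_y_px),
               frame_rate = meta$frame_rate, pixels_per_cm = ppc,
               implant_side = meta$implant_side, validate_rate = FALSE)
}

#' @describeIn shuttlebox-io Write a `raw_photometry` object to CSV
#'   (columns `time_s, f465, f405`) with a sidecar YAML (`pulse_rate`).
#' @param raw a [raw_photometry()].
#' @export
write_photometry_csv <- function(raw, path) {
  utils::write.csv(data.frame(time_s = raw$time, f465 = raw$f465,
                              f405 = raw$f405),
                   path, row.names = FALSE)
  yaml::write_yaml(list(pulse_rate = raw$pulse_rate), paste0(path, ".yaml"))
  invisible(path)
}

#' @describeIn shuttlebox-io Read a photometry CSV back into a
#'   [raw_photometry()].
#' @export
read_photometry_csv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.csv(path)
  miss <- setdiff(c("time_s", "f465", "f405"), names(df))
  if (length(miss))
    stop("photometry CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw_photometry(df$time_s, df$f465, df$f405, pulse_rate = meta$pulse_rate)
}

#' @describeIn shuttlebox-io Write detected events as a JSON array of
#'   `{time_s, kind, magnitude, direction}` records.
#' @param events a `detected_events` data frame.
#' @export
write_events_json <- function(events, path) {
  recs <- data.frame(time_s = events$time, index = events$index,
                     kind = events$kind, magnitude = events$magnitude,
                     direction = events$direction)
  jsonlite::write_json(recs, path, digits = NA, na = "null")
  invisible(path)
}

#' @describeIn shuttlebox-io Read an events JSON back into a
#'   `detected_events` data frame.
#' @export
read_events_json <- function(path) {
  recs <- jsonlite::fromJSON(path)
  if (!length(recs)) return(.empty_events())
  out <- data.frame(time = recs$time_s, index = as.integer(recs$index),
                    kind = recs$kind, magnitude = recs$magnitude,
                    direction = if ("direction" %in% names(recs))
                      as.numeric(recs$direction) else NA_real_)
  class(out) <- c("detected_events", "data.frame")
  out
}

#' @describeIn shuttlebox-io Write a `session_log` as JSON Lines, one
#'   trial record per line (with its ITC times inlined).
#' @param log a `session_log`.
#' @export
write_session_jsonl <- function(log, path) {
  itc <- attr(log, "itc_times")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- as.list(log[i, , drop = FALSE])
    rec <- lapply(rec, function(v) if (is.factor(v)) as.character(v) else v)
    rec$itc_times <- as.numeric(itc[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  writeLines(jsonlite::toJSON(list(meta = TRUE,
                                   procedure = attr(log, "procedure"),
                                   seed = attr(log, "seed")),
                              auto_unbox = TRUE), con)
  invisible(path)
}

#' @describeIn shuttlebox-io Read a session JSONL back into a
#'   `session_log`; malformed lines raise an error naming the line.
#' @export
read_session_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- vector("list", length(lines))
  meta <- NULL
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("malformed JSONL at line %d of %s", i, path),
                           call. = FALSE))
    if (isTRUE(rec$meta)) meta <- rec else recs[[i]] <- rec
  }
  recs <- Filter(Negate(is.null), recs)
  itc <- lapply(recs, function(r) as.numeric(r$itc_times))
  rows <- lapply(recs, function(r) {
    r$itc_times <- NULL
    r$latency <- if (is.null(r$latency)) NA_real_ else as.numeric(r$latency)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, rows)
  structure(log, itc_times = itc,
            procedure = if (!is.null(meta)) meta$procedure else NA_character_,
            seed = if (!is.null(meta)) meta$seed else NA_integer_,
            class = c("session_log", "data.frame"))
}

#' @describeIn shuttlebox-io Write a `class_assignment` as a CSV of
#'   `item_id, scheme, label, ordering_statistic`.
#' @param assignment a `class_assignment`.
#' @param scheme scheme name recorded per row.
#' @export
write_assignment_csv <- function(assignment, path, scheme = "kmeans") {
  stat <- assignment$ordering_statistic[as.character(assignment$labels)]
  utils::write.csv(data.frame(item_id = seq_along(assignment$labels),
                              scheme = scheme,
                              label = as.character(assignment$labels),
                              ordering_statistic = as.numeric(stat)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @describeIn shuttlebox-io Read an assignment CSV (plain data frame).
#' @export
read_assignment_csv <- function(path) utils::read.csv(path)

#' @describeIn shuttlebox-io Write a long-format trial table CSV.
#' @param table a trial table data frame.
#' @export
write_trial_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn shuttlebox-io Read a trial table CSV.
#' @export
read_trial_table_csv <- function(path) utils::read.csv(path)

#' @describeIn shuttlebox-io Write a `snippet_matrix` as CSV with a
#'   one-line `#` header carrying alignment, span and rate.
#' @param mat a `snippet_matrix`.
#' @export
write_snippets_csv <- function(mat, path) {
  grid <- attr(mat, "grid")
  hdr <- sprintf("# alignment=%s span=%g,%g rate=%g n_dropped=%d",
                 attr(mat, "alignment"), grid[1L], grid[length(grid)],
                 attr(mat, "sample_rate"), attr(mat, "n_dropped"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(mat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @describeIn shuttlebox-io Read a snippet CSV back into a
#'   `snippet_matrix`.
#' @export
read_snippets_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "alignment=(\\S+) span=([-0-9.]+),([-0-9.]+) rate=([0-9.]+) n_dropped=([0-9]+)",
    hdr))[[1L]]
  if (length(m) != 6L)
    stop("snippet CSV header malformed: ", hdr, call. = FALSE)
  mat <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  dimnames(mat) <- NULL
  rate <- as.numeric(m[5L])
  structure(mat,
            grid = seq(as.numeric(m[3L]), as.numeric(m[4L]), by = 1 / rate),
            alignment = m[2L], sample_rate = rate,
            event_times = numeric(0), n_dropped = as.integer(m[6L]),
            class = c("snippet_matrix", "matrix"))
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order against a generated dataset:
#' tracking -> kinematic decomposition -> photometry -> dF/F -> turn and
#' movement-peak detection -> event-triggered snippets and window
#' measures -> behavior simulation and mode classification, writing each
#' stage's output (plain-text formats) plus a provenance record to
#' `out_dir`.
#'
#' @param config a [synth_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   provenance record.
#' @export
run_pipeline <- function(config = synth_config(), seed = 1L,
                         out_dir = tempfile("shuttlebox_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trk <- gen_tracking(config, seed = seed)
  write_tracking_csv(trk$track, file.path(out_dir, "tracking.csv"))
  kin <- decompose_markers(trk$track)
  pho <- gen_photometry(config, kin, seed = seed + 1L)
  write_photometry_csv(pho$raw, file.path(out_dir, "photometry.csv"))
  dff <- compute_dff(pho$raw, fit_isosbestic(pho$raw))
  turns <- detect_peaks(kin$time, kin$head_angle, kind = "turn")
  turns <- label_direction(turns, config$implant_side)
  write_events_json(turns, file.path(out_dir, "turns.json"))
  snips <- extract_snippets(dff$time, dff$z, turns$time, span = c(-3, 3),
                            alignment = "action")
  if (nrow(snips))
    write_snippets_csv(snips, file.path(out_dir, "snippets.csv"))
  beh <- gen_behavior(config, seed = seed + 2L)
  write_session_jsonl(beh$log, file.path(out_dir, "session.jsonl"))
  perf <- performance(beh$log)
  prov <- list(seed = seed,
               config_hash = sum(utils::head(
                 utf8ToInt(paste(deparse(unclass(config)), collapse = "")),
                 10000L)),
               n_turns_detected = nrow(turns),
               n_snippets = nrow(snips),
               pct_avoids = perf$per_cs$pct_avoids[1L])
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(track = trk, kin = kin, dff = dff, turns = turns,
                 snippets = snips, behavior = beh, performance = perf,
                 provenance = prov, out_dir = out_dir))
}
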