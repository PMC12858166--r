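#' Trial specification for the signaled avoidance procedures
#'
#' Builds the trial structure of one of the four shuttle-box avoidance
#' procedures. A trial is an avoidance interval signaled by a CS tone,
#' followed (if the animal fails to cross) by an escape interval in which
#' the US (foot-shock plus white noise) is delivered until escape.
#'
#' * **AA1** — basic active avoidance: CS1, 7 s avoidance interval.
#' * **AA2** — like AA1 but intertrial crossings (ITCs) are punished with
#'   a 0.2 s shock.
#' * **AA3** — go/no-go discrimination: CS1 trials as in AA1 (ITCs no
#'   longer punished); CS2 trials signal passive avoidance, where crossing
#'   during the CS2 avoidance interval is punished with a 0.5 s shock and
#'   the trial ends.
#' * **AA4** — like AA1 but three CSs signal avoidance intervals of 4, 7
#'   and 15 s (CS1, CS2, CS3).
#'
#' @param procedure `"AA1"`, `"AA2"`, `"AA3"` or `"AA4"`.
#' @param escape_interval escape-interval duration in seconds (default 10).
#' @param iti_range intertrial-interval range in seconds, sampled
#'   uniformly (default `c(25, 45)`).
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(procedure = c("AA1", "AA2", "AA3", "AA4"),
                       escape_interval = 10, iti_range = c(25, 45)) {
  procedure <- match.arg(procedure)
  cs <- switch(procedure,
    AA1 = data.frame(cs_id = "CS1", avoidance_interval = 7,
                     rule = "active", stringsAsFactors = FALSE),
    AA2 = data.frame(cs_id = "CS1", avoidance_interval = 7,
                     rule = "active", stringsAsFactors = FALSE),
    AA3 = data.frame(cs_id = c("CS1", "CS2"), avoidance_interval = c(7, 7),
                     rule = c("active", "passive"), stringsAsFactors = FALSE),
    AA4 = data.frame(cs_id = c("CS1", "CS2", "CS3"),
                     avoidance_interval = c(4, 7, 15),
                     rule = "active", stringsAsFactors = FALSE))
  structure(list(procedure = procedure, cs = cs,
                 escape_interval = escape_interval,
                 iti_range = iti_range,
                 itc_punishment = if (procedure == "AA2") 0.2 else 0,
                 cs2_punishment = if (procedure == "AA3") 0.5 else 0),
            class = "trial_spec")
}

#' Agent policy for the avoidance simulator
#'
#' Defines how a simulated animal behaves: a crossing-latency distribution
#' per CS, a Poisson rate of intertrial crossings, and a short escape
#' delay after US onset. Latency distributions are given as samplers so
#' any family can be plugged in.
#'
#' @param latency named list mapping each CS id to a function `n ->
#'   latencies (s)` drawing crossing latencies from CS onset, or a single
#'   function used for every CS. `function(n) rep(Inf, n)` never crosses.
#' @param itc_rate intertrial crossings per minute (Poisson, default 2).
#' @param escape_delay constant delay from US onset to the escape crossing
#'   (s, default 0.3; escape occurs rapidly).
#' @param mode_mixture optional weights over avoidance modes 1-3, recorded
#'   for generators that emulate mode structure; must sum to 1.
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(latency, itc_rate = 2, escape_delay = 0.3,
                         mode_mixture = NULL) {
  if (is.function(latency)) latency <- list(default = latency)
  stopifnot(is.list(latency), all(vapply(latency, is.function, logical(1))))
  if (!is.null(mode_mixture)) {
    if (any(mode_mixture < 0) || abs(sum(mode_mixture) - 1) > 1e-8)
      stop("mode_mixture weights must be non-negative and sum to 1",
           call. = FALSE)
  }
  structure(list(latency = latency, itc_rate = itc_rate,
                 escape_delay = escape_delay, mode_mixture = mode_mixture),
            class = "agent_policy")
}

.agent_latency <- function(agent, cs_id, n = 1L) {
  f <- agent$latency[[cs_id]]
  if (is.null(f)) f <- agent$latency[["default"]]
  if (is.null(f))
    stop(sprintf("agent has no latency distribution for %s", cs_id),
         call. = FALSE)
  f(n)
}

#' Run one simulated avoidance session
#'
#' Event-driven simulation of a session of `n_trials` trials under a trial
#' specification and an agent policy. Each trial: an intertrial interval
#' is drawn uniformly from the spec range, ITCs are sampled within it as a
#' Poisson process (punished in AA2), then the CS for the trial is chosen
#' (AA3 randomizes CS1/CS2 half-and-half; AA4 randomizes its three CSs)
#' and a crossing latency is drawn from the agent. On active-rule trials a
#' latency shorter than the avoidance interval is an avoid (the CS ends
#' and the trial is over); otherwise the US starts at the end of the
#' interval and the agent escapes after its escape delay. On passive-rule
#' trials (AA3-CS2) a crossing during the avoidance interval is a punished
#' passive error that ends the trial; withholding is a passive avoid.
#'
#' @param spec a [trial_spec()].
#' @param agent an [agent_policy()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; identical seeds give identical logs.
#' @return A `session_log`: data frame with one row per trial
#'   (`trial_index`, `cs_id`, `cs_onset`, `response`, `latency`,
#'   `n_itc`, `punished`) and attributes `itc_times` (list per trial),
#'   `procedure` and `seed`. Times in seconds, ms resolution.
#' @export
run_session <- function(spec, agent, n_trials, seed = 1L) {
  stopifnot(inherits(spec, "trial_spec"), inherits(agent, "agent_policy"))
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  set.seed(seed)
  clock <- 0
  rows <- vector("list", n_trials)
  itc_times <- vector("list", n_trials)
  n_cs <- nrow(spec$cs)
  for (i in seq_len(n_trials)) {
    iti <- stats::runif(1, spec$iti_range[1L], spec$iti_range[2L])
    n_itc <- stats::rpois(1, agent$itc_rate * iti / 60)
    itc <- sort(stats::runif(n_itc, 0, iti)) + clock
    clock <- clock + iti
    cs_row <- if (n_cs == 1L) 1L else sample.int(n_cs, 1L)
    cs_id <- spec$cs$cs_id[cs_row]
    interval <- spec$cs$avoidance_interval[cs_row]
    rule <- spec$cs$rule[cs_row]
    lat <- .agent_latency(agent, cs_id)
    if (rule == "active") {
      if (lat < interval) {
        response <- "avoid"; latency <- lat; punished <- FALSE
        trial_dur <- lat
      } else {
        response <- "escape"
        latency <- interval + agent$escape_delay
        punished <- TRUE               # the US is experienced
        trial_dur <- latency
      }
    } else {                            # passive rule (AA3-CS2)
      if (lat < interval) {
        response <- "passive_error"; latency <- lat; punished <- TRUE
        trial_dur <- lat                # punished crossing ends the trial
      } else {
        response <- "passive_avoid"; latency <- NA_real_; punished <- FALSE
        trial_dur <- interval
      }
    }
    rows[[i]] <- data.frame(
      trial_index = i, cs_id = cs_id,
      cs_onset = round(clock, 3),
      response = response,
      latency = round(latency, 3),
      n_itc = n_itc,
      punished = punished, stringsAsFactors = FALSE)
    itc_times[[i]] <- round(itc, 3)
    clock <- clock + trial_dur
  }
  log <- do.call(rbind, rows)
  structure(log, itc_times = itc_times, procedure = spec$procedure,
            seed = seed, class = c("session_log", "data.frame"))
}

#' Summarize performance of an avoidance session
#'
#' Computes the standard session metrics: the percentage of active avoids
#' per CS (for passive-rule CS2 trials the complementary percentage of
#' passive avoids and of passive errors), the mean response latency over
#' successful avoids only (escape trials excluded), the total number of
#' intertrial crossings, and the percentage of error trials (escapes and
#' passive errors).
#'
#' @param log a `session_log` from [run_session()].
#' @return A list with elements `per_cs` (data frame: `cs_id`, `n_trials`,
#'   `pct_avoids`, `mean_avoid_latency`, `pct_errors`), `itc_count` and
#'   `pct_errors` overall.
#' @export
performance <- function(log) {
  stopifnot(inherits(log, "session_log"))
  if (!nrow(log)) stop("empty session log", call. = FALSE)
  per_cs <- do.call(rbind, lapply(split(log, log$cs_id), function(d) {
    avoids <- d$response %in% c("avoid", "passive_avoid")
    data.frame(
      cs_id = d$cs_id[1L],
      n_trials = nrow(d),
      pct_avoids = 100 * mean(avoids),
      mean_avoid_latency = if (any(d$response == "avoid"))
        mean(d$latency[d$response == "avoid"]) else NA_real_,
      pct_errors = 100 * mean(d$response %in% c("escape", "passive_error")),
      stringsAsFactors = FALSE)
  }))
  rownames(per_cs) <- NULL
  list(per_cs = per_cs,
       itc_count = sum(log$n_itc),
       pct_errors = 100 * mean(log$response %in% c("escape", "passive_error")))
}
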