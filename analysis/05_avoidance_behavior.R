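#!/usr/bin/env Rscript
# Simulate the four avoidance procedures with matched agents, summarize
# performance, and classify active-avoid trials into response modes from
# their CS-aligned speed trajectories.

suppressMessages(library(shuttlebox))

seed <- 20260105L

# one agent profile across procedures: mode-mixture latencies, modest ITCs
perf_rows <- list()
for (proc in c("AA1", "AA2", "AA3", "AA4")) {
  beh <- gen_behavior(synth_config(procedure = proc, n_trials = 120),
                      seed = seed)
  p <- performance(beh$log)
  for (i in seq_len(nrow(p$per_cs)))
    perf_rows[[paste(proc, p$per_cs$cs_id[i])]] <-
      data.frame(procedure = proc, p$per_cs[i, ], itc_count = p$itc_count)
  cat(sprintf("%s: %s; ITCs %d\n", proc,
              paste(sprintf("%s %.0f%% avoids (lat %.1f s)",
                            p$per_cs$cs_id, p$per_cs$pct_avoids,
                            p$per_cs$mean_avoid_latency), collapse = "; "),
              p$itc_count))
}
perf <- do.call(rbind, perf_rows)
rownames(perf) <- NULL
write.csv(perf, "results/05_performance.csv", row.names = FALSE)

# avoidance modes from CS-aligned speed time series (AA1 session)
beh <- gen_behavior(synth_config(n_trials = 300), seed = seed + 1)
av <- beh$log$response == "avoid"
asg <- classify_modes(beh$speed[av, ], beh$log$latency[av], k = 3,
                      seed = seed)
cat(sprintf("\nAvoidance modes over %d avoids (of %d trials):\n",
            sum(av), nrow(beh$log)))
props <- summarize_proportions(asg)
for (i in seq_len(nrow(props)))
  cat(sprintf("  %s: n = %3d (%.1f%%), mean avoid latency %.2f s\n",
              props$label[i], props$n[i], props$pct[i],
              asg$mode_latency[[props$label[i]]]))
agree <- table(truth = beh$truth$modes[av], assigned = asg$labels)
cat(sprintf("Mode recovery agreement: %.1f%%\n",
            100 * sum(apply(agree, 2, max)) / sum(agree)))
write.csv(data.frame(trial = which(av), latency = beh$log$latency[av],
                     truth_mode = beh$truth$modes[av],
                     mode = as.character(asg$labels)),
          "results/05_modes.csv", row.names = FALSE)
write_session_jsonl(beh$log, "results/05_session.jsonl")
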