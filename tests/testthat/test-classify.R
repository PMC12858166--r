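snip <- function(mat, grid) {
  structure(mat, grid = grid, alignment = "action", sample_rate = 20,
            event_times = numeric(0), n_dropped = 0L,
            class = c("snippet_matrix", "matrix"))
}

test_that("turn bias is the contra-minus-ipsi mean trace and antisymmetric", {
  grid <- seq(-2, 2, by = 0.05)
  g <- exp(-grid^2 / (2 * 0.3^2))
  set.seed(31)
  mk <- function(amp, n_ev = 6, noise = 0.01)
    snip(t(replicate(n_ev, amp * g + rnorm(length(grid), 0, noise))), grid)

  # identical responses in both directions: bias identically ~0
  contra <- list(mk(1), mk(1, noise = 0))
  ipsi <- list(mk(1), mk(1, noise = 0))
  b0 <- turn_bias(contra, ipsi)
  expect_equal(b0$bias[2, ], rep(0, length(grid)))

  # planted contra-only responder: +1 peak bias
  b1 <- turn_bias(list(mk(1, noise = 0.02)), list(mk(0, noise = 0.02)))
  expect_lt(abs(b1$peak_bias[1] - 1), 0.1)

  # swapping the inputs negates the trace exactly
  b_swap <- turn_bias(list(mk(0, noise = 0)), list(mk(1, noise = 0)))
  b_orig <- turn_bias(list(mk(1, noise = 0)), list(mk(0, noise = 0)))
  expect_equal(b_swap$bias, -b_orig$bias)

  # neurons with too few events are excluded with a warning
  expect_warning(
    b2 <- turn_bias(list(mk(1), snip(matrix(g, 1), grid)),
                    list(mk(1), mk(1))),
    "excluded")
  expect_equal(b2$excluded, 2L)
})

test_that("k-means recovers well-separated populations with canonical names", {
  set.seed(32)
  bl <- blob_features()
  asg <- cluster_assign(bl$x, k = 3, seed = 1,
                        ordering_stat = rowMeans(bl$x),
                        labels = c("C", "B", "A"))
  expect_equal(ari(asg$labels, bl$labels), 1)
  expect_equal(asg$k, 3)
  # label canonicalization: permuting item order leaves class names unchanged
  perm <- sample(nrow(bl$x))
  asg_p <- cluster_assign(bl$x[perm, ], k = 3, seed = 1,
                          ordering_stat = rowMeans(bl$x)[perm],
                          labels = c("C", "B", "A"))
  expect_equal(as.character(asg_p$labels), as.character(asg$labels)[perm])
  # ordering statistic is monotone over the canonical class order
  expect_true(all(diff(asg$ordering_statistic) <= 0))

  expect_error(cluster_assign(matrix(1, 20, 4), k = 3), "identical")
  expect_error(cluster_assign(bl$x, k = 1), "k must be")
  expect_error(cluster_assign(bl$x[1:2, ], k = 3), "exceeds")
})

test_that("clustering is reproducible per seed and stable across seeds", {
  set.seed(33)
  bl <- blob_features(n_per = 40)
  a1 <- cluster_assign(bl$x, k = 3, seed = 7, ordering_stat = rowMeans(bl$x))
  a2 <- cluster_assign(bl$x, k = 3, seed = 7, ordering_stat = rowMeans(bl$x))
  expect_identical(a1$labels, a2$labels)
  aris <- vapply(1:10, function(s) {
    a <- cluster_assign(bl$x, k = 3, seed = s, ordering_stat = rowMeans(bl$x))
    ari(a$labels, bl$labels)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("class proportions reproduce printed percentages and sum to 100", {
  p <- summarize_proportions(c(C = 192, B = 256, A = 585))
  expect_equal(p$pct[p$label == "C"], 18.6)
  expect_equal(p$pct[p$label == "B"], 24.8)
  expect_equal(p$pct[p$label == "A"], 56.6)
  expect_lt(abs(sum(p$pct) - 100), 0.1)

  expect_equal(summarize_proportions(factor(rep("only", 9)))$pct, 100)
  expect_equal(summarize_proportions(c(a = 2, b = 1, c = 1))$pct,
               c(50, 25, 25))
  set.seed(34)
  for (rep in 1:10) {
    counts <- rpois(5, 40) + 1
    expect_lt(abs(sum(summarize_proportions(counts)$pct) - 100), 0.1)
  }
  expect_error(summarize_proportions(integer(0)), "empty")
})

test_that("cross-correlation classes split lead, lag and flat populations", {
  set.seed(35)
  lags <- seq(-2, 2, by = 0.05)
  mk_cc <- function(center, amp, n)
    t(replicate(n, amp * exp(-(lags - center)^2 / (2 * 0.3^2)) +
                  rnorm(length(lags), 0, 0.02)))
  cc <- rbind(mk_cc(0.4, 0.8, 20),          # follows movement
              mk_cc(-0.4, 0.8, 20),         # precedes movement
              mk_cc(0, 0.05, 40))           # flat
  truth <- rep(c("follow", "lead", "flat"), c(20, 20, 40))
  asg <- classify_crosscorr(cc, lags, k = 3, seed = 2)
  lab <- as.character(asg$labels)
  # strongest two classes carry the lead/lag split with correct mean lags
  expect_equal(ari(lab, truth), 1)
  expect_lt(abs(asg$class_mean_lag[["Class 2"]] - 0.4), 0.05)
  expect_lt(abs(asg$class_mean_lag[["Class 3"]] + 0.4), 0.05)
  expect_true(all(lab[truth == "flat"] == "Class 1"))

  # sign flip of the traces preserves class identity, flips correlations
  asg_f <- classify_crosscorr(-cc, lags, k = 3, seed = 2)
  expect_equal(ari(asg_f$labels, truth), 1)

  # all-flat population collapses to one effective class
  flat <- mk_cc(0, 0.03, 40)
  asg0 <- classify_crosscorr(flat, lags, k = 3, seed = 3,
                             noise_floor = 0.3)
  expect_equal(asg0$effective_k, 1L)
})

test_that("avoidance modes are ordered by latency and merge when homogeneous", {
  cfg <- synth_config(n_trials = 120)
  beh <- gen_behavior(cfg, seed = 36)
  av <- beh$log$response == "avoid"
  asg <- classify_modes(beh$speed[av, ], beh$log$latency[av], k = 3, seed = 1)
  expect_true(all(diff(asg$mode_latency) > 0))
  expect_gt(ari(asg$labels, beh$truth$modes[av]), 0.8)

  # a pure Mode 1 session degrades to a single effective mode
  beh1 <- gen_behavior(synth_config(mode_mixture = c(1, 0, 0), n_trials = 60),
                       seed = 37)
  av1 <- beh1$log$response == "avoid"
  asg1 <- classify_modes(beh1$speed[av1, ], beh1$log$latency[av1],
                         k = 3, seed = 1)
  expect_gte(mean(asg1$labels == "Mode 1"), 0.95)

  # a never-avoiding session returns an empty assignment gracefully
  behn <- gen_behavior(synth_config(mode_latency_mean = c(50, 50, 50),
                                    n_trials = 20), seed = 38)
  avn <- behn$log$response == "avoid"
  expect_null(classify_modes(behn$speed[avn, , drop = FALSE],
                             behn$log$latency[avn]))
})
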