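#' Directional activation bias of each neuron around turns
#'
#' For each neuron, the mean event-aligned trace for contraversive turns
#' minus the mean trace for ipsiversive turns on the common grid. The
#' signed extremum of the difference is the neuron's peak bias, used to
#' classify cells by turn-direction preference. Swapping the two inputs
#' negates the bias exactly.
#'
#' @param contra_snippets,ipsi_snippets lists (one element per neuron) of
#'   `snippet_matrix` objects (events x time) on a common grid.
#' @param min_events neurons with fewer events than this in either
#'   direction are excluded with a warning (default 2).
#' @return A `bias_trace` list: `bias` (neurons x time matrix), `grid`,
#'   `peak_bias` (signed extremum per neuron), `excluded` (indices).
#' @export
turn_bias <- function(contra_snippets, ipsi_snippets, min_events = 2L) {
  if (length(contra_snippets) != length(ipsi_snippets))
    stop("need one contra and one ipsi snippet matrix per neuron", call. = FALSE)
  n <- length(contra_snippets)
  if (!n) stop("no neurons supplied", call. = FALSE)
  grid <- attr(contra_snippets[[1L]], "grid")
  ok <- vapply(seq_len(n), function(i)
    nrow(contra_snippets[[i]]) >= min_events &&
    nrow(ipsi_snippets[[i]]) >= min_events, logical(1))
  if (any(!ok))
    warning(sprintf("%d neuron(s) excluded: fewer than %d events in a direction",
                    sum(!ok), min_events), call. = FALSE)
  keep <- which(ok)
  bias <- t(vapply(keep, function(i)
    colMeans(contra_snippets[[i]]) - colMeans(ipsi_snippets[[i]]),
    numeric(length(grid))))
  peak <- apply(bias, 1L, function(v) v[which.max(abs(v))])
  structure(list(bias = bias, grid = grid, peak_bias = peak,
                 neuron = keep, excluded = which(!ok)),
            class = "bias_trace")
}

.kmeans_safe <- function(xs, k, seed, nstart) {
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(xs, centers = k, nstart = nstart,
                                 iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) return(km)
  }
  stop("degenerate clustering: could not find k non-empty clusters",
       call. = FALSE)
}

#' K-means classification with canonical, deterministic labels
#'
#' K-means (multiple restarts under a fixed seed) over a feature matrix or
#' a set of time-series traces, followed by canonical relabelling: classes
#' are ordered by a per-class ordering statistic so that the same
#' populations always receive the same names regardless of k-means'
#' arbitrary cluster numbering or of the input order. Features are
#' standardized (z-scored by column) before clustering.
#'
#' @param x items-by-features numeric matrix (rows may be time-series
#'   traces; columns with zero variance are dropped from the standardized
#'   space but retained for the ordering statistic).
#' @param k number of classes (>= 2, <= rows).
#' @param seed integer seed controlling the restarts.
#' @param ordering_stat per-item numeric vector (e.g. peak turn bias, or
#'   avoid latency) whose per-class mean orders the classes; defaults to
#'   the row means of `x`.
#' @param labels class names assigned in `decreasing` order of the
#'   per-class ordering statistic; defaults to `LETTERS[k:1]` (so the
#'   class with the largest statistic is named last, "C, B, A" style for
#'   k = 3).
#' @param decreasing order classes by decreasing statistic (default
#'   `TRUE`); ties broken by class size (larger first).
#' @param nstart k-means restarts (default 50).
#' @param standardize z-score columns before clustering (default `TRUE`).
#' @return A `class_assignment` list: `labels` (factor, canonical order),
#'   `k`, `inertia` (total within-class sum of squares), `seed`,
#'   `ordering_statistic` (named per-class means), `sizes`, `centers`.
#' @export
cluster_assign <- function(x, k, seed = 1L, ordering_stat = NULL,
                           labels = NULL, decreasing = TRUE,
                           nstart = 50L, standardize = TRUE) {
  x <- as.matrix(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of items", call. = FALSE)
  xs <- x
  if (standardize) {
    sds <- apply(xs, 2L, stats::sd)
    xs <- scale(xs[, sds > 0, drop = FALSE])
    if (!ncol(xs))
      stop("degenerate clustering: all items identical", call. = FALSE)
  }
  if (all(stats::dist(utils::head(xs, 50L)) == 0))
    stop("degenerate clustering: all items identical", call. = FALSE)
  km <- .kmeans_safe(xs, k, seed, nstart)
  stat <- if (is.null(ordering_stat)) rowMeans(x) else ordering_stat
  per_class <- tapply(stat, km$cluster, mean)
  sizes <- tabulate(km$cluster, nbins = k)
  ord <- order(per_class, sizes, decreasing = decreasing)
  if (is.null(labels)) labels <- LETTERS[seq_len(k)][order(seq_len(k),
                                                           decreasing = TRUE)]
  if (length(labels) != k) stop("need exactly k labels", call. = FALSE)
  relabel <- character(k)
  relabel[as.integer(names(per_class))[ord]] <- labels
  lab <- factor(relabel[km$cluster], levels = labels)
  structure(list(labels = lab, k = k, inertia = km$tot.withinss,
                 seed = seed,
                 ordering_statistic = stats::setNames(per_class[ord][seq_len(k)],
                                                      labels),
                 sizes = stats::setNames(sizes[as.integer(names(per_class))[ord]],
                                         labels),
                 centers = km$centers),
            class = "class_assignment")
}

#' Per-class counts and percentages
#'
#' @param x a `class_assignment`, a factor of labels, or a named vector of
#'   class counts.
#' @param digits decimals for the percentage (default 1, the reporting
#'   convention).
#' @return Data frame: `label`, `n`, `pct` (percentages of the total,
#'   rounded to `digits`).
#' @export
summarize_proportions <- function(x, digits = 1) {
  counts <- if (inherits(x, "class_assignment")) table(x$labels)
            else if (is.factor(x) || is.character(x)) table(x)
            else x
  n_ <- as.vector(counts)
  nm <- names(counts)
  if (is.null(nm)) nm <- as.character(seq_along(n_))
  if (!length(n_) || sum(n_) == 0) stop("empty assignment", call. = FALSE)
  data.frame(label = nm, n = n_,
             pct = round(100 * n_ / sum(n_), digits),
             stringsAsFactors = FALSE)
}

#' Classify neurons by their movement cross-correlation functions
#'
#' K-means over cross-correlation traces on a common lag grid, with the
#' canonical ordering used for movement-coupling classes: classes are
#' numbered by increasing correlation strength (mean of the per-item peak
#' |r|), and among the strongest classes the one whose mean peak lag is
#' positive (activity following movement) precedes the one whose lag is
#' negative (activity preceding movement). Per-class mean peak lags are
#' reported so lead/lag identity is explicit.
#'
#' @param cc items-by-lags matrix of cross-correlation values, or a list
#'   of `crosscorr_result` objects on a common lag grid.
#' @param lags lag grid in seconds (taken from the list if omitted).
#' @param k number of classes (default 4).
#' @param seed integer seed.
#' @param noise_floor optional correlation strength below which classes
#'   are not considered distinct couplings: classes whose mean peak |r|
#'   all fall under the floor collapse into one effective class
#'   (`effective_k`); `NULL` (default) keeps all k. A reasonable floor
#'   for n paired samples is about `3 / sqrt(n)`.
#' @return A `class_assignment` with extra elements `peak_lag` (per item,
#'   s), `class_mean_lag`, `class_mean_strength` (named per class
#'   `"Class 1"` ... `"Class k"`) and `effective_k`.
#' @export
classify_crosscorr <- function(cc, lags = NULL, k = 4L, seed = 1L,
                               noise_floor = NULL) {
  if (is.list(cc) && !is.matrix(cc)) {
    lags <- cc[[1L]]$lags
    cc <- t(vapply(cc, function(r) r$r, numeric(length(lags))))
  }
  if (is.null(lags)) stop("lag grid required", call. = FALSE)
  strength <- apply(cc, 1L, function(r) max(abs(r)))
  peak_lag <- lags[apply(cc, 1L, function(r) which.max(abs(r)))]
  asg <- cluster_assign(cc, k = k, seed = seed, ordering_stat = strength,
                        labels = paste("Class", seq_len(k)),
                        decreasing = FALSE, standardize = FALSE)
  # among the two strongest classes, positive mean lag is named first
  lev <- levels(asg$labels)
  mean_lag <- tapply(peak_lag, asg$labels, mean)
  if (k >= 2L) {
    top2 <- lev[c(k - 1L, k)]
    if (diff(mean_lag[top2]) > 0) {       # stronger-lagged order wrong way round
      lab <- as.character(asg$labels)
      lab[lab == top2[1L]] <- ".swap."
      lab[lab == top2[2L]] <- top2[1L]
      lab[lab == ".swap."] <- top2[2L]
      asg$labels <- factor(lab, levels = lev)
      mean_lag <- tapply(peak_lag, asg$labels, mean)
    }
  }
  asg$peak_lag <- peak_lag
  asg$class_mean_lag <- mean_lag
  asg$class_mean_strength <- tapply(strength, asg$labels, mean)
  asg$sizes <- table(asg$labels)
  asg$effective_k <- if (is.null(noise_floor)) k
                     else sum(asg$class_mean_strength >= noise_floor) +
                          as.integer(any(asg$class_mean_strength < noise_floor))
  asg
}

#' Classify avoidance trials into response modes
#'
#' K-means over CS-aligned speed time series (the trial-level scheme for
#' avoidance modes), with classes named `"Mode 1"`, `"Mode 2"`, ... in
#' ascending order of mean avoid latency: Mode 1 collects the rapid
#' avoids, higher modes the increasingly delayed, cautious ones. When the
#' trials do not actually contain `k` distinguishable modes, clusters
#' whose mean latencies lie within `min_sep` seconds of each other are
#' merged into one effective mode, so a homogeneous session degrades to a
#' single class instead of an arbitrary split. An empty trial set returns
#' an empty assignment rather than an error.
#'
#' @param speed trials x time matrix of CS-aligned speed traces.
#' @param latency per-trial avoid latency (s), the ordering statistic.
#' @param k number of modes (default 3).
#' @param seed integer seed.
#' @param min_sep minimum separation of cluster mean latencies before
#'   merging (s, default 0.75; 0 disables merging).
#' @return A `class_assignment` whose labels are `"Mode 1"` ... (possibly
#'   fewer after merging), plus `mode_latency` (mean per mode); or
#'   `NULL` for an empty trial set.
#' @export
classify_modes <- function(speed, latency, k = 3L, seed = 1L,
                           min_sep = 0.75) {
  if (is.null(speed) || nrow(speed) == 0L) return(NULL)
  if (nrow(speed) < k) k <- max(1L, nrow(speed) - 1L)
  if (k < 2L) {
    lab <- factor(rep("Mode 1", nrow(speed)), levels = "Mode 1")
    return(structure(list(labels = lab, k = 1L, inertia = 0, seed = seed,
                          ordering_statistic = c("Mode 1" = mean(latency)),
                          sizes = c("Mode 1" = nrow(speed)),
                          mode_latency = c("Mode 1" = mean(latency))),
                     class = "class_assignment"))
  }
  asg <- cluster_assign(speed, k = k, seed = seed, ordering_stat = latency,
                        labels = paste("Mode", seq_len(k)),
                        decreasing = FALSE, standardize = FALSE)
  # merge modes whose latency centers are indistinguishable
  if (min_sep > 0) {
    means <- tapply(latency, asg$labels, mean)
    lev <- levels(asg$labels)
    grp <- cumsum(c(TRUE, diff(means) >= min_sep))
    if (max(grp) < k) {
      new_names <- paste("Mode", grp)
      map <- stats::setNames(new_names, lev)
      lab <- factor(unname(map[as.character(asg$labels)]),
                    levels = unique(new_names))
      asg$labels <- lab
      asg$k <- length(levels(lab))
      asg$sizes <- table(lab)
      asg$ordering_statistic <- tapply(latency, lab, mean)
    }
  }
  asg$mode_latency <- tapply(latency, asg$labels, mean)
  asg
}
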