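# Independent brute-force oracles and small fixtures shared across tests.
# Oracles are written naively (explicit sums, exhaustive enumeration) so they
# stay independent of the implementation paths they check.

# naive implementation of the seven per-channel statistics
brute_features <- function(x, fs = 1) {
  n <- length(x)
  mu <- sum(x) / n
  t <- (seq_len(n) - 1) / fs
  tbar <- sum(t) / n
  slope <- sum((t - tbar) * (x - mu)) / sum((t - tbar)^2)
  v <- sum((x - mu)^2) / (n - 1)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(mean = mu, max = max(x), slope = slope, var = v,
    skew = m3 / m2^1.5, kurt = m4 / m2^2, median = med)
}

# exhaustive minimum-SSE 2-clustering of a 1-D instance: the optimum is a
# contiguous split of the sorted values
brute_kmeans_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  for (k in seq_len(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, centers = sort(c(mean(a), mean(b))))
  }
  best
}

# exhaustive minimum-SSE 2-partition of up to ~15 points in any dimension
brute_kmeans_parts <- function(points) {
  n <- nrow(points)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {  # point 1 fixed in cluster 1
    grp <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    if (length(unique(grp)) < 2) next
    c1 <- colMeans(points[grp == 1L, , drop = FALSE])
    c2 <- colMeans(points[grp == 2L, , drop = FALSE])
    sse <- sum(sweep(points[grp == 1L, , drop = FALSE], 2, c1)^2) +
      sum(sweep(points[grp == 2L, , drop = FALSE], 2, c2)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, centers = rbind(c1, c2))
  }
  best
}

# small geometry for pipeline tests: 2 subjects x 1 session x 20 trials,
# few channels, EEG already at its post-downsampling rate
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, n_sessions = 1, trials_per_session = 20,
         n_nirs_channels = 4, n_eeg_channels = 4, fs_eeg_raw = 200),
    list(...))
  do.call(sim_config, args)
}

# i.i.d. noise feature table with balanced labels (no class signal at all)
noise_table <- function(n = 400, d = 20, seed = 1) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * d), n, d,
                       dimnames = list(NULL, paste0("f", 1:d))),
                rep(c(1L, 2L), length.out = n), set = "noise")
}
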