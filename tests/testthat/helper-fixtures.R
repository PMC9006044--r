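# Shared fixtures: small deterministic objects built in code.

# A symmetric FC-like matrix with prescribed entries (diag 0).
make_sym <- function(n, entries) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- entries
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

as_fc <- function(M, subject = "s1", group = "g", normalized = FALSE) {
  structure(M, subject_id = subject, group = group, normalized = normalized,
            class = c("fc_matrix", "matrix", "array"))
}

# Constant-signal run with additive spikes at given volume indices: DVARS is
# exactly zero off-spike, so outlier identification is fully deterministic.
constant_spike_run <- function(n_volumes, spike_at, amplitude = 5,
                               n_channels = 19) {
  X <- matrix(0, n_volumes, n_channels)
  if (length(spike_at)) X[spike_at, ] <- amplitude
  bold_run(X, subject_id = "const", repetition_time_s = 0.392)
}

# Exhaustive-search oracle for the minimum-outlier contiguous window.
brute_force_window <- function(mask, len) {
  n <- length(mask)
  counts <- vapply(seq_len(n - len + 1),
                   function(s) sum(mask[s:(s + len - 1)]), 0L)
  s <- which.min(counts)
  list(window_start = s, n_outliers_in_window = counts[s])
}

# From-scratch one-way repeated-measures ANOVA + Greenhouse-Geisser epsilon
# via the double-centred covariance of the raw condition scores; an
# independent route from the orthonormal-contrast implementation.
oneway_rm_oracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cm <- colMeans(Y); rm_ <- rowMeans(Y)
  ss_cond <- n * sum((cm - grand)^2)
  ss_err <- sum((Y - outer(rm_, rep(1, k)) -
                   outer(rep(1, n), cm) + grand)^2)
  Fval <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  S <- stats::cov(Y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
  list(F = Fval, df1 = k - 1, df2 = (n - 1) * (k - 1), epsilon = eps)
}

# Brute-force average-linkage (UPGMA) agglomeration: returns merge heights
# and the k-cluster partition, tracking all singleton members explicitly.
brute_force_upgma <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partition <- NULL
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    if (length(clusters) == k) {
      partition <- integer(n)
      for (c_i in seq_along(clusters)) partition[clusters[[c_i]]] <- c_i
    }
  }
  list(heights = heights, partition = partition)
}

# Canonical form of a partition (labels renumbered by first appearance) so
# partitions can be compared irrespective of label identity.
canon_partition <- function(p) as.integer(factor(p, levels = unique(p)))
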