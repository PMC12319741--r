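#' Spearman correlation clusters between an ECG difference and EEG differences
#'
#' For each channel-time sample, the Spearman rank correlation across
#' subjects between the ECG condition difference at that time point and the
#' EEG condition difference at that channel and time (average ranks for
#' ties). Correlations are converted to t statistics
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))`), thresholded two-tailed at
#' `alpha`, and clustered as in [find_clusters()]; clusters are kept only if
#' they span at least `min_channels` neighbouring channels. The null
#' distribution permutes the subject assignment of the ECG difference time
#' courses, each time retaining the largest surviving cluster statistic; a
#' cluster is significant when its |summed t| exceeds 95% of the null.
#'
#' @param delta_ecg subjects x time matrix of ECG condition differences.
#' @param delta_eeg subjects x channels x time array of EEG condition
#'   differences.
#' @param adjacency `channel_adjacency` matrix.
#' @param min_channels minimum number of distinct channels per cluster
#'   (default 2).
#' @param n_perm permutations (default 1000).
#' @param alpha sample-level threshold (default 0.05).
#' @param seed permutation seed.
#' @return a `cluster_result` with an extra `rho_map` field.
#' @export
spearman_cluster_corr <- function(delta_ecg, delta_eeg, adjacency,
                                  min_channels = 2, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  E <- as.matrix(delta_ecg)
  G <- as_3d(delta_eeg)
  n <- nrow(E)
  if (n < 3L) stop_hv("need >= 3 subjects")
  if (dim(G)[1] != n || dim(G)[3] != ncol(E))
    stop_hv("delta_ecg and delta_eeg axes do not match")
  if (any(apply(E, 2, stats::sd) == 0))
    stop_hv("constant delta_ecg across subjects: correlation undefined")
  ch <- dim(G)[2]; len <- dim(G)[3]

  std_ranks <- function(M) {                     # column-wise standardised ranks
    R <- apply(M, 2, rank)                       # average ranks for ties
    R <- sweep(R, 2, colMeans(R))
    s <- sqrt(colSums(R^2))
    s[s == 0] <- 1
    sweep(R, 2, s, "/")
  }
  Er <- std_ranks(E)                             # n x len
  Gm <- matrix(G, nrow = n)                      # n x (ch*len)
  Gr <- std_ranks(Gm)
  tcol <- rep(seq_len(len), each = ch)           # column -> time index

  rho_of <- function(order_idx) colSums(Er[order_idx, tcol, drop = FALSE] * Gr)
  to_result <- function(rho) {
    rho <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rho))
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    pv <- 2 * stats::pt(abs(tv), n - 2, lower.tail = FALSE)
    list(t = matrix(tv, ch, len), p = matrix(pv, ch, len),
         rho = matrix(rho, ch, len))
  }
  keep_big <- function(clusters) {
    Filter(function(cl) length(unique(cl$members[, "channel"])) >= min_channels,
           clusters)
  }

  obs <- to_result(rho_of(seq_len(n)))
  clusters <- keep_big(find_clusters(obs$t, obs$p, adjacency, alpha))

  perm_idx <- with_seed(seed, replicate(n_perm, sample(n), simplify = FALSE))
  null_max <- vapply(perm_idx, function(ord) {
    pm <- to_result(rho_of(ord))
    cl <- keep_big(find_clusters(pm$t, pm$p, adjacency, alpha))
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "sum_t")))
  }, numeric(1))

  for (i in seq_along(clusters)) {
    s <- abs(clusters[[i]]$sum_t)
    clusters[[i]]$p_mc <- max(sum(null_max >= s), 1) / n_perm
    clusters[[i]]$significant <- s > empirical_cutoff(null_max, 0.95)
  }
  res <- new_cluster_result(clusters, obs$t, n - 2, null_max, n_perm, alpha,
                            channels = rownames(adjacency), seed = seed)
  res$rho_map <- obs$rho
  res
}
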