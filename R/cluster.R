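# ---- t maps ----------------------------------------------------------------

# Coerce subjects/trials x channels x time input to a 3D array.
as_3d <- function(x) {
  if (inherits(x, "epoch_set")) return(x$data)
  if (is.matrix(x)) return(array(x, dim = c(nrow(x), 1L, ncol(x))))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_hv("expected an epoch_set, a units x time matrix, or a units x channels x time array")
}

#' Paired t map over subjects
#'
#' Per channel-time sample, the paired t statistic over subjects
#' (`df = n - 1`) with its two-tailed p value. Samples with zero variance of
#' the differences get `t = 0` (counted in the `n_zero_variance` attribute)
#' rather than an infinite statistic.
#'
#' @param cond_a,cond_b subjects x channels x time arrays (or matrices for a
#'   single channel) of per-subject evoked responses, matching axes.
#' @return list with `t` and `p` (channels x time matrices), `df`.
#' @export
paired_t_map <- function(cond_a, cond_b) {
  A <- as_3d(cond_a); B <- as_3d(cond_b)
  if (!identical(dim(A), dim(B))) stop_hv("condition arrays differ in shape")
  n <- dim(A)[1]
  if (n < 2L) stop_hv("need >= 2 paired subjects")
  D <- A - B
  dm <- matrix(D, nrow = n)                       # n x (ch*time)
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tv <- ifelse(v > 0, m / sqrt(v / n), 0)
  n_zero <- sum(v == 0 & m != 0)
  if (n_zero) message(sprintf("paired_t_map: %d sample(s) had zero difference variance; t set to 0", n_zero))
  p <- 2 * stats::pt(abs(tv), df = n - 1, lower.tail = FALSE)
  ch <- dim(A)[2]; len <- dim(A)[3]
  list(t = matrix(tv, ch, len), p = matrix(p, ch, len), df = n - 1,
       n_zero_variance = n_zero)
}

#' Independent-samples t map over trials
#'
#' Pooled-variance two-sample t per channel-time sample
#' (`df = n_a + n_b - 2`), for trial-level designs where the two conditions
#' are disjoint trial groups. Zero pooled variance gives `t = 0`.
#'
#' @param cond_a,cond_b trials x channels x time arrays (or matrices).
#' @return list with `t`, `p`, `df`.
#' @export
indep_t_map <- function(cond_a, cond_b) {
  A <- as_3d(cond_a); B <- as_3d(cond_b)
  if (!identical(dim(A)[-1], dim(B)[-1])) stop_hv("channel/time axes differ")
  na <- dim(A)[1]; nb <- dim(B)[1]
  if (na < 2L || nb < 2L) stop_hv("need >= 2 trials per group")
  am <- matrix(A, nrow = na); bm <- matrix(B, nrow = nb)
  ma <- colMeans(am); mb <- colMeans(bm)
  ssa <- colSums(am^2) - na * ma^2
  ssb <- colSums(bm^2) - nb * mb^2
  df <- na + nb - 2
  vp <- (ssa + ssb) / df
  se <- sqrt(vp * (1 / na + 1 / nb))
  tv <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- 2 * stats::pt(abs(tv), df = df, lower.tail = FALSE)
  ch <- dim(A)[2]; len <- dim(A)[3]
  list(t = matrix(tv, ch, len), p = matrix(p, ch, len), df = df)
}

# ---- cluster formation -----------------------------------------------------

# Connected components of a channels x time mask under the relation: same
# channel at adjacent time samples, or neighbouring channels at the same time
# sample. Segments (temporal runs per channel) are built first, then merged
# across adjacency edges with union-find; this keeps the cost proportional to
# the number of runs rather than the grid size.
mask_components <- function(mask, adj = NULL) {
  nch <- nrow(mask); len <- ncol(mask)
  segs <- list()
  for (ch in seq_len(nch)) {
    r <- rle(as.vector(mask[ch, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      segs[[length(segs) + 1L]] <- c(ch, starts[j], ends[j])
  }
  if (!length(segs)) return(list())
  S <- do.call(rbind, segs)
  ns <- nrow(S)
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(adj) && nch > 1L) {
    by_ch <- split(seq_len(ns), S[, 1])
    for (a in seq_len(nch - 1L)) for (b in (a + 1L):nch) {
      if (!adj[a, b]) next
      ia <- by_ch[[as.character(a)]]; ib <- by_ch[[as.character(b)]]
      if (is.null(ia) || is.null(ib)) next
      for (i in ia) for (j in ib) {
        if (S[i, 2] <= S[j, 3] && S[j, 2] <= S[i, 3]) {  # time overlap
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  lapply(split(seq_len(ns), roots), function(idx) S[idx, , drop = FALSE])
}

cluster_members <- function(comp) {
  do.call(rbind, lapply(seq_len(nrow(comp)), function(i)
    cbind(channel = comp[i, 1], time = comp[i, 2]:comp[i, 3])))
}

#' Form spatio-temporal clusters of suprathreshold samples
#'
#' Positive and negative suprathreshold samples (`p_map < cluster_alpha`)
#' are clustered separately under the adjacency x temporal-succession
#' relation; each cluster reports the sum of its member t values.
#'
#' @param t_map channels x time matrix of t statistics.
#' @param p_map matching matrix of two-tailed p values.
#' @param adjacency a `channel_adjacency` matrix covering all rows of
#'   `t_map` (ignored for a single channel).
#' @param cluster_alpha sample-level threshold (default 0.05).
#' @return list of clusters: each with `members` (matrix of channel/time
#'   indices), `polarity` (+1/-1), `sum_t`. Empty list when nothing is
#'   suprathreshold.
#' @export
find_clusters <- function(t_map, p_map, adjacency = NULL,
                          cluster_alpha = 0.05) {
  t_map <- as.matrix(t_map); p_map <- as.matrix(p_map)
  if (nrow(t_map) > 1L) {
    if (is.null(adjacency)) stop_hv("adjacency required for > 1 channel")
    if (nrow(adjacency) != nrow(t_map))
      stop_hv("adjacency does not cover all channels")
  }
  out <- list()
  for (pol in c(1, -1)) {
    mask <- (p_map < cluster_alpha) & (sign(t_map) == pol)
    for (comp in mask_components(mask, adjacency)) {
      mem <- cluster_members(comp)
      out[[length(out) + 1L]] <- list(
        members = mem, polarity = pol,
        sum_t = sum(t_map[mem]))
    }
  }
  # largest |sum_t| first
  if (length(out))
    out <- out[order(-abs(vapply(out, `[[`, numeric(1), "sum_t")))]
  out
}

max_cluster_stat <- function(t_map, p_map, adjacency, cluster_alpha) {
  cl <- find_clusters(t_map, p_map, adjacency, cluster_alpha)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "sum_t")))
}

# ---- permutation engines ---------------------------------------------------

new_cluster_result <- function(clusters, t_map, df, null_max, n_perm,
                               cluster_alpha, time_ms = NULL,
                               channels = NULL, seed = NULL) {
  max_abs <- if (length(clusters))
    max(abs(vapply(clusters, `[[`, numeric(1), "sum_t"))) else 0
  structure(list(clusters = clusters, t_map = t_map, df = df,
                 null_max = null_max, n_perm = n_perm,
                 cluster_alpha = cluster_alpha,
                 max_abs_sum_t = max_abs,
                 time_ms = time_ms, channels = channels, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s); sample-level alpha %g, %s permutation(s)\n",
              length(x$clusters), x$cluster_alpha,
              if (is.null(x$n_perm)) "no" else format(x$n_perm)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    span <- if (!is.null(x$time_ms))
      sprintf(" [%g, %g] ms", min(x$time_ms[cl$members[, "time"]]),
              max(x$time_ms[cl$members[, "time"]])) else ""
    cat(sprintf("  #%d %s sum(t) = %.2f%s, %d sample(s)%s\n", i,
                if (cl$polarity > 0) "pos" else "neg", cl$sum_t, span,
                nrow(cl$members),
                if (!is.null(cl$p_mc)) sprintf(", p = %.4g%s", cl$p_mc,
                                               if (cl$p_mc < 0.05) " *" else "")
                else ""))
  }
  invisible(x)
}

rademacher_matrix <- function(n_perm, n, seed, exact = FALSE) {
  if (exact) {
    if (n > 20L) stop_hv("exhaustive enumeration limited to n <= 20")
    G <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(G) <- NULL
    return(G)
  }
  with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                         n_perm, n))
}

# Null distribution of the max |cluster sum(t)| for the paired design:
# within-subject condition-label flips = random signs on the differences.
paired_null_max <- function(D, ch, len, adjacency, cluster_alpha, n_perm,
                            seed, exact = FALSE) {
  n <- nrow(D)
  S <- rademacher_matrix(n_perm, n, seed, exact)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  V <- (ssq - n * M^2) / (n - 1)
  V[V < 0] <- 0
  Tm <- ifelse(V > 0, M / sqrt(V / n), 0)
  df <- n - 1
  Pm <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
  vapply(seq_len(nrow(S)), function(i)
    max_cluster_stat(matrix(Tm[i, ], ch, len), matrix(Pm[i, ], ch, len),
                     adjacency, cluster_alpha), numeric(1))
}

# Null for the independent design: permute group labels across trials.
indep_null_max <- function(X, na, ch, len, adjacency, cluster_alpha, n_perm,
                           seed) {
  n <- nrow(X)
  nb <- n - na
  df <- n - 2
  perms <- with_seed(seed, replicate(n_perm, sample(n, na)))
  P <- matrix(0, n_perm, n)
  P[cbind(rep(seq_len(n_perm), each = na), as.vector(perms))] <- 1
  X2 <- X^2
  tot <- matrix(colSums(X), n_perm, ncol(X), byrow = TRUE)
  tot2 <- matrix(colSums(X2), n_perm, ncol(X), byrow = TRUE)
  SA <- P %*% X; SA2 <- P %*% X2
  SB <- tot - SA; SB2 <- tot2 - SA2
  MA <- SA / na; MB <- SB / nb
  ss <- (SA2 - na * MA^2) + (SB2 - nb * MB^2)
  ss[ss < 0] <- 0
  SE <- sqrt(ss / df * (1 / na + 1 / nb))
  Tm <- ifelse(SE > 0, (MA - MB) / SE, 0)
  Pm <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
  vapply(seq_len(n_perm), function(i)
    max_cluster_stat(matrix(Tm[i, ], ch, len), matrix(Pm[i, ], ch, len),
                     adjacency, cluster_alpha), numeric(1))
}

#' Cluster-based permutation t test
#'
#' Spatio-temporal cluster-based permutation test: suprathreshold samples
#' (two-tailed p < `cluster_alpha`) adjacent in space and time are summed
#' into cluster statistics; the null is built by randomising the condition
#' labels — within-subject sign flips of the paired differences for the
#' paired design, group-label permutations across trials for the independent
#' design — each time retaining the maximum |summed t| across all clusters of
#' either polarity (0 when none). Each observed cluster's Monte-Carlo p is
#' `max(count(null >= |sum_t|), 1) / n_perm`, so the attainable floor with
#' 1000 permutations is exactly 0.001.
#'
#' @param cond_a,cond_b per-subject evoked arrays (paired) or per-trial
#'   arrays (independent): units x channels x time, or units x time matrices
#'   for one channel; `epoch_set` objects are accepted.
#' @param adjacency `channel_adjacency` matrix (not needed for one channel).
#' @param n_perm number of permutations (default 1000).
#' @param cluster_alpha sample-level threshold (default 0.05, two-tailed).
#' @param seed permutation seed.
#' @param paired `TRUE` for the within-subject design (default), `FALSE` for
#'   disjoint trial groups.
#' @param exact paired design only: enumerate all `2^n` sign assignments
#'   instead of sampling (allowed for n <= 12 by default; a warning is given
#'   when `n_perm` exceeds the number of distinct assignments).
#' @return a `cluster_result`: observed clusters (with `p_mc` each), the t
#'   map, the permutation null vector `null_max`, and `max_abs_sum_t`.
#' @examples
#' a <- matrix(rnorm(8 * 30), 8); b <- matrix(rnorm(8 * 30), 8)
#' cluster_permutation_test(a, b, n_perm = 200, seed = 1)
#' @export
cluster_permutation_test <- function(cond_a, cond_b, adjacency = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1, paired = TRUE, exact = FALSE) {
  check_scalar(n_perm, "n_perm", lower = 1)
  if (cluster_alpha <= 0 || cluster_alpha >= 1)
    stop_hv("'cluster_alpha' must be in (0, 1)")
  A <- as_3d(cond_a); B <- as_3d(cond_b)
  ch <- dim(A)[2]; len <- dim(A)[3]
  if (ch == 1L) adjacency <- NULL
  if (paired) {
    tm <- paired_t_map(A, B)
    n <- dim(A)[1]
    if (!exact && n_perm > 2^n)
      warning(sprintf("n_perm = %d exceeds the %d distinct sign assignments for n = %d; consider exact = TRUE", n_perm, 2^n, n))
    if (exact && n > 12L)
      stop_hv("exhaustive enumeration offered for n <= 12 subjects only")
    D <- matrix(A - B, nrow = n)
    null_max <- paired_null_max(D, ch, len, adjacency, cluster_alpha,
                                n_perm, seed, exact)
  } else {
    tm <- indep_t_map(A, B)
    X <- rbind(matrix(A, nrow = dim(A)[1]), matrix(B, nrow = dim(B)[1]))
    null_max <- indep_null_max(X, dim(A)[1], ch, len, adjacency,
                               cluster_alpha, n_perm, seed)
  }
  clusters <- find_clusters(tm$t, tm$p, adjacency, cluster_alpha)
  n_eff <- length(null_max)
  for (i in seq_along(clusters)) {
    s <- abs(clusters[[i]]$sum_t)
    # count ties (e.g. the identity assignment under exhaustive enumeration)
    # up to floating noise
    tol <- 1e-9 * max(1, s)
    clusters[[i]]$p_mc <- max(sum(null_max >= s - tol), 1) / n_eff
  }
  new_cluster_result(clusters, tm$t, tm$df, null_max, n_eff, cluster_alpha,
                     channels = rownames(adjacency), seed = seed)
}

#' Temporal cluster-based permutation t test
#'
#' Single-channel specialisation of [cluster_permutation_test()] (trivial
#' adjacency): clusters are runs of consecutive suprathreshold samples. The
#' default design is independent trial groups, matching trial-sorted
#' comparisons; set `paired = TRUE` for subject-level time courses (e.g.
#' condition-wise ECG averages).
#'
#' @param cond_a,cond_b units x time matrices (or `epoch_set`s with one
#'   channel).
#' @inheritParams cluster_permutation_test
#' @return a `cluster_result`.
#' @export
temporal_cluster_test <- function(cond_a, cond_b, n_perm = 1000,
                                  cluster_alpha = 0.05, seed = 1,
                                  paired = FALSE, exact = FALSE) {
  A <- as_3d(cond_a); B <- as_3d(cond_b)
  if (dim(A)[2] != 1L || dim(B)[2] != 1L)
    stop_hv("temporal_cluster_test expects single-channel data")
  cluster_permutation_test(A, B, adjacency = NULL, n_perm = n_perm,
                           cluster_alpha = cluster_alpha, seed = seed,
                           paired = paired, exact = exact)
}
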