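test_that("paired t maps follow the closed form and its symmetries", {
  set.seed(3)
  A <- array(rnorm(6 * 2 * 10), c(6, 2, 10))
  # identical conditions: all t = 0
  tm0 <- paired_t_map(A, A)
  expect_true(all(tm0$t == 0))
  # constant difference d with known sd: t = d * sqrt(n) / s everywhere
  n <- 8
  d <- 1.5
  noise <- matrix(rnorm(n * 12), n, 12)
  noise <- sweep(noise, 2, colMeans(noise))   # zero-mean per sample
  B <- array(0, c(n, 1, 12))
  Aa <- array(d + noise, c(n, 1, 12))
  tm <- paired_t_map(Aa, B)
  s <- apply(noise, 2, sd)
  expect_equal(as.vector(tm$t), d * sqrt(n) / s, tolerance = 1e-9)
  expect_equal(tm$df, n - 1)
  # antisymmetry
  tm_rev <- paired_t_map(B, Aa)
  expect_equal(tm_rev$t, -tm$t)
  # zero-variance samples give t = 0 with a note
  Z <- array(0, c(4, 1, 3)); O <- array(1, c(4, 1, 3))
  expect_message(tmz <- paired_t_map(O, Z), "zero difference variance")
  expect_true(all(tmz$t == 0))
})

test_that("independent t maps match t.test with pooled variance", {
  set.seed(4)
  a <- matrix(rnorm(30, 1), 15, 2); b <- matrix(rnorm(24), 12, 2)
  tm <- indep_t_map(array(a, c(15, 1, 2)), array(b, c(12, 1, 2)))
  for (j in 1:2) {
    ref <- t.test(a[, j], b[, j], var.equal = TRUE)
    expect_equal(tm$t[1, j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(tm$p[1, j], ref$p.value, tolerance = 1e-9)
  }
  expect_equal(tm$df, 25)
})

test_that("cluster formation matches a brute-force flood fill", {
  # single channel: a run of length L with t = 3 sums to 3L
  tmap <- matrix(0, 1, 20); tmap[1, 6:11] <- 3
  pmap <- matrix(1, 1, 20); pmap[1, 6:11] <- 0.01
  cl <- find_clusters(tmap, pmap, cluster_alpha = 0.05)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$sum_t, 18)
  expect_equal(cl[[1]]$polarity, 1)

  # two suprathreshold samples on non-neighbouring channels, same time
  adj3 <- chain_adjacency(c("a", "b", "c"))   # a-b-c: a and c not adjacent
  tmap <- matrix(0, 3, 5); tmap[1, 3] <- 4; tmap[3, 3] <- 4
  pmap <- matrix(1, 3, 5); pmap[1, 3] <- 0.01; pmap[3, 3] <- 0.01
  expect_length(find_clusters(tmap, pmap, adj3), 2)

  # randomized small maps against the oracle
  set.seed(9)
  for (i in 1:25) {
    nch <- sample(2:4, 1); len <- sample(4:6, 1)
    labs <- letters[seq_len(nch)]
    edges <- t(combn(labs, 2))
    edges <- edges[runif(nrow(edges)) < 0.5, , drop = FALSE]
    adj <- channel_adjacency(edges, labs)
    tmap <- matrix(rnorm(nch * len, sd = 2), nch, len)
    pmap <- matrix(0.2, nch, len); pmap[abs(tmap) > 2] <- 0.01
    cl <- find_clusters(tmap, pmap, adj, 0.05)
    for (pol in c(1, -1)) {
      mask <- pmap < 0.05 & sign(tmap) == pol
      lab <- oracle_components(mask, adj)
      n_comp <- max(lab)
      got <- Filter(function(x) x$polarity == pol, cl)
      expect_length(got, n_comp)
      # identical member partitions
      oracle_sets <- lapply(seq_len(n_comp), function(k)
        as.numeric(sort(which(lab == k))))
      got_sets <- lapply(got, function(x)
        unname(sort((x$members[, "time"] - 1) * nch + x$members[, "channel"])))
      expect_setequal(got_sets, oracle_sets)
    }
  }
})

test_that("permutation p-values have the stated floor and conventions", {
  # huge constant effect, 20 subjects: observed beats every null draw, and
  # with 1000 permutations the floor is exactly 0.001
  set.seed(5)
  n <- 20
  A <- array(5 + rnorm(n * 30, sd = 0.2), c(n, 1, 30))
  B <- array(rnorm(n * 30, sd = 0.2), c(n, 1, 30))
  res <- cluster_permutation_test(A, B, n_perm = 1000, seed = 1)
  expect_equal(res$clusters[[1]]$p_mc, 0.001)
  # identical conditions: no clusters at all
  res0 <- cluster_permutation_test(A, A, n_perm = 100, seed = 1)
  expect_length(res0$clusters, 0)
  expect_equal(res0$max_abs_sum_t, 0)
  # antisymmetry: swapping conditions flips polarity, keeps |sum_t|
  res_rev <- cluster_permutation_test(B, A, n_perm = 100, seed = 1)
  res_fwd <- cluster_permutation_test(A, B, n_perm = 100, seed = 1)
  expect_equal(res_rev$clusters[[1]]$sum_t, -res_fwd$clusters[[1]]$sum_t)
  expect_equal(res_rev$t_map, -res_fwd$t_map)
  # warning when n_perm exceeds the distinct assignments
  A4 <- A[1:4, , , drop = FALSE]; B4 <- B[1:4, , , drop = FALSE]
  expect_warning(cluster_permutation_test(A4, B4, n_perm = 100, seed = 1),
                 "distinct sign assignments")
})

test_that("Monte-Carlo p agrees with exhaustive sign-flip enumeration", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(6:8, 1); len <- sample(8:12, 1)
    eff <- runif(1, 0, 1.2)
    A <- matrix(rnorm(n * len) + eff, n, len)
    B <- matrix(rnorm(n * len), n, len)
    oracle <- oracle_signflip_p(A, B)
    mc <- suppressWarnings(
      cluster_permutation_test(A, B, n_perm = 400, seed = i))
    exact <- cluster_permutation_test(A, B, exact = TRUE, seed = i)
    if (length(mc$clusters)) {
      s_obs <- abs(mc$clusters[[1]]$sum_t)
      p_exact <- sum(exact$null_max >= s_obs - 1e-9 * max(1, s_obs)) /
        length(exact$null_max)
      # the package's exhaustive null reproduces the independent oracle
      expect_equal(exact$max_abs_sum_t, oracle$observed, tolerance = 1e-9)
      expect_equal(p_exact, oracle$p, tolerance = 1e-9)
      # Monte-Carlo p within 3 binomial SEs of the exhaustive p
      se <- sqrt(oracle$p * (1 - oracle$p) / 400)
      expect_lt(abs(mc$clusters[[1]]$p_mc - oracle$p), 3 * se + 1 / 400)
    } else {
      expect_equal(oracle$observed, 0, tolerance = 1e-9)
    }
  }
})

test_that("the temporal test is the single-channel specialisation", {
  set.seed(7)
  a <- matrix(rnorm(40 * 25, 0.8), 40, 25)
  b <- matrix(rnorm(40 * 25), 40, 25)
  r1 <- temporal_cluster_test(a, b, n_perm = 150, seed = 3)
  r2 <- cluster_permutation_test(array(a, c(40, 1, 25)),
                                 array(b, c(40, 1, 25)),
                                 n_perm = 150, seed = 3, paired = FALSE)
  expect_equal(r1$t_map, r2$t_map)
  expect_equal(r1$null_max, r2$null_max)
  expect_identical(temporal_cluster_test(a, a, n_perm = 50,
                                         seed = 1)$clusters, list())
  expect_error(temporal_cluster_test(array(rnorm(8), c(2, 2, 2)),
                                     array(rnorm(8), c(2, 2, 2))),
               "single-channel")
})

test_that("label exchangeability keeps the false-positive rate nominal", {
  # null by construction: both groups from one pool; cluster-level
  # significance should fire at ~5 % (99 % binomial band around 0.05)
  set.seed(8)
  hits <- 0
  n_runs <- 400
  for (i in 1:n_runs) {
    X <- matrix(rnorm(16 * 12), 16, 12)
    r <- temporal_cluster_test(X[1:8, ], X[9:16, ], n_perm = 100,
                               seed = i, paired = FALSE)
    ps <- vapply(r$clusters, `[[`, numeric(1), "p_mc")
    if (length(ps) && min(ps) < 0.05) hits <- hits + 1
  }
  band <- qbinom(c(0.005, 0.995), n_runs, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("Spearman correlation clusters respect the channel-count rule", {
  set.seed(10)
  n <- 12; len <- 30
  adj <- chain_adjacency(paste0("ch", 1:4))
  ecg <- matrix(rnorm(n * len), n, len)
  # EEG = ECG copied onto two neighbouring channels -> rho = 1 there
  eeg <- array(rnorm(n * 4 * len, sd = 0.01), c(n, 4, len))
  eeg[, 1, ] <- ecg; eeg[, 2, ] <- ecg
  res <- spearman_cluster_corr(ecg, eeg, adj, n_perm = 200, seed = 1)
  expect_gte(length(res$clusters), 1)
  expect_equal(max(res$rho_map[1:2, ]), 1, tolerance = 1e-9)
  top <- res$clusters[[1]]
  expect_true(all(c(1, 2) %in% top$members[, "channel"]))
  expect_true(top$significant)

  # a single-channel association is discarded by the min-2-channels rule
  eeg2 <- array(rnorm(n * 4 * len, sd = 1), c(n, 4, len))
  eeg2[, 3, ] <- ecg
  res2 <- spearman_cluster_corr(ecg, eeg2, adj, n_perm = 100, seed = 2)
  for (cl in res2$clusters)
    expect_gte(length(unique(cl$members[, "channel"])), 2)

  expect_error(spearman_cluster_corr(matrix(1, n, len), eeg, adj),
               "constant")
})
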