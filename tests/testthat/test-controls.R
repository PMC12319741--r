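make_selection <- function(n_per_cond = 5, fs = 250, seed = 1) {
  set.seed(seed)
  stim <- seq(3000L, by = 1000L, length.out = 2 * n_per_cond)
  cond <- rep(c("high", "low"), each = n_per_cond)
  lat <- runif(2 * n_per_cond, -1100, -600)
  data.frame(
    onset_sample = stim + hepvalid:::ms_to_samples(lat, fs),
    latency_ms = hepvalid:::ms_to_samples(lat, fs) * 1000 / fs,
    parent_stim = seq_along(stim),
    condition = cond, rt_ms = NA_real_, stringsAsFactors = FALSE)
}

test_that("R-peak shuffling permutes latencies within condition only", {
  sel <- make_selection(6)
  sh <- shuffle_rpeaks_within_condition(sel, 250, seed = 7)
  for (cond in c("high", "low")) {
    i <- sel$condition == cond
    # per-condition latency multiset preserved exactly
    expect_setequal(sh$latency_ms[i], sel$latency_ms[i])
    expect_equal(sum(i), sum(sh$condition == cond))
  }
  # onsets recomputed against the trial's own stimulus
  stim_onset <- sel$onset_sample - hepvalid:::ms_to_samples(sel$latency_ms, 250)
  expect_equal(sh$onset_sample,
               stim_onset + hepvalid:::ms_to_samples(sh$latency_ms, 250))
  # deterministic under seed; different seeds differ
  expect_identical(sh, shuffle_rpeaks_within_condition(sel, 250, seed = 7))
  sh2 <- shuffle_rpeaks_within_condition(sel, 250, seed = 8)
  expect_false(identical(sh, sh2))
  # single-trial conditions keep the identity permutation
  one <- make_selection(1)
  expect_message(sh1 <- shuffle_rpeaks_within_condition(one, 250, seed = 1),
                 "identity")
  expect_equal(sh1$onset_sample, one$onset_sample)
})

test_that("surrogate nulls store the statistic vector and its cutoff", {
  null <- surrogate_null(function(seed) 4.2, n_iter = 50, seed = 1)
  expect_equal(null$max_abs_sum_t, rep(4.2, 50))
  expect_equal(null$alpha_cutoff, 4.2)
  # deterministic: the iteration seeds derive from the master seed
  f <- function(seed) abs(hepvalid:::with_seed(seed, rnorm(1)))
  n1 <- surrogate_null(f, 30, seed = 5)
  n2 <- surrogate_null(f, 30, seed = 5)
  expect_identical(n1$max_abs_sum_t, n2$max_abs_sum_t)
  # an iteration with no clusters contributes zero
  expect_message(n0 <- surrogate_null(function(seed) NULL, 3, 1),
                 "contributing 0")
  expect_equal(n0$max_abs_sum_t, rep(0, 3))
})

test_that("comparison against the null follows the stated conventions", {
  null <- structure(list(max_abs_sum_t = as.numeric(1:100), n_iter = 100L,
                         alpha_cutoff = quantile(as.numeric(1:100), 0.95,
                                                 names = FALSE),
                         seed = 1),
                    class = "surrogate_null")
  # observed above every null value: significant, p = 1/100
  r <- compare_to_null(150, null)
  expect_true(r$significant)
  expect_equal(r$p, 0.01)
  # at the median: p ~ 0.5, not significant
  r2 <- compare_to_null(50, null)
  expect_false(r2$significant)
  expect_equal(r2$p, 0.51)
  # below the minimum: p = 1
  expect_equal(compare_to_null(0.5, null)$p, 1)
})

test_that("pseudo-R-peak insertion is one-per-trial, in-window, seeded", {
  stim <- event_table(seq(5000L, by = 1000L, length.out = 12), "stimulus",
                      condition = rep(c("A", "B"), 6))
  ps <- insert_pseudo_rpeaks(stim, c(-1100, -600), 250, seed = 3)
  expect_equal(nrow(ps), 12)
  expect_true(all(ps$latency_ms >= -1100 & ps$latency_ms <= -600))
  expect_equal(ps$condition, stim$condition)
  expect_identical(ps, insert_pseudo_rpeaks(stim, c(-1100, -600), 250,
                                            seed = 3))
  expect_false(identical(ps$onset_sample,
                         insert_pseudo_rpeaks(stim, c(-1100, -600), 250,
                                              seed = 4)$onset_sample))
  expect_error(insert_pseudo_rpeaks(stim, c(-600, 100), 250, 1),
               "pre-stimulus")
})

test_that("pseudotrial correction subtracts the per-condition pseudo average", {
  n <- 40
  mk <- function(rows, cond) hepvalid:::new_epoch_set(
    array(rows, c(length(cond), 1, n)), seq_len(n), 250, "Cz",
    condition = cond)
  real <- mk(rep(c(2, 6), each = 2), c("A", "A", "B", "B"))
  pseudo <- mk(rep(c(2, 6), each = 2), c("A", "A", "B", "B"))
  corr <- pseudotrial_correct(real, pseudo)
  expect_true(all(abs(corr$data) < 1e-12))    # real == pseudo average -> 0

  # rejected pseudo epochs are excluded from the average
  pseudo2 <- mk(c(2, 100, 6, 6), c("A", "A", "B", "B"))
  pseudo2$rejected <- c(FALSE, TRUE, FALSE, FALSE)
  corr2 <- pseudotrial_correct(real, pseudo2)
  expect_true(all(abs(corr2$data) < 1e-12))

  # a condition with zero surviving pseudo epochs raises for exclusion
  pseudo3 <- mk(c(2, 2, 6, 6), c("A", "A", "B", "B"))
  pseudo3$rejected <- c(FALSE, FALSE, TRUE, TRUE)
  expect_error(pseudotrial_correct(real, pseudo3), "exclude this subject")
})

test_that("pseudotrial correction commutes with baseline correction", {
  s <- tiny_session(seed = 31, len = 300, isi = 4)
  rec <- s$recording
  stim <- hepvalid:::events_of(s$events, "stimulus")
  stim$condition <- rep(c("A", "B"), length.out = nrow(stim))
  sel <- select_prestim_rpeaks(event_table(stim$onset_sample, "stimulus",
                                           stim$condition),
                               hepvalid:::events_of(s$events, "simhep"),
                               c(-1500, -600), 250)
  ps <- insert_pseudo_rpeaks(event_table(stim$onset_sample, "stimulus",
                                         stim$condition),
                             c(-1500, -600), 250, seed = 5)
  real <- extract_epochs(rec, sel$onset_sample, -200, 600,
                         condition = sel$condition)
  pseudo <- extract_epochs(rec, ps$onset_sample, -200, 600,
                           condition = ps$condition)
  a <- baseline_correct(pseudotrial_correct(real, pseudo))
  b <- pseudotrial_correct(baseline_correct(real), baseline_correct(pseudo))
  expect_equal(a$data, b$data, tolerance = 1e-9)
})

test_that("the adapted surrogate for corrected data is reproducible", {
  s <- tiny_session(seed = 32, len = 300)
  stim <- hepvalid:::events_of(s$events, "stimulus")
  stim_c <- event_table(stim$onset_sample, "stimulus",
                        condition = rep(c("A", "B"),
                                        length.out = nrow(stim)))
  analysis <- function(p1, p2, iter_seed) {
    e1 <- extract_epochs(s$recording, p1$onset_sample, -200, 600,
                         condition = p1$condition)
    e2 <- extract_epochs(s$recording, p2$onset_sample, -200, 600,
                         condition = p2$condition)
    corr <- pseudotrial_correct(e1, e2)
    tm <- indep_t_map(corr$data[corr$condition == "A", , , drop = FALSE],
                      corr$data[corr$condition == "B", , , drop = FALSE])
    hepvalid:::max_cluster_stat(tm$t, tm$p, NULL, 0.05)
  }
  n1 <- surrogate_for_corrected(stim_c, c(-1500, -600), 250, analysis,
                                n_iter = 10, seed = 9)
  n2 <- surrogate_for_corrected(stim_c, c(-1500, -600), 250, analysis,
                                n_iter = 10, seed = 9)
  expect_identical(n1$max_abs_sum_t, n2$max_abs_sum_t)
  expect_equal(n1$n_iter, 10)
  expect_true(all(is.finite(n1$max_abs_sum_t)))
})
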