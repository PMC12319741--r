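test_that("pre-stimulus R-peak selection applies the closed latency window", {
  fs <- 250
  stim <- event_table(10000L, "stimulus", condition = "A", rt_ms = 450)
  at_ms <- function(ms) event_table(10000L + hepvalid:::ms_to_samples(ms, fs),
                                    "rpeak")
  sel <- select_prestim_rpeaks(stim, at_ms(-800), c(-1100, -600), fs)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$latency_ms, -800)
  expect_equal(sel$condition, "A")
  expect_equal(sel$rt_ms, 450)
  # endpoints are included, outside is excluded
  expect_equal(nrow(select_prestim_rpeaks(stim, at_ms(-1100),
                                          c(-1100, -600), fs)), 1)
  expect_equal(nrow(select_prestim_rpeaks(stim, at_ms(-600),
                                          c(-1100, -600), fs)), 1)
  expect_equal(nrow(select_prestim_rpeaks(stim, at_ms(-500),
                                          c(-1100, -600), fs)), 0)
  expect_equal(nrow(select_prestim_rpeaks(stim, at_ms(-1200),
                                          c(-1100, -600), fs)), 0)
  # no R-peaks -> empty result
  expect_equal(nrow(select_prestim_rpeaks(stim, event_table(integer(0)),
                                          c(-1100, -600), fs)), 0)
})

test_that("selection is order-invariant and assigns overlaps to the earlier stimulus", {
  fs <- 250
  stim <- event_table(c(5000L, 5100L), "stimulus",
                      condition = c("A", "B"))
  # one R-peak inside both windows (stimuli 400 ms apart, wide window)
  rp <- event_table(4800L, "rpeak")
  sel <- select_prestim_rpeaks(stim, rp, c(-1100, -100), fs)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$parent_stim, 1)            # earlier stimulus wins
  # permuting the input order changes nothing
  stim_rev <- event_table(c(5100L, 5000L), "stimulus",
                          condition = c("B", "A"))
  expect_equal(select_prestim_rpeaks(stim_rev, rp, c(-1100, -100), fs), sel)
  # many R-peaks, shuffled input order
  set.seed(2)
  rps <- event_table(sample(seq(3000L, 4900L, by = 100L)), "rpeak")
  s1 <- select_prestim_rpeaks(stim, rps, c(-1100, -600), fs)
  s2 <- select_prestim_rpeaks(stim, event_table(sort(rps$onset_sample),
                                                "rpeak"),
                              c(-1100, -600), fs)
  expect_equal(s1, s2)
})

test_that("minimum-trial rule matches the stated inclusion boundary", {
  expect_false(enforce_min_trials(19))
  expect_true(enforce_min_trials(20))
  expect_true(enforce_min_trials(0, minimum = 0))
})

test_that("median split balances groups and resolves ties deterministically", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  # ties at the median alternate so groups stay balanced
  s <- median_split(c(1, 2, 2, 3))
  expect_equal(sum(s == "low"), 2)
  expect_equal(sum(s == "high"), 2)
  expect_equal(s[1], "low")
  # property: group sizes differ by at most one, across sizes and ties
  set.seed(13)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    v <- sample(1:6, n, replace = TRUE)       # heavy ties
    if (diff(range(v)) == 0) next
    sp <- median_split(v)
    expect_lte(abs(sum(sp == "low") - sum(sp == "high")), 1)
  }
  sp <- median_split(rnorm(10000))
  expect_lte(abs(sum(sp == "low") - sum(sp == "high")), 1)
  expect_error(median_split(c(2, 2, 2)), "all values equal")
  expect_error(median_split(3), "2 finite")
})

test_that("LDA spatial filter finds the discriminative direction", {
  set.seed(21)
  n <- 60
  # class difference only in channel 1, isotropic noise
  Xa <- cbind(rnorm(n, 2), rnorm(n, 0), rnorm(n, 0))
  Xb <- cbind(rnorm(n, 0), rnorm(n, 0), rnorm(n, 0))
  f <- lda_spatial_filter(Xa, Xb)
  expect_gt(abs(f$weights[1]), abs(f$weights[2]))
  expect_gt(abs(f$weights[1]), abs(f$weights[3]))
  expect_equal(sqrt(sum(f$weights^2)), 1, tolerance = 1e-9)

  # the projection separates classes at least as well (in pooled-sd units)
  # as the best single channel, on the training features
  proj_a <- Xa %*% f$weights; proj_b <- Xb %*% f$weights
  sep <- function(a, b) abs(mean(a) - mean(b)) /
    sqrt((var(a) * (length(a) - 1) + var(b) * (length(b) - 1)) /
           (length(a) + length(b) - 2))
  best_single <- max(sapply(1:3, function(j) sep(Xa[, j], Xb[, j])))
  expect_gte(sep(proj_a, proj_b), best_single * 0.999)

  # projecting an epoch set yields one time course per trial
  ep <- hepvalid:::new_epoch_set(array(rnorm(5 * 3 * 20), c(5, 3, 20)),
                                 seq_len(20), 250, c("c1", "c2", "c3"))
  pr <- f$project(ep)
  expect_equal(dim(pr), c(5, 20))

  expect_error(lda_spatial_filter(Xa[1, , drop = FALSE], Xb), ">= 2")
  Z <- matrix(rnorm(40), 20, 2)
  expect_error(lda_spatial_filter(Z, Z), "qual class means")
})

test_that("event transplantation copies onsets verbatim and drops overflow", {
  ev <- event_table(c(100L, 500L, 900L), "stimulus",
                    condition = c("A", "B", "A"), rt_ms = c(400, 500, 450))
  rest <- continuous_recording(matrix(0, 1, 1000), 250, "Cz")
  out <- transplant_events(ev, rest)
  expect_equal(as.data.frame(out), as.data.frame(ev))
  short <- continuous_recording(matrix(0, 1, 600), 250, "Cz")
  expect_message(out2 <- transplant_events(ev, short), "dropped 1")
  expect_equal(nrow(out2), 2)
  expect_lte(nrow(out2), nrow(ev))
})
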