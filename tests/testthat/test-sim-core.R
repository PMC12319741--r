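test_that("phase randomization preserves the amplitude spectrum and variance", {
  # constant trace: only the DC bin carries energy, so nothing can change
  x <- rep(3.2, 100)
  expect_equal(phase_randomize(x, seed = 1), x, tolerance = 1e-12)

  set.seed(42)
  for (case in 1:5) {
    n <- sample(c(255, 256, 1000), 1)          # odd and even lengths
    x <- rnorm(n) + sin(2 * pi * 7 * seq_len(n) / 250)
    y <- phase_randomize(x, seed = case)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-9)
    expect_true(max(abs(Im(fft(y)[1]))) < 1e-8) # output real-valued
  }

  # Parseval: a 10 Hz sinusoid keeps its variance exactly
  s <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 250))
  y <- phase_randomize(s, seed = 9)
  expect_equal(var(y), var(s), tolerance = 1e-9)

  expect_error(phase_randomize(c(1, NA, 3)), "non-finite")
  expect_error(phase_randomize(1), "length")
})

test_that("background generator is deterministic with the stated spectrum", {
  expect_identical(generate_background(5000, 250, 1, seed = 3),
                   generate_background(5000, 250, 1, seed = 3))

  # exponent 0 is white noise: lag-1 autocorrelation vanishes
  w <- generate_background(1e5, 250, 0, seed = 4)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.02)
  expect_equal(mean(w), 0, tolerance = 1e-8)

  # exponent 1: log-log PSD slope over 1-40 Hz close to -1
  x <- generate_background(2^17, 250, 1, seed = 5)
  ps <- Mod(fft(x))^2
  f <- (seq_along(ps) - 1) * 250 / length(ps)
  sel <- f >= 1 & f <= 40
  # bin the periodogram in log-f to stabilise the regression
  bins <- cut(log(f[sel]), 30)
  lp <- tapply(log(ps[sel]), bins, mean)
  lf <- tapply(log(f[sel]), bins, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
})

test_that("amplitude draws match the configured normal distribution", {
  a <- draw_amplitudes(50000, 7, 2, seed = 1)
  expect_lt(abs(mean(a) - 7), 0.05)
  b <- draw_amplitudes(50000, 1.5, 0.8, seed = 2)
  expect_lt(abs(sd(b) - 0.8), 0.02)
  expect_error(draw_amplitudes(10, 1, 0), "sd")
})

test_that("amplitude coupling has the normalise-mix-rescale structure", {
  erp <- draw_amplitudes(1e5, 7, 2, seed = 10)
  hep <- draw_amplitudes(1e5, 1.5, 0.8, seed = 11)
  # k = 0 is an exact identity under population-parameter rescaling
  expect_equal(couple_amplitudes(0, erp, hep), hep, tolerance = 1e-12)
  # k = 1 degenerates to the standardised ERP amplitude
  expect_equal(cor(couple_amplitudes(1, erp, hep), erp), 1, tolerance = 1e-12)
  # intermediate k: correlation converges to k; unit variance before rescale
  for (k in c(-1, -0.5, 0.5)) {
    out <- couple_amplitudes(k, erp, hep)
    expect_lt(abs(cor(out, erp) - k), 0.01)
    expect_lt(abs(sd(out) - 0.8), 0.01)
    expect_lt(abs(mean(out) - 1.5), 0.01)
  }
  expect_error(couple_amplitudes(1.2, erp, hep), "k")
  expect_error(couple_amplitudes(0.5, 1:3, 1:2), "length")
})

test_that("gaussian pulse has the stated length, peak and support", {
  p <- gaussian_pulse(400, 2.5, 250)
  expect_length(p, 100)                      # duration x rate, half-open
  expect_equal(max(p), 2.5, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(gaussian_pulse(400, 0, 250), rep(0, 100))
  # sigma = duration/6: endpoints carry < 1.2% of the peak
  expect_lt(p[1] / max(p), 0.012)
})

test_that("SNR measurement and calibration round-trip", {
  bg <- generate_background(20000, 250, 1, seed = 6)
  expect_equal(measure_snr_db(bg, bg), 0)
  expect_equal(measure_snr_db(sqrt(2) * bg, bg), 10 * log10(2),
               tolerance = 1e-9)
  pulses <- lapply(draw_amplitudes(50, 7, 2, seed = 7),
                   function(a) a * gaussian_pulse(600, 1, 250))
  sc <- scale_to_snr(pulses, bg, 3.3)
  expect_equal(measure_snr_db(sc$pulses, bg), 3.3, tolerance = 0.01)
  sc2 <- scale_to_snr(pulses, bg, -9.3)
  expect_equal(measure_snr_db(sc2$pulses, bg), -9.3, tolerance = 0.01)
  # amplitude scales as 10^(dB/20): +6.0206 dB doubles the factor
  sc3 <- scale_to_snr(pulses, bg, 3.3 + 20 * log10(2))
  expect_equal(sc3$factor, 2 * sc$factor, tolerance = 1e-9)
  expect_error(scale_to_snr(list(rep(0, 10)), bg, 0), "zero power")
  expect_error(measure_snr_db(pulses, rep(0, 10)), "background power")
})

test_that("assembled sessions respect the trigger grid and truth record", {
  s <- assemble_session(sim_config(session_length = 120, seed = 21))
  tt <- s$truth$trials
  # margin 2 s, ISI 4 s, ERP must end before 120 s -> 30 trials
  expect_equal(nrow(tt), 30)
  expect_equal(diff(tt$stim_onset), rep(4 * 250, 29))

  # truth record and event table agree exactly
  ev <- s$events
  expect_setequal(ev$onset_sample[ev$event_type == "stimulus"], tt$stim_onset)
  expect_setequal(ev$onset_sample[ev$event_type == "simhep"],
                  tt$hep_onset[tt$has_hep])
  expect_setequal(ev$onset_sample[ev$event_type == "pseudo"],
                  tt$pseudo_onset[!tt$has_hep])

  # every HEP trigger and every pseudo candidate inside the placement window
  expect_true(all(tt$hep_lat_ms[tt$has_hep] >= -1500 &
                    tt$hep_lat_ms[tt$has_hep] <= -600))
  lat_pseudo <- (tt$pseudo_onset - tt$stim_onset)[!tt$has_hep] * 1000 / 250
  expect_true(all(lat_pseudo >= -1501 & lat_pseudo <= -599))

  # determinism
  s2 <- assemble_session(sim_config(session_length = 120, seed = 21))
  expect_identical(s$recording$data, s2$recording$data)
  expect_identical(s$events, s2$events)

  # hep_trial_fraction is honoured
  s3 <- assemble_session(sim_config(session_length = 120, seed = 21,
                                    hep_trial_fraction = 0.25))
  expect_equal(sum(s3$truth$trials$has_hep), round(0.25 * 30))

  # injected SNR calibration holds on the assembled pulse sets
  shape <- gaussian_pulse(600, 1, 250)
  pulses <- lapply(tt$erp_amp_cal, function(a) a * shape)
  bgr <- generate_background(120 * 250, 250, 1,
                             seed = ss(21, "background"),
                             hp_cutoff = 0.3, lp_cutoff = 45)
  expect_equal(measure_snr_db(pulses, bgr), 3.3, tolerance = 0.01)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(k = 1.5), "k")
  expect_error(sim_config(hep_sd = 0), "hep_sd")
  expect_error(sim_config(hep_placement_window = c(-600, 100)),
               "before the stimulus")
  expect_error(sim_config(hep_placement_window = c(-600, -1500)), "ordered")
  expect_error(sim_config(hep_trial_fraction = 0), "fraction")
})

test_that("validation sessions carry realistic heartbeats and labelled trials", {
  sess <- make_validation_session(n_subjects = 2, seed = 3, n_trials = 40,
                                  heart_rate = 60, rr_sd = 0.03)
  expect_length(sess, 2)
  s <- sess[[1]]
  rp <- s$events$onset_sample[s$events$event_type == "rpeak"]
  rr <- diff(rp) / 250
  expect_lt(abs(mean(rr) - 1.0), 0.05)       # 60 bpm -> 1 s RR
  stim <- s$events[s$events$event_type == "stimulus", ]
  expect_equal(nrow(stim), 40)
  expect_setequal(unique(stim$condition), c("A", "B"))
  expect_equal(sum(stim$condition == "A"), 20)
  expect_true(all(is.finite(stim$rt_ms)))
  expect_equal(s$recording$channel_roles,
               c(rep("eeg", 4), "ecg"))
})

test_that("the CNV-like confound grows toward stimulus onset at the stated rate", {
  sess <- make_validation_session(n_subjects = 6, confound_uv = 8, seed = 5,
                                  n_trials = 60, noise_sd = 0.5)
  # average condition difference of the injected ramp at two pre-stimulus
  # latencies: closed form is confound_uv * (1 - |t|/1200) for t > -1200 ms
  diffs <- sapply(sess, function(s) {
    stim <- s$events[s$events$event_type == "stimulus", ]
    ep <- extract_epochs(s$recording, event_table(stim$onset_sample,
                                                  "stimulus",
                                                  stim$condition),
                         -1200, 0)
    evA <- epoch_average(ep, "A")[1, ]; evB <- epoch_average(ep, "B")[1, ]
    d <- evB - evA                            # A is more negative
    idx <- function(ms) which.min(abs(ep$time_ms - ms))
    c(d[idx(-900)], d[idx(-300)])
  })
  d900 <- mean(diffs[1, ]); d300 <- mean(diffs[2, ])
  expect_equal(d900, 8 * (1 - 900 / 1200), tolerance = 0.6)
  expect_equal(d300, 8 * (1 - 300 / 1200), tolerance = 0.6)
  expect_gt(d300, d900)                       # grows toward onset
})
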