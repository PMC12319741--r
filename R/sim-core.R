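#' Phase-randomise a time series
#'
#' Spectrum-preserving surrogate: the Fourier amplitude spectrum of the input
#' is kept bin-by-bin while the phases of all non-DC, non-Nyquist bins are
#' replaced by independent uniform draws (with conjugate symmetry enforced so
#' the output is real). Evoked, time-locked structure is destroyed while the
#' power at every frequency — and hence the total variance — is preserved.
#'
#' @param trace numeric vector, length >= 2, finite.
#' @param seed integer seed.
#' @return numeric vector of the same length as `trace`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 1/250))
#' y <- phase_randomize(x, seed = 1)
#' all.equal(var(x), var(y))
#' @export
phase_randomize <- function(trace, seed = 1) {
  if (!is.numeric(trace) || length(trace) < 2L)
    stop_hv("'trace' must be a numeric vector of length >= 2")
  if (!all(is.finite(trace)))
    stop_hv("'trace' contains non-finite values")
  n <- length(trace)
  sp <- stats::fft(trace)
  half <- (n - 1L) %/% 2L                       # bins 2..half+1 are free
  phases <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  out_sp <- sp
  if (half > 0) {
    idx <- 2L:(half + 1L)
    out_sp[idx] <- Mod(sp[idx]) * exp(1i * phases)
    out_sp[n + 2L - idx] <- Conj(out_sp[idx])   # conjugate symmetry
  }
  # DC bin (and Nyquist bin for even n) stay untouched: they are real and
  # carry no phase freedom for a real-valued output.
  Re(stats::fft(out_sp, inverse = TRUE)) / n
}

#' Generate 1/f^a background noise
#'
#' Zero-mean Gaussian noise whose expected power spectral density follows
#' `1/f^spectral_exponent`, built by shaping the spectrum of white noise.
#' Optionally the spectrum is flattened below `hp_cutoff` (mimicking a
#' high-pass-filtered recording, and avoiding the divergence of 1/f at DC)
#' and rolled off above `lp_cutoff` with a 4th-order Butterworth magnitude
#' response. The output is rescaled to unit variance; callers set the scale
#' via SNR calibration.
#'
#' @param n_samples number of samples (>= 2).
#' @param sampling_rate Hz.
#' @param spectral_exponent exponent a >= 0 (0 gives white noise; default 1).
#' @param seed integer seed (fixed seed gives identical traces).
#' @param hp_cutoff Hz; spectrum is flat below this (0 disables).
#' @param lp_cutoff Hz; Butterworth-magnitude roll-off above this
#'   (NULL disables).
#' @return numeric vector of length `n_samples` with mean 0 and variance 1.
#' @export
generate_background <- function(n_samples, sampling_rate,
                                spectral_exponent = 1, seed = 1,
                                hp_cutoff = 0, lp_cutoff = NULL) {
  check_scalar(n_samples, "n_samples", lower = 2)
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  check_scalar(spectral_exponent, "spectral_exponent", lower = 0)
  n <- as.integer(n_samples)
  white <- with_seed(seed, stats::rnorm(n))
  if (spectral_exponent == 0 && hp_cutoff == 0 && is.null(lp_cutoff))
    return(as.numeric(scale(white)))
  sp <- stats::fft(white)
  freq <- c(0, seq_len(n - 1)) * sampling_rate / n
  freq <- pmin(freq, sampling_rate - freq)      # two-sided frequency axis
  f_eff <- pmax(freq, max(hp_cutoff, sampling_rate / n))
  gain <- f_eff^(-spectral_exponent / 2)
  if (!is.null(lp_cutoff))
    gain <- gain / sqrt(sqrt(1 + (freq / lp_cutoff)^8))  # |H| of order-4 Butterworth
  gain[1] <- 0                                  # zero-mean: drop DC
  x <- Re(stats::fft(sp * gain, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Draw evoked-response amplitudes
#'
#' @param n number of draws (>= 1).
#' @param mean,sd normal distribution parameters (sd > 0).
#' @param seed integer seed.
#' @return numeric vector of i.i.d. normal draws, in uV.
#' @export
draw_amplitudes <- function(n, mean, sd, seed = 1) {
  check_scalar(n, "n", lower = 1)
  check_scalar(sd, "sd", lower = .Machine$double.eps)
  with_seed(seed, stats::rnorm(as.integer(n), mean, sd))
}

#' Couple HEP amplitudes to ERP amplitudes
#'
#' Standardise both amplitude vectors with the population parameters, mix
#' with weights `(k, sqrt(1 - k^2))`, and rescale by the HEP population SD
#' and mean. For independent unit-variance inputs the output has unit
#' variance before rescaling and correlation `k` with the ERP amplitudes;
#' `k = 0` returns `hep_amps` unchanged.
#'
#' @param k coupling factor in \[-1, 1\].
#' @param erp_amps,hep_amps equal-length amplitude vectors, uV.
#' @param erp_mean,erp_sd,hep_mean,hep_sd population parameters used for the
#'   standardise/rescale steps.
#' @return numeric vector of coupled HEP amplitudes, uV.
#' @export
couple_amplitudes <- function(k, erp_amps, hep_amps,
                              hep_mean = 1.5, hep_sd = 0.8,
                              erp_mean = 7, erp_sd = 2) {
  check_scalar(k, "k", lower = -1, upper = 1)
  if (length(erp_amps) != length(hep_amps))
    stop_hv("'erp_amps' and 'hep_amps' must have equal length")
  z_erp <- (erp_amps - erp_mean) / erp_sd
  z_hep <- (hep_amps - hep_mean) / hep_sd
  mixed <- k * z_erp + sqrt(1 - k^2) * z_hep
  mixed * hep_sd + hep_mean
}

#' Gaussian deflection waveform
#'
#' Bell-shaped, non-negative pulse of the stated duration. The pulse spans
#' `duration_ms` (half-open sample count `round(duration * rate)`), with
#' `sigma = duration / 6` so that more than 99.7% of the mass lies inside the
#' window, and peaks exactly at the requested amplitude on the centre sample
#' (`floor(n/2)`, 0-based).
#'
#' @param duration_ms pulse duration in ms (> 0).
#' @param amplitude peak amplitude in uV (finite).
#' @param sampling_rate Hz.
#' @return numeric waveform vector.
#' @export
gaussian_pulse <- function(duration_ms, amplitude, sampling_rate) {
  check_scalar(duration_ms, "duration_ms", lower = .Machine$double.eps)
  check_scalar(amplitude, "amplitude")
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  n <- max(1L, as.integer(round(duration_ms / 1000 * sampling_rate)))
  centre <- floor(n / 2)
  sigma <- duration_ms / 1000 * sampling_rate / 6
  i <- seq_len(n) - 1L
  amplitude * exp(-((i - centre)^2) / (2 * sigma^2))
}

pulse_power <- function(pulse_set) {
  if (is.numeric(pulse_set)) pulse_set <- list(pulse_set)
  mean(vapply(pulse_set, function(w) mean(w^2), numeric(1)))
}

#' Signal-to-noise ratio of a pulse set in dB
#'
#' `10 * log10(mean pulse power / background power)` where pulse power is the
#' mean squared amplitude over each pulse's duration, averaged over pulses,
#' and background power is the mean squared background sample.
#'
#' @param pulse_set a waveform vector or list of waveform vectors.
#' @param background numeric background trace (nonzero power).
#' @return SNR in dB.
#' @export
measure_snr_db <- function(pulse_set, background) {
  bp <- mean(background^2)
  if (!is.finite(bp) || bp <= 0) stop_hv("background power must be positive")
  10 * log10(pulse_power(pulse_set) / bp)
}

#' Scale a pulse set to a target SNR
#'
#' Applies a single multiplicative factor to every pulse so that
#' [measure_snr_db()] returns `target_db` against the given background.
#'
#' @inheritParams measure_snr_db
#' @param target_db target SNR in dB.
#' @return list with `pulses` (scaled set, as a list) and `factor`.
#' @export
scale_to_snr <- function(pulse_set, background, target_db) {
  if (is.numeric(pulse_set)) pulse_set <- list(pulse_set)
  pp <- pulse_power(pulse_set)
  if (!is.finite(pp) || pp <= 0) stop_hv("pulse set has zero power")
  current <- measure_snr_db(pulse_set, background)
  factor <- 10^((target_db - current) / 20)
  list(pulses = lapply(pulse_set, function(w) w * factor), factor = factor)
}
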