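#' Simulation configuration
#'
#' Parameters of the synthetic single-channel session generator. Defaults
#' encode the study conditions the power analyses assume: task triggers
#' every 4 s over a
#' ~28 min session (422 trials), simulated ERP amplitudes N(7, 2^2) uV with a
#' Gaussian deflection at 300 ms post-stimulus (600 ms duration), simulated
#' HEP amplitudes N(1.5, 0.8^2) uV (400 ms duration, peak 200 ms after a
#' trigger placed uniformly in [-1500, -600] ms before the stimulus) on half
#' of the trials, and signal-to-noise calibration to +3.3 dB (ERP) and
#' -9.3 dB (HEP) against the background.
#'
#' The coupling factor `k` in \[-1, 1\] mixes the standardised ERP amplitude
#' into the HEP amplitude: `a_hep' = k * z_erp + sqrt(1 - k^2) * z_hep`,
#' rescaled back to the HEP mean/SD, so `cor(a_hep'', a_erp) = k` for
#' independent inputs.
#'
#' The background is 1/f^`spectral_exponent` noise, spectrally shaped to the
#' analysis bandwidth of a typical preprocessed EEG: flat below `hp_cutoff`
#' and with a 4th-order Butterworth-magnitude roll-off above `lp_cutoff`.
#'
#' @param sampling_rate Hz.
#' @param session_length seconds.
#' @param isi inter-stimulus interval, seconds.
#' @param erp_mean,erp_sd simulated ERP amplitude distribution, uV.
#' @param hep_mean,hep_sd simulated HEP amplitude distribution, uV.
#' @param k coupling factor in \[-1, 1\].
#' @param erp_onset ERP deflection onset, ms post-stimulus.
#' @param erp_duration ERP deflection duration, ms.
#' @param hep_duration HEP deflection duration, ms.
#' @param hep_latency HEP deflection peak latency after its trigger, ms.
#' @param hep_placement_window length-2 ms window (relative to the stimulus,
#'   strictly pre-stimulus) in which HEP triggers are placed uniformly.
#' @param hep_trial_fraction fraction of trials receiving a simulated HEP,
#'   in (0, 1].
#' @param erp_snr_db,hep_snr_db calibration targets in dB (mean pulse power
#'   over background power).
#' @param spectral_exponent background 1/f exponent (>= 0).
#' @param hp_cutoff Hz below which the background spectrum is flat.
#' @param lp_cutoff Hz of the background low-pass shaping (NULL for none).
#' @param edge_margin seconds kept free of triggers at both recording edges.
#' @param seed master seed for the session.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(session_length = 120, seed = 7)
#' cfg
#' @export
sim_config <- function(sampling_rate = 250, session_length = 1688, isi = 4,
                       erp_mean = 7, erp_sd = 2, hep_mean = 1.5, hep_sd = 0.8,
                       k = 0, erp_onset = 300, erp_duration = 600,
                       hep_duration = 400, hep_latency = 200,
                       hep_placement_window = c(-1500, -600),
                       hep_trial_fraction = 0.5,
                       erp_snr_db = 3.3, hep_snr_db = -9.3,
                       spectral_exponent = 1, hp_cutoff = 0.3, lp_cutoff = 45,
                       edge_margin = 2, seed = 1) {
  check_scalar(sampling_rate, "sampling_rate", lower = 1)
  check_scalar(session_length, "session_length", lower = 1)
  check_scalar(isi, "isi", lower = 1e-3)
  check_scalar(erp_sd, "erp_sd", lower = 1e-12)
  check_scalar(hep_sd, "hep_sd", lower = 1e-12)
  check_scalar(k, "k", lower = -1, upper = 1)
  check_scalar(hep_trial_fraction, "hep_trial_fraction")
  if (hep_trial_fraction <= 0 || hep_trial_fraction > 1)
    stop_hv("'hep_trial_fraction' must be in (0, 1]")
  if (length(hep_placement_window) != 2L ||
      hep_placement_window[1] >= hep_placement_window[2])
    stop_hv("'hep_placement_window' must be an ordered ms pair")
  if (hep_placement_window[2] > 0)
    stop_hv("'hep_placement_window' must lie strictly before the stimulus")
  check_scalar(spectral_exponent, "spectral_exponent", lower = 0)
  cfg <- list(sampling_rate = sampling_rate, session_length = session_length,
              isi = isi, erp_mean = erp_mean, erp_sd = erp_sd,
              hep_mean = hep_mean, hep_sd = hep_sd, k = k,
              erp_onset = erp_onset, erp_duration = erp_duration,
              hep_duration = hep_duration, hep_latency = hep_latency,
              hep_placement_window = as.numeric(hep_placement_window),
              hep_trial_fraction = hep_trial_fraction,
              erp_snr_db = erp_snr_db, hep_snr_db = hep_snr_db,
              spectral_exponent = spectral_exponent,
              hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
              edge_margin = edge_margin, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %g Hz, %g s session, ISI %g s, seed %s\n",
              x$sampling_rate, x$session_length, x$isi, format(x$seed)))
  cat(sprintf("  ERP: N(%g, %g^2) uV @ %g ms (dur %g ms), SNR %g dB\n",
              x$erp_mean, x$erp_sd, x$erp_onset, x$erp_duration, x$erp_snr_db))
  cat(sprintf("  HEP: N(%g, %g^2) uV, dur %g ms, window [%g, %g] ms, SNR %g dB\n",
              x$hep_mean, x$hep_sd, x$hep_duration,
              x$hep_placement_window[1], x$hep_placement_window[2],
              x$hep_snr_db))
  cat(sprintf("  coupling k = %g, HEP trial fraction %g\n",
              x$k, x$hep_trial_fraction))
  invisible(x)
}
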