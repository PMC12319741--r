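#' Assemble a synthetic single-channel session
#'
#' Builds one continuous synthetic EEG trace with stimulus triggers every
#' `isi` seconds, a Gaussian ERP deflection on every trial (amplitude drawn
#' from the configured normal distribution), and — on a configured fraction of
#' trials — a pre-stimulus HEP-like deflection whose amplitude is coupled to
#' that trial's ERP amplitude with factor `k`, triggered at a uniform random
#' time inside the placement window. Trials without a HEP carry one candidate
#' pseudo-trigger drawn from the same window. Both pulse sets are calibrated
#' to the configured SNR targets before injection. Trigger placement starts
#' after `edge_margin` seconds; trials whose ERP window would extend past the
#' recording end are not generated.
#'
#' @param config a [sim_config()].
#' @param background optional numeric background trace; when `NULL` it is
#'   generated from the config (1/f noise with the configured band shaping).
#'   Supply [phase_randomize()]d real data here to mirror a
#'   surrogate-background design.
#' @return An object of class `synthetic_session`: a list with `recording`
#'   (a [continuous_recording()]), `events` (an [event_table()] holding
#'   stimulus, simhep and pseudo events) and `truth` (per-trial record of
#'   injected onsets and amplitudes plus the scaling factors and config).
#' @examples
#' s <- assemble_session(sim_config(session_length = 60, seed = 2))
#' s$events
#' @export
assemble_session <- function(config, background = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  if (is.null(background)) {
    n <- as.integer(round(config$session_length * fs))
    background <- generate_background(
      n, fs, config$spectral_exponent,
      seed = substream_seed(config$seed, "background"),
      hp_cutoff = config$hp_cutoff, lp_cutoff = config$lp_cutoff)
  }
  if (!all(is.finite(background)))
    stop_hv("background contains non-finite values")
  n <- length(background)
  len_s <- n / fs

  # stimulus grid: margin at the start; drop trials whose ERP would overrun
  erp_end_s <- (config$erp_onset + config$erp_duration) / 1000
  last_ok <- len_s - erp_end_s
  if (config$edge_margin > last_ok)
    stop_hv("background too short for any trial")
  onsets_s <- seq(config$edge_margin, last_ok, by = config$isi)
  if (length(onsets_s) < 2L) stop_hv("background too short for >= 2 trials")
  stim <- as.integer(round(onsets_s * fs))
  n_trials <- length(stim)

  # which trials carry a simulated HEP
  n_hep <- round(config$hep_trial_fraction * n_trials)
  hep_trials <- sort(with_seed(substream_seed(config$seed, "hep_select"),
                               sample(n_trials, n_hep)))
  is_hep <- seq_len(n_trials) %in% hep_trials

  # amplitudes (uV), coupling on the HEP-bearing subset
  erp_amps <- draw_amplitudes(n_trials, config$erp_mean, config$erp_sd,
                              seed = substream_seed(config$seed, "erp_amps"))
  hep_raw <- draw_amplitudes(max(n_hep, 1L), config$hep_mean, config$hep_sd,
                             seed = substream_seed(config$seed, "hep_amps"))
  hep_raw <- hep_raw[seq_len(n_hep)]
  hep_coupled <- couple_amplitudes(config$k, erp_amps[hep_trials], hep_raw,
                                   hep_mean = config$hep_mean,
                                   hep_sd = config$hep_sd,
                                   erp_mean = config$erp_mean,
                                   erp_sd = config$erp_sd)

  # unit-peak shapes; SNR calibration scales each pulse set as a whole
  erp_shape <- gaussian_pulse(config$erp_duration, 1, fs)
  hep_shape <- gaussian_pulse(config$hep_duration, 1, fs)
  erp_cal <- scale_to_snr(lapply(erp_amps, function(a) a * erp_shape),
                          background, config$erp_snr_db)
  erp_amps_cal <- erp_amps * erp_cal$factor
  if (n_hep > 0) {
    hep_cal <- scale_to_snr(lapply(hep_coupled, function(a) a * hep_shape),
                            background, config$hep_snr_db)
    hep_amps_cal <- hep_coupled * hep_cal$factor
    hep_factor <- hep_cal$factor
  } else {
    hep_amps_cal <- numeric(0)
    hep_factor <- NA_real_
  }

  # trigger placements (continuous uniform in ms, rounded to samples)
  w <- config$hep_placement_window
  hep_lat_ms <- with_seed(substream_seed(config$seed, "hep_placement"),
                          stats::runif(n_hep, w[1], w[2]))
  pseudo_lat_ms <- with_seed(substream_seed(config$seed, "pseudo_placement"),
                             stats::runif(n_trials - n_hep, w[1], w[2]))
  hep_onset <- stim[hep_trials] + ms_to_samples(hep_lat_ms, fs)
  pseudo_onset <- stim[!is_hep] + ms_to_samples(pseudo_lat_ms, fs)

  # inject pulses (in place: start indices are 0-based)
  trace <- background + 0
  erp_start <- stim + ms_to_samples(config$erp_onset, fs)
  erp_offs <- seq_along(erp_shape)
  for (i in seq_len(n_trials)) {
    idx <- erp_start[i] + erp_offs
    trace[idx] <- trace[idx] + erp_amps_cal[i] * erp_shape
  }
  # HEP pulse peaks hep_latency ms after its trigger; with the centre-sample
  # convention the pulse starts at trigger + latency - floor(n/2) samples
  hep_centre <- floor(length(hep_shape) / 2)
  hep_start <- hep_onset + ms_to_samples(config$hep_latency, fs) - hep_centre
  hep_offs <- seq_along(hep_shape)
  for (j in seq_len(n_hep)) {
    idx <- hep_start[j] + hep_offs
    trace[idx] <- trace[idx] + hep_amps_cal[j] * hep_shape
  }

  events <- event_table(
    onset_sample = c(stim, hep_onset, pseudo_onset),
    event_type = c(rep("stimulus", n_trials), rep("simhep", n_hep),
                   rep("pseudo", n_trials - n_hep)))

  trial_tab <- data.frame(
    trial = seq_len(n_trials),
    stim_onset = stim,
    erp_amp_uv = erp_amps,
    erp_amp_cal = erp_amps_cal,
    has_hep = is_hep,
    hep_onset = NA_integer_, hep_lat_ms = NA_real_,
    hep_amp_uv = NA_real_, hep_amp_cal = NA_real_,
    pseudo_onset = NA_integer_)
  trial_tab$hep_onset[hep_trials] <- hep_onset
  trial_tab$hep_lat_ms[hep_trials] <- hep_lat_ms
  trial_tab$hep_amp_uv[hep_trials] <- hep_coupled
  trial_tab$hep_amp_cal[hep_trials] <- hep_amps_cal
  trial_tab$pseudo_onset[!is_hep] <- pseudo_onset

  structure(list(
    recording = continuous_recording(trace, fs, "SIM", "eeg"),
    events = events,
    truth = list(trials = trial_tab,
                 erp_scale_factor = erp_cal$factor,
                 hep_scale_factor = hep_factor,
                 hep_amps_raw = hep_raw,
                 config = config)),
    class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  tt <- x$truth$trials
  cat(sprintf("<synthetic_session> %d trials (%d with simulated HEP), k = %g\n",
              nrow(tt), sum(tt$has_hep), x$truth$config$k))
  print(x$recording)
  invisible(x)
}

#' Generate multichannel validation sessions
#'
#' Fixture generator for end-to-end tests of the control procedures: each
#' "subject" is a multichannel session with 1/f EEG background, stimulus
#' triggers at a fixed ISI carrying balanced condition labels (`"A"`/`"B"`)
#' and reaction times, an R-peak train at a realistic heart rate with a
#' two-component synthetic ECG channel (R spike + T wave), and a genuine
#' Gaussian HEP deflection after every R-peak on a subset of EEG channels.
#' Two optional manipulations drive the tests:
#' \describe{
#'   \item{`effect_uv`}{a genuine heartbeat-locked condition effect: R-peaks
#'     inside the trial's pre-stimulus window of interest evoke a HEP that is
#'     `effect_uv` larger in condition A.}
#'   \item{`confound_uv`}{a CNV-like heartbeat-independent confound: a linear
#'     pre-stimulus ramp from `ramp_onset_ms` to the stimulus, whose endpoint
#'     amplitude is `confound_uv` more negative in condition A.}
#' }
#'
#' @param n_subjects number of sessions.
#' @param effect_uv genuine condition difference in HEP peak amplitude, uV.
#' @param confound_uv condition difference in ramp endpoint amplitude, uV.
#' @param seed master seed.
#' @param n_trials stimulus count per session.
#' @param isi inter-stimulus interval, seconds.
#' @param sampling_rate Hz.
#' @param n_eeg number of EEG channels (a chain montage; see
#'   [chain_adjacency()]).
#' @param effect_channels indices of EEG channels carrying HEPs, ramp and
#'   effect (default: first half).
#' @param heart_rate mean heart rate, bpm.
#' @param rr_sd SD of the RR intervals, seconds.
#' @param noise_sd background SD per channel, uV.
#' @param hep_base_uv baseline HEP peak amplitude, uV.
#' @param hep_latency,hep_duration HEP pulse timing, ms.
#' @param prestim_window ms window (relative to stimulus) defining which
#'   R-peaks carry the condition effect — the analysis window of interest.
#' @param ramp_onset_ms start of the CNV-like ramp, ms before the stimulus.
#' @param cnv_base_uv ramp endpoint amplitude common to both conditions, uV
#'   (negative-going).
#' @param rt_mean_ms,rt_sd_ms reaction-time distribution.
#' @return list of `synthetic_session` objects, each with an extra
#'   `truth$params` record.
#' @export
make_validation_session <- function(n_subjects = 12, effect_uv = 0,
                                    confound_uv = 0, seed = 1,
                                    n_trials = 60, isi = 1.5,
                                    sampling_rate = 250, n_eeg = 4,
                                    effect_channels = NULL,
                                    heart_rate = 63, rr_sd = 0.05,
                                    noise_sd = 2, hep_base_uv = 1.5,
                                    hep_latency = 200, hep_duration = 400,
                                    prestim_window = c(-1100, -600),
                                    ramp_onset_ms = -1200, cnv_base_uv = 3,
                                    rt_mean_ms = 490, rt_sd_ms = 80) {
  check_scalar(n_subjects, "n_subjects", lower = 1)
  fs <- sampling_rate
  if (is.null(effect_channels)) effect_channels <- seq_len(ceiling(n_eeg / 2))
  lapply(seq_len(n_subjects), function(s) {
    sseed <- substream_seed(seed, paste0("subject", s))
    len_s <- 2 + n_trials * isi + 2
    n <- as.integer(round(len_s * fs))
    eeg <- vapply(seq_len(n_eeg), function(ch) {
      noise_sd * generate_background(n, fs, 1,
                                     seed = substream_seed(sseed, paste0("bg", ch)),
                                     hp_cutoff = 0.3, lp_cutoff = 45)
    }, numeric(n))
    eeg <- t(eeg)                                   # channels x samples

    stim_s <- seq(2, by = isi, length.out = n_trials)
    stim <- as.integer(round(stim_s * fs))
    cond <- with_seed(substream_seed(sseed, "cond"),
                      sample(rep(c("A", "B"), length.out = n_trials)))
    rts <- with_seed(substream_seed(sseed, "rt"),
                     pmax(150, stats::rnorm(n_trials, rt_mean_ms, rt_sd_ms)))

    # R-peak train
    rr <- with_seed(substream_seed(sseed, "rr"),
                    pmax(0.4, stats::rnorm(ceiling(len_s / (60 / heart_rate)) + 5,
                                           60 / heart_rate, rr_sd)))
    rpeak_s <- cumsum(c(0.5, rr))
    rpeak_s <- rpeak_s[rpeak_s < len_s - 1.2]
    rpeaks <- as.integer(round(rpeak_s * fs))

    # HEP amplitude per R-peak: base + effect when the beat falls in the
    # pre-stimulus window of interest of a condition-A trial
    in_window_cond <- function(r) {
      lat <- (r - stim) / fs * 1000
      hit <- which(lat >= prestim_window[1] & lat <= prestim_window[2])
      if (length(hit)) cond[hit[1]] else NA_character_
    }
    beat_cond <- vapply(rpeaks, in_window_cond, character(1))
    amp_jit <- with_seed(substream_seed(sseed, "hepamp"),
                         stats::rnorm(length(rpeaks), 0, 0.2))
    hep_amp <- hep_base_uv + amp_jit +
      ifelse(!is.na(beat_cond) & beat_cond == "A", effect_uv, 0)

    hep_shape <- gaussian_pulse(hep_duration, 1, fs)
    centre <- floor(length(hep_shape) / 2)
    hep_start <- rpeaks + ms_to_samples(hep_latency, fs) - centre
    for (ch in effect_channels) for (j in seq_along(rpeaks)) {
      idx <- hep_start[j] + seq_along(hep_shape)
      ok <- idx >= 1 & idx <= n
      eeg[ch, idx[ok]] <- eeg[ch, idx[ok]] + hep_amp[j] * hep_shape[ok]
    }

    # CNV-like ramp: linear from 0 at ramp onset to -endpoint at the stimulus
    ramp_len <- ms_to_samples(-ramp_onset_ms, fs)
    ramp_unit <- seq(0, 1, length.out = ramp_len)
    for (i in seq_len(n_trials)) {
      endpoint <- cnv_base_uv + if (cond[i] == "A") confound_uv else 0
      idx <- (stim[i] - ramp_len + 1):stim[i] + 1L
      ok <- idx >= 1 & idx <= n
      for (ch in effect_channels)
        eeg[ch, idx[ok]] <- eeg[ch, idx[ok]] - endpoint * ramp_unit[ok]
    }

    # two-component synthetic ECG: R spike + T wave
    ecg <- numeric(n)
    r_wave <- gaussian_pulse(24, 600, fs)
    t_wave <- gaussian_pulse(200, 150, fs)
    for (r in rpeaks) {
      i1 <- r - floor(length(r_wave) / 2) + seq_along(r_wave)
      ok <- i1 >= 1 & i1 <= n
      ecg[i1[ok]] <- ecg[i1[ok]] + r_wave[ok]
      i2 <- r + ms_to_samples(250, fs) - floor(length(t_wave) / 2) +
        seq_along(t_wave)
      ok <- i2 >= 1 & i2 <= n
      ecg[i2[ok]] <- ecg[i2[ok]] + t_wave[ok]
    }

    rec <- continuous_recording(
      rbind(eeg, ecg), fs,
      c(paste0("EEG", seq_len(n_eeg)), "ECG"),
      c(rep("eeg", n_eeg), "ecg"))
    ev <- event_table(
      onset_sample = c(stim, rpeaks),
      event_type = c(rep("stimulus", n_trials), rep("rpeak", length(rpeaks))),
      condition = c(cond, rep(NA_character_, length(rpeaks))),
      rt_ms = c(rts, rep(NA_real_, length(rpeaks))))
    structure(list(
      recording = rec, events = ev,
      truth = list(
        trials = data.frame(trial = seq_len(n_trials), stim_onset = stim,
                            condition = cond, rt_ms = rts),
        rpeaks = data.frame(onset = rpeaks, hep_amp_uv = hep_amp,
                            window_condition = beat_cond),
        params = list(effect_uv = effect_uv, confound_uv = confound_uv,
                      effect_channels = effect_channels,
                      heart_rate = heart_rate, noise_sd = noise_sd,
                      seed = sseed))),
      class = "synthetic_session")
  })
}
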