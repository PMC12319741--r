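# Per-subject preparation: eligible pre-stimulus R-peaks -> processed HEP
# epochs with condition labels. Returns NULL when the subject is excluded by
# the minimum-trial rule.
prepare_subject <- function(session, select_window, epoch_window,
                            ptp_threshold, baseline, baseline_window,
                            min_trials) {
  rec <- channels_by_role(session$recording, "eeg")
  fs <- rec$sampling_rate
  stim <- events_of(session$events, "stimulus")
  rpeaks <- events_of(session$events, "rpeak")
  sel <- select_prestim_rpeaks(stim, rpeaks, select_window, fs)
  if (!nrow(sel)) return(NULL)
  ep <- extract_epochs(rec, sel$onset_sample, epoch_window[1],
                       epoch_window[2], condition = sel$condition)
  ep <- reject_ptp(ep, ptp_threshold)
  if (baseline) ep <- baseline_correct(ep, baseline_window)
  if (!enforce_min_trials(sum(!ep$rejected), min_trials)) return(NULL)
  list(recording = rec, stim = stim, sel = sel, epochs = ep, sfreq = fs)
}

subject_evokeds <- function(epochs, conditions) {
  lapply(conditions, function(cond) epoch_average(epochs, cond))
}

stack_evokeds <- function(per_subject) {
  # list (subjects) of channels x time -> subjects x channels x time
  n <- length(per_subject)
  d <- dim(per_subject[[1]])
  out <- array(NA_real_, c(n, d[1], d[2]))
  for (i in seq_len(n)) out[i, , ] <- per_subject[[i]]
  out
}

#' Validate heartbeat-locked condition effects across subjects
#'
#' The combined control pipeline for a group of sessions with two condition
#' labels: per subject, pre-stimulus R-peaks are selected, epoched, cleaned
#' and averaged per condition; conditions are compared with a spatio-temporal
#' cluster-based permutation t test. The observed maximum cluster statistic
#' is then gated by a surrogate-heartbeat null (R-peak latency shuffles
#' within condition), the whole analysis is repeated after pseudotrial
#' correction, and the corrected analysis is gated by the adapted
#' two-pseudotrial surrogate. The verdict for each branch is
#' "significant" only when the cluster test finds a cluster with
#' Monte-Carlo p < 0.05 *and* the statistic exceeds the surrogate cutoff.
#'
#' @param sessions list of sessions (e.g. from [make_validation_session()]),
#'   each with a `recording` and an `events` table holding condition-labelled
#'   stimuli and R-peaks.
#' @param conditions the two condition labels to compare (A minus B).
#' @param select_window R-peak eligibility window, ms relative to stimulus.
#' @param epoch_window HEP epoch window, ms relative to the R-peak.
#' @param adjacency `channel_adjacency`; defaults to a chain over the EEG
#'   channels.
#' @param ptp_threshold peak-to-peak rejection threshold, uV.
#' @param baseline,baseline_window baseline-correction toggle and window.
#' @param min_trials minimum surviving epochs per subject.
#' @param n_perm cluster-test permutations.
#' @param n_surrogate surrogate iterations.
#' @param pseudo_window window for pseudo-R-peak insertion (defaults to
#'   `select_window`).
#' @param seed master seed.
#' @return An object of class `hep_validation` with elements `uncorrected`
#'   and `corrected`, each holding the `cluster_result`, the
#'   `surrogate_null`, the gate decision and Monte-Carlo p; plus bookkeeping
#'   (`n_subjects`, excluded subjects, config echo).
#' @export
hep_validation <- function(sessions, conditions = c("A", "B"),
                           select_window = c(-1100, -600),
                           epoch_window = c(-200, 600), adjacency = NULL,
                           ptp_threshold = 150, baseline = TRUE,
                           baseline_window = c(-150, -50), min_trials = 20,
                           n_perm = 200, n_surrogate = 100,
                           pseudo_window = NULL, seed = 1) {
  stopifnot(length(sessions) >= 2L, length(conditions) == 2L)
  if (is.null(pseudo_window)) pseudo_window <- select_window
  subjects <- lapply(sessions, prepare_subject, select_window = select_window,
                     epoch_window = epoch_window,
                     ptp_threshold = ptp_threshold, baseline = baseline,
                     baseline_window = baseline_window,
                     min_trials = min_trials)
  excluded <- which(vapply(subjects, is.null, logical(1)))
  if (length(excluded))
    message(sprintf("hep_validation: excluded %d subject(s) by the minimum-trial rule", length(excluded)))
  subjects <- Filter(Negate(is.null), subjects)
  ns <- length(subjects)
  if (ns < 2L) stop_hv("fewer than 2 includable subjects")
  if (is.null(adjacency))
    adjacency <- chain_adjacency(subjects[[1]]$recording$channel_labels)

  evoked_pair <- function(epochs_list) {
    a <- stack_evokeds(lapply(epochs_list, epoch_average, conditions[1]))
    b <- stack_evokeds(lapply(epochs_list, epoch_average, conditions[2]))
    list(a = a, b = b)
  }
  run_cbp <- function(pair, cbp_seed) {
    cluster_permutation_test(pair$a, pair$b, adjacency, n_perm = n_perm,
                             seed = cbp_seed, paired = TRUE)
  }
  tmap_max <- function(pair) {
    tm <- paired_t_map(pair$a, pair$b)
    max_cluster_stat(tm$t, tm$p, adjacency, 0.05)
  }
  reepoch <- function(subj, sel) {
    ep <- extract_epochs(subj$recording, sel$onset_sample, epoch_window[1],
                         epoch_window[2], condition = sel$condition)
    ep <- reject_ptp(ep, ptp_threshold)
    if (baseline) ep <- baseline_correct(ep, baseline_window)
    ep
  }

  # ---- uncorrected branch --------------------------------------------------
  obs_pair <- evoked_pair(lapply(subjects, `[[`, "epochs"))
  obs_res <- run_cbp(obs_pair, substream_seed(seed, "cbp_obs"))
  null_unc <- surrogate_null(function(iter_seed) {
    eps <- lapply(seq_len(ns), function(s) {
      subj <- subjects[[s]]
      shuf <- shuffle_rpeaks_within_condition(
        subj$sel, subj$sfreq, seed = substream_seed(iter_seed, paste0("s", s)))
      reepoch(subj, shuf)
    })
    tmap_max(evoked_pair(eps))
  }, n_iter = n_surrogate, seed = substream_seed(seed, "null_unc"))
  gate_unc <- compare_to_null(obs_res$max_abs_sum_t, null_unc)

  # ---- corrected branch ----------------------------------------------------
  pseudo_for <- function(subj, pseudo_seed) {
    ps <- insert_pseudo_rpeaks(subj$stim, pseudo_window, subj$sfreq,
                               seed = pseudo_seed)
    reepoch(subj, ps)
  }
  corrected_eps <- lapply(seq_len(ns), function(s) {
    subj <- subjects[[s]]
    pseudotrial_correct(subj$epochs,
                        pseudo_for(subj, substream_seed(seed, paste0("pseudo", s))))
  })
  corr_pair <- evoked_pair(corrected_eps)
  corr_res <- run_cbp(corr_pair, substream_seed(seed, "cbp_corr"))
  null_corr <- surrogate_null(function(iter_seed) {
    eps <- lapply(seq_len(ns), function(s) {
      subj <- subjects[[s]]
      e1 <- pseudo_for(subj, substream_seed(iter_seed, paste0("a", s)))
      e2 <- pseudo_for(subj, substream_seed(iter_seed, paste0("b", s)))
      pseudotrial_correct(e1, e2)
    })
    tmap_max(evoked_pair(eps))
  }, n_iter = n_surrogate, seed = substream_seed(seed, "null_corr"))
  gate_corr <- compare_to_null(corr_res$max_abs_sum_t, null_corr)

  branch <- function(res, null, gate) {
    cbp_sig <- length(res$clusters) > 0 &&
      any(vapply(res$clusters, `[[`, numeric(1), "p_mc") < 0.05)
    list(result = res, null = null, cbp_significant = cbp_sig,
         surrogate_p = gate$p, surrogate_pass = gate$significant,
         significant = cbp_sig && gate$significant)
  }
  structure(list(
    uncorrected = branch(obs_res, null_unc, gate_unc),
    corrected = branch(corr_res, null_corr, gate_corr),
    n_subjects = ns, excluded = excluded, conditions = conditions,
    params = list(select_window = select_window, epoch_window = epoch_window,
                  ptp_threshold = ptp_threshold, baseline = baseline,
                  baseline_window = baseline_window, min_trials = min_trials,
                  n_perm = n_perm, n_surrogate = n_surrogate,
                  pseudo_window = pseudo_window, seed = seed)),
    class = "hep_validation")
}

#' @export
print.hep_validation <- function(x, ...) {
  cat(sprintf("<hep_validation> %d subject(s), conditions %s vs %s\n",
              x$n_subjects, x$conditions[1], x$conditions[2]))
  for (nm in c("uncorrected", "corrected")) {
    br <- x[[nm]]
    cat(sprintf("  %-11s max |sum(t)| = %8.2f | cluster test %s | surrogate gate %s (p = %.3g) -> %s\n",
                nm, br$result$max_abs_sum_t,
                if (br$cbp_significant) "significant" else "n.s.",
                if (br$surrogate_pass) "passed" else "failed",
                br$surrogate_p,
                if (br$significant) "heartbeat-locked effect" else "no verdict"))
  }
  invisible(x)
}
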