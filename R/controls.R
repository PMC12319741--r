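#' Shuffle pre-stimulus R-peak latencies within condition
#'
#' The surrogate-heartbeat null construction: the multiset of R-peak
#' latencies relative to their parent stimulus is randomly permuted across
#' trials *within each condition*; every trial keeps its own stimulus onset
#' (and hence regains its original number of R-peaks), so per-condition
#' latency multisets, trial counts, mean heart rate and inter-beat intervals
#' are preserved exactly while the temporal alignment between heartbeat and
#' EEG is broken. A condition with a single eligible R-peak keeps the
#' identity permutation (with a message).
#'
#' @param selected data.frame from [select_prestim_rpeaks()] (columns
#'   `onset_sample`, `latency_ms`, `parent_stim`, `condition`).
#' @param sampling_rate Hz.
#' @param seed permutation seed.
#' @return the same data.frame with permuted `latency_ms` and recomputed
#'   `onset_sample`.
#' @export
shuffle_rpeaks_within_condition <- function(selected, sampling_rate, seed = 1) {
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  if (!all(c("onset_sample", "latency_ms", "condition") %in% names(selected)))
    stop_hv("'selected' must come from select_prestim_rpeaks()")
  out <- selected
  stim_onset <- selected$onset_sample -
    ms_to_samples(selected$latency_ms, sampling_rate)
  conds <- unique(selected$condition)
  with_seed(seed, {
    for (cond in conds) {
      idx <- which(selected$condition %in% cond)
      if (length(idx) < 2L) {
        message(sprintf("shuffle_rpeaks_within_condition: condition '%s' has a single eligible R-peak; identity permutation", cond))
        next
      }
      out$latency_ms[idx] <- sample(selected$latency_ms[idx])
    }
  })
  out$onset_sample <- stim_onset + ms_to_samples(out$latency_ms, sampling_rate)
  out
}

#' Build a surrogate null distribution
#'
#' Runs an analysis function on `n_iter` independently shuffled datasets and
#' stores each iteration's maximum absolute cluster statistic. The analysis
#' function receives a derived iteration seed and must return a scalar
#' max |sum(t)|; an iteration yielding no clusters contributes 0 (logged).
#'
#' @param analysis_fn `function(iter_seed)` returning a scalar statistic.
#' @param n_iter iterations (>= 1; 100 or more recommended).
#' @param seed master seed; iteration seeds are derived deterministically.
#' @return An object of class `surrogate_null`: `max_abs_sum_t` (vector of
#'   length `n_iter`), `n_iter`, `alpha_cutoff` (empirical 95th percentile),
#'   `seed`.
#' @export
surrogate_null <- function(analysis_fn, n_iter = 100, seed = 1) {
  check_scalar(n_iter, "n_iter", lower = 1)
  stats_vec <- vapply(seq_len(n_iter), function(i) {
    s <- analysis_fn(substream_seed(seed, paste0("surrogate", i)))
    if (is.null(s) || !length(s) || !is.finite(s)) {
      message(sprintf("surrogate_null: iteration %d returned no clusters; contributing 0", i))
      0
    } else abs(as.numeric(s[1]))
  }, numeric(1))
  structure(list(max_abs_sum_t = stats_vec, n_iter = n_iter,
                 alpha_cutoff = empirical_cutoff(stats_vec, 0.95),
                 seed = seed),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %d iteration(s); 95%% cutoff |sum(t)| = %.3f (median %.3f)\n",
              x$n_iter, x$alpha_cutoff, stats::median(x$max_abs_sum_t)))
  invisible(x)
}

#' Compare an observed cluster statistic with a surrogate null
#'
#' Monte-Carlo p is `max(count(null >= |observed|), 1) / n_iter`; the effect
#' is called significant when |observed| exceeds the null's 95th-percentile
#' cutoff (i.e. it is larger than 95% of the surrogate statistics).
#'
#' @param observed_sum_t observed (maximum) cluster summed t value.
#' @param null a [surrogate_null()].
#' @return list with `p`, `significant`, `cutoff`.
#' @export
compare_to_null <- function(observed_sum_t, null) {
  stopifnot(inherits(null, "surrogate_null"))
  obs <- abs(observed_sum_t)
  p <- max(sum(null$max_abs_sum_t >= obs), 1) / null$n_iter
  list(p = p, significant = obs > null$alpha_cutoff,
       cutoff = null$alpha_cutoff)
}

#' Insert pseudo-R-peak triggers
#'
#' For each stimulus, inserts exactly one pseudo trigger at a uniformly
#' random time inside the (strictly pre-stimulus) window, independently
#' across trials; reproducible under the seed. Condition labels and reaction
#' times of the parent stimulus are copied onto the pseudo events.
#'
#' @param stim_events [event_table()] of stimulus events.
#' @param window_ms pre-stimulus window, default `c(-1100, -600)` ms.
#' @param sampling_rate Hz.
#' @param seed draw seed.
#' @return data.frame with `onset_sample`, `latency_ms`, `parent_stim`,
#'   `condition`, `rt_ms` (one row per stimulus), usable like the output of
#'   [select_prestim_rpeaks()].
#' @export
insert_pseudo_rpeaks <- function(stim_events, window_ms = c(-1100, -600),
                                 sampling_rate, seed = 1) {
  if (window_ms[2] > 0 || window_ms[1] >= window_ms[2])
    stop_hv("'window_ms' must be an ordered, strictly pre-stimulus pair")
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  n <- nrow(stim_events)
  lat <- with_seed(seed, stats::runif(n, window_ms[1], window_ms[2]))
  data.frame(
    onset_sample = stim_events$onset_sample + ms_to_samples(lat, sampling_rate),
    latency_ms = lat,
    parent_stim = seq_len(n),
    condition = stim_events$condition,
    rt_ms = stim_events$rt_ms,
    stringsAsFactors = FALSE)
}

#' Pseudotrial correction
#'
#' Within each condition, the average pseudo-epoch (epochs locked to
#' randomly inserted pseudo-R-peaks, processed through the identical
#' rejection/baseline pipeline as the real HEP epochs) is subtracted
#' sample-wise from every real HEP epoch of that condition, removing
#' heartbeat-independent activity such as slow anticipatory potentials. A
#' condition with zero surviving pseudo epochs raises an error so the caller
#' can exclude the subject from that comparison.
#'
#' @param hep_epochs `epoch_set` of real HEP epochs with condition labels.
#' @param pseudo_epochs `epoch_set` of pseudo epochs with condition labels,
#'   on the same time axis.
#' @return the corrected `epoch_set`.
#' @export
pseudotrial_correct <- function(hep_epochs, pseudo_epochs) {
  stopifnot(inherits(hep_epochs, "epoch_set"),
            inherits(pseudo_epochs, "epoch_set"))
  if (!isTRUE(all.equal(hep_epochs$time_ms, pseudo_epochs$time_ms)))
    stop_hv("real and pseudo epochs are on different time axes")
  out <- hep_epochs
  for (cond in unique(hep_epochs$condition)) {
    ridx <- which(hep_epochs$condition %in% cond & !hep_epochs$rejected)
    pidx <- which(pseudo_epochs$condition %in% cond & !pseudo_epochs$rejected)
    if (!length(ridx)) next
    if (!length(pidx))
      stop_hv(sprintf("no surviving pseudo epochs for condition '%s'; exclude this subject from the comparison", cond))
    d <- dim(pseudo_epochs$data)
    avg <- matrix(colMeans(matrix(pseudo_epochs$data[pidx, , , drop = FALSE],
                                  nrow = length(pidx))), d[2], d[3])
    out$data[ridx, , ] <- out$data[ridx, , , drop = FALSE] -
      array(rep(avg, each = length(ridx)), c(length(ridx), d[2], d[3]))
  }
  out
}

#' Surrogate null adapted to pseudotrial-corrected data
#'
#' Per iteration, two independent pseudo-onset draws per condition generate
#' two pseudotrial sets; the analysis function receives both draws and the
#' iteration seed, corrects the first set by the second's per-condition
#' average (mirroring how the real data are corrected by the pseudotrial
#' average), runs the cluster analysis, and returns the maximum |sum(t)|.
#' This controls for structure introduced by the correction itself.
#'
#' @param stim_events [event_table()] of stimulus events (with condition
#'   labels).
#' @param window_ms pre-stimulus pseudo window.
#' @param sampling_rate Hz.
#' @param analysis_fn `function(pseudo_events_1, pseudo_events_2, iter_seed)`
#'   returning a scalar max |sum(t)|.
#' @param n_iter iterations.
#' @param seed master seed.
#' @return a [surrogate_null()] object.
#' @export
surrogate_for_corrected <- function(stim_events, window_ms = c(-1100, -600),
                                    sampling_rate, analysis_fn,
                                    n_iter = 100, seed = 1) {
  surrogate_null(function(iter_seed) {
    p1 <- insert_pseudo_rpeaks(stim_events, window_ms, sampling_rate,
                               seed = substream_seed(iter_seed, "draw1"))
    p2 <- insert_pseudo_rpeaks(stim_events, window_ms, sampling_rate,
                               seed = substream_seed(iter_seed, "draw2"))
    analysis_fn(p1, p2, iter_seed)
  }, n_iter = n_iter, seed = seed)
}
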