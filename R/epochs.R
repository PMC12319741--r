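new_epoch_set <- function(data, time_ms, sfreq, channels, condition = NULL,
                          source_event = NULL, rejected = NULL,
                          n_dropped = 0L) {
  n <- dim(data)[1]
  structure(list(
    data = data, time_ms = time_ms, sfreq = sfreq, channels = channels,
    condition = if (is.null(condition)) rep(NA_character_, n) else condition,
    source_event = if (is.null(source_event)) seq_len(n) else source_event,
    rejected = if (is.null(rejected)) rep(FALSE, n) else rejected,
    n_dropped = n_dropped),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d sample(s), [%g, %g] ms @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time_ms), max(x$time_ms), x$sfreq))
  if (any(x$rejected))
    cat(sprintf("  %d trial(s) marked rejected\n", sum(x$rejected)))
  if (!all(is.na(x$condition)))
    print(table(condition = x$condition, useNA = "no"))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]

#' Extract epochs around events
#'
#' Cuts per-event windows `[tmin_ms, tmax_ms)` (half-open in samples) out of a
#' continuous recording; the sample at the locking event maps to time 0.
#' Events whose window does not fit inside the recording are dropped and
#' counted in the result's `n_dropped` field.
#'
#' @param recording a [continuous_recording()].
#' @param events an [event_table()], or an integer vector of 0-based onset
#'   samples.
#' @param tmin_ms,tmax_ms epoch window in ms relative to the event.
#' @param condition optional per-event condition labels (taken from the event
#'   table when absent).
#' @return An object of class `epoch_set` with a trials x channels x time
#'   array in uV.
#' @examples
#' rec <- continuous_recording(matrix(sin(1:1000 / 10), 1), 250, "Cz")
#' ep <- extract_epochs(rec, c(250L, 500L), -200, 600)
#' ep
#' @export
extract_epochs <- function(recording, events, tmin_ms, tmax_ms,
                           condition = NULL) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (inherits(events, "event_table")) {
    onsets <- events$onset_sample
    if (is.null(condition)) condition <- events$condition
  } else {
    onsets <- as.integer(events)
  }
  if (tmax_ms <= tmin_ms) stop_hv("tmax_ms must exceed tmin_ms")
  fs <- recording$sampling_rate
  t0 <- ms_to_samples(tmin_ms, fs)
  len <- as.integer(round((tmax_ms - tmin_ms) / 1000 * fs))
  time_ms <- (t0 + seq_len(len) - 1L) * 1000 / fs
  ns <- n_samples(recording)
  start0 <- onsets + t0                       # 0-based first sample
  ok <- start0 >= 0L & (start0 + len) <= ns
  n_drop <- sum(!ok)
  if (n_drop)
    message(sprintf("extract_epochs: dropped %d event(s) whose window falls outside the recording", n_drop))
  keep <- which(ok)
  nch <- nrow(recording$data)
  out <- array(NA_real_, dim = c(length(keep), nch, len))
  if (length(keep)) {
    offs <- seq_len(len)
    for (i in seq_along(keep)) {
      idx <- start0[keep[i]] + offs
      out[i, , ] <- recording$data[, idx, drop = FALSE]
    }
  }
  if (!is.null(condition)) condition <- rep_len(condition, length(onsets))[keep]
  new_epoch_set(out, time_ms, fs, recording$channel_labels,
                condition = condition, source_event = keep,
                n_dropped = n_drop)
}

#' Moving-window peak-to-peak artifact rejection
#'
#' Marks a trial rejected iff in any channel the max-minus-min amplitude
#' within any window position meets or exceeds the threshold. The mask is
#' monotone in the threshold and never destructive: previously rejected
#' trials stay rejected.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv peak-to-peak threshold in uV (default 150).
#' @param win_ms moving window length in ms (default 200).
#' @param step_ms window step in ms (default 100).
#' @return the `epoch_set` with an updated rejection mask.
#' @export
reject_ptp <- function(epochs, threshold_uv = 150, win_ms = 200,
                       step_ms = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.finite(threshold_uv)) return(epochs)
  fs <- epochs$sfreq
  len <- dim(epochs$data)[3]
  win <- max(2L, ms_to_samples(win_ms, fs))
  step <- max(1L, ms_to_samples(step_ms, fs))
  if (win > len) stop_hv("window longer than the epoch")
  starts <- unique(c(seq(1L, len - win + 1L, by = step), len - win + 1L))
  nt <- n_epochs(epochs)
  nch <- dim(epochs$data)[2]
  # fast pre-check: a trial can only fail a window if its whole-epoch
  # peak-to-peak already reaches the threshold
  M <- matrix(epochs$data, nt * nch)            # rows: trial x channel
  ridx <- seq_len(nt * nch)
  g_max <- M[cbind(ridx, max.col(M, ties.method = "first"))]
  g_min <- M[cbind(ridx, max.col(-M, ties.method = "first"))]
  suspect <- rowSums(matrix(g_max - g_min >= threshold_uv, nt, nch)) > 0
  bad <- rep(FALSE, nt)
  for (i in which(suspect)) {
    rows <- matrix(M[seq(i, by = nt, length.out = nch), , drop = FALSE], nch)
    for (s in starts) {
      sub <- rows[, s:(s + win - 1L), drop = FALSE]
      ptp <- apply(sub, 1, function(v) max(v) - min(v))
      if (any(ptp >= threshold_uv)) { bad[i] <- TRUE; break }
    }
  }
  epochs$rejected <- epochs$rejected | bad
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#' Idempotent: the corrected window mean recomputes to zero.
#'
#' @param epochs an `epoch_set`.
#' @param window_ms baseline window in ms (default `c(-150, -50)`).
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-150, -50)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_indices(epochs$time_ms, window_ms)
  d <- dim(epochs$data)
  bl <- rowMeans(matrix(epochs$data[, , idx, drop = FALSE], d[1] * d[2]))
  epochs$data <- epochs$data - array(bl, dim = d)
  epochs
}

#' Mean amplitude in a time window
#'
#' Arithmetic mean over the samples inside `window_ms` (closed interval), per
#' trial and channel for an `epoch_set`, or per channel for a plain
#' channels x time matrix with a time axis attribute.
#'
#' @param epochs an `epoch_set`.
#' @param window_ms length-2 ms window.
#' @return trials x channels matrix of window means (uV); a vector when there
#'   is a single channel.
#' @export
window_mean <- function(epochs, window_ms) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_indices(epochs$time_ms, window_ms)
  d <- dim(epochs$data)
  m <- matrix(rowMeans(matrix(epochs$data[, , idx, drop = FALSE],
                              d[1] * d[2])), d[1], d[2])
  if (ncol(m) == 1L) drop(m) else m
}

#' Average non-rejected epochs into an evoked response
#' @param epochs an `epoch_set`.
#' @param condition optional condition label to restrict to.
#' @return channels x time matrix (uV).
#' @export
epoch_average <- function(epochs, condition = NULL) {
  keep <- !epochs$rejected
  if (!is.null(condition)) keep <- keep & epochs$condition %in% condition
  if (!any(keep)) stop_hv("no surviving epochs to average")
  d <- dim(epochs$data)
  ev <- matrix(colMeans(matrix(epochs$data[keep, , , drop = FALSE],
                               nrow = sum(keep))), d[2], d[3])
  dimnames(ev) <- list(epochs$channels, NULL)
  ev
}

#' Grand average evoked responses per condition
#'
#' Per subject and condition, the unweighted mean over non-rejected trials;
#' then the unweighted mean over subjects. A subject contributing zero
#' surviving trials to a condition is excluded from that condition's average
#' (with a message).
#'
#' @param epoch_sets list of `epoch_set` objects, one per subject.
#' @param conditions condition labels to average (default: all observed).
#' @return list per condition with `subject_evoked`
#'   (subjects x channels x time) and `grand` (channels x time).
#' @export
grand_average <- function(epoch_sets, conditions = NULL) {
  stopifnot(length(epoch_sets) >= 1L)
  if (is.null(conditions))
    conditions <- sort(unique(stats::na.omit(
      unlist(lapply(epoch_sets, `[[`, "condition")))))
  if (!length(conditions)) conditions <- NA_character_
  out <- list()
  for (cond in conditions) {
    evs <- list()
    for (s in seq_along(epoch_sets)) {
      ep <- epoch_sets[[s]]
      keep <- !ep$rejected &
        (if (is.na(cond)) TRUE else ep$condition %in% cond)
      if (!any(keep)) {
        message(sprintf("grand_average: subject %d has no surviving trials for condition '%s'; excluded", s, cond))
        next
      }
      evs[[length(evs) + 1L]] <- apply(ep$data[keep, , , drop = FALSE],
                                       c(2, 3), mean)
    }
    if (!length(evs)) stop_hv(sprintf("no subject has data for condition '%s'", cond))
    se <- array(NA_real_, dim = c(length(evs), dim(evs[[1]])))
    for (i in seq_along(evs)) se[i, , ] <- evs[[i]]
    out[[as.character(cond)]] <- list(subject_evoked = se,
                                      grand = apply(se, c(2, 3), mean))
  }
  out
}
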