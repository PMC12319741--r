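#' Select pre-stimulus R-peaks
#'
#' An R-peak is eligible iff its latency relative to some stimulus lies inside
#' `window_ms` (closed on both ends). Each eligible R-peak is assigned to
#' exactly one stimulus — the earliest matching one if windows of two stimuli
#' overlap — and inherits that stimulus's condition label and reaction time.
#' The result is invariant to the input ordering of either event set.
#'
#' @param stim_events [event_table()] (or rows) of stimulus events.
#' @param rpeak_events [event_table()] (or rows) of R-peak events.
#' @param window_ms selection window relative to the stimulus, default
#'   `c(-1100, -600)` ms.
#' @param sampling_rate Hz (needed to convert the window to samples).
#' @return a `data.frame` of eligible R-peaks: `onset_sample`, `latency_ms`,
#'   `parent_stim` (index into the sorted stimulus table), `condition`,
#'   `rt_ms`.
#' @export
select_prestim_rpeaks <- function(stim_events, rpeak_events,
                                  window_ms = c(-1100, -600),
                                  sampling_rate) {
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  stim <- sort(unique(stim_events$onset_sample))
  meta <- stim_events[match(stim, stim_events$onset_sample), , drop = FALSE]
  rp <- sort(unique(rpeak_events$onset_sample))
  lo <- window_ms[1] * sampling_rate / 1000
  hi <- window_ms[2] * sampling_rate / 1000
  # eligible stimulus onsets for R-peak r satisfy r - hi <= s <= r - lo;
  # the earliest such stimulus wins when two windows overlap
  cand <- findInterval(rp - hi, stim, left.open = TRUE) + 1L
  ok <- cand <= length(stim) & (rp - stim[pmin(cand, length(stim))]) >= lo &
    (rp - stim[pmin(cand, length(stim))]) <= hi
  rp <- rp[ok]
  s <- cand[ok]
  data.frame(
    onset_sample = rp,
    latency_ms = (rp - stim[s]) * 1000 / sampling_rate,
    parent_stim = s,
    condition = if ("condition" %in% names(meta))
      meta$condition[s] else rep(NA_character_, length(s)),
    rt_ms = if ("rt_ms" %in% names(meta))
      meta$rt_ms[s] else rep(NA_real_, length(s)),
    stringsAsFactors = FALSE)
}

#' Minimum-trial inclusion rule
#'
#' @param n_selected number of usable epochs for a subject.
#' @param minimum inclusion threshold (default 20).
#' @return `TRUE` iff `n_selected >= minimum`.
#' @export
enforce_min_trials <- function(n_selected, minimum = 20) {
  check_scalar(n_selected, "n_selected", lower = 0)
  n_selected >= minimum
}

#' Median split of per-trial values
#'
#' Values strictly below the median go to the first group, strictly above to
#' the second. Ties at the median are assigned in trial order to whichever
#' group is currently smaller (first tie to the low group on exact balance),
#' so group sizes never differ by more than one.
#'
#' @param values numeric vector (>= 2 finite values, not all equal).
#' @param labels two group labels, low then high.
#' @return character vector of per-trial labels.
#' @examples
#' median_split(c(1, 2, 2, 3))
#' @export
median_split <- function(values, labels = c("low", "high")) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop_hv("'values' must hold >= 2 finite numbers")
  if (diff(range(values)) == 0)
    stop_hv("all values equal: median split undefined")
  stopifnot(length(labels) == 2L)
  med <- stats::median(values)
  out <- rep(NA_character_, length(values))
  out[values < med] <- labels[1]
  out[values > med] <- labels[2]
  for (i in which(values == med)) {
    n_low <- sum(out == labels[1], na.rm = TRUE)
    n_high <- sum(out == labels[2], na.rm = TRUE)
    out[i] <- if (n_low <= n_high) labels[1] else labels[2]
  }
  out
}

#' LDA spatial filter from two classes of feature vectors
#'
#' Fisher discriminant direction `w = S^-1 (mu_a - mu_b)` with a
#' shrinkage-regularised pooled within-class covariance
#' `S = (1 - lambda) S_pooled + lambda nu I` (`nu` = mean diagonal). The
#' shrinkage intensity is chosen analytically (Ledoit-Wolf-style: the ratio
#' of the summed sampling variances of the covariance entries to the summed
#' squared deviations from the target), which keeps the estimate
#' well-conditioned for many channels and few trials. The projection applied
#' to single-trial channel data yields one virtual-channel time course per
#' trial.
#'
#' @param class_a_features,class_b_features observations x channels matrices
#'   of per-trial features (e.g. channel-wise window means), >= 2 rows each.
#' @return list with `weights` (unit-norm), `lambda`, and `project(epochs)`
#'   returning a trials x time matrix for an `epoch_set` (or an epochs x 1 x
#'   time collapse).
#' @export
lda_spatial_filter <- function(class_a_features, class_b_features) {
  Xa <- as.matrix(class_a_features); Xb <- as.matrix(class_b_features)
  if (nrow(Xa) < 2L || nrow(Xb) < 2L)
    stop_hv("need >= 2 observations per class")
  if (ncol(Xa) != ncol(Xb)) stop_hv("feature dimensions differ between classes")
  mu_a <- colMeans(Xa); mu_b <- colMeans(Xb)
  Ra <- sweep(Xa, 2, mu_a); Rb <- sweep(Xb, 2, mu_b)
  R <- rbind(Ra, Rb)
  n <- nrow(R)
  S <- crossprod(R) / (n - 2)
  d <- mu_a - mu_b
  if (sum(d^2) == 0 && sum(S^2) == 0)
    stop_hv("degenerate input: identical class means with zero scatter")
  if (sum(d^2) == 0)
    stop_hv("equal class means: no discriminative direction")
  # analytic shrinkage toward nu * I
  nu <- mean(diag(S))
  target <- diag(nu, ncol(S))
  # sampling variance of each covariance entry, estimated from the data
  W <- array(0, dim = c(ncol(S), ncol(S)))
  for (i in seq_len(n)) {
    ci <- tcrossprod(R[i, ])
    W <- W + (ci - S)^2
  }
  var_s <- W / (n^2)
  denom <- sum((S - target)^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_s) / denom)) else 1
  S_shrunk <- (1 - lambda) * S + lambda * target
  w <- tryCatch(solve(S_shrunk, d),
                error = function(e) stop_hv("within-class covariance is singular even after shrinkage"))
  w <- w / sqrt(sum(w^2))
  project <- function(epochs) {
    stopifnot(inherits(epochs, "epoch_set"))
    nt <- n_epochs(epochs); len <- dim(epochs$data)[3]
    out <- matrix(NA_real_, nt, len)
    for (i in seq_len(nt)) out[i, ] <- w %*% epochs$data[i, , ]
    out
  }
  list(weights = w, lambda = lambda, project = project)
}

#' Transplant a task trial structure onto a resting recording
#'
#' Copies event onsets and metadata verbatim onto another recording; events
#' whose onset lies beyond the target recording are dropped with a message.
#'
#' @param task_events an [event_table()].
#' @param rest_recording a [continuous_recording()].
#' @return an [event_table()] valid for `rest_recording`.
#' @export
transplant_events <- function(task_events, rest_recording) {
  stopifnot(inherits(rest_recording, "continuous_recording"))
  ns <- n_samples(rest_recording)
  keep <- task_events$onset_sample < ns
  if (any(!keep))
    message(sprintf("transplant_events: dropped %d event(s) beyond the rest recording", sum(!keep)))
  ev <- task_events[keep, , drop = FALSE]
  event_table(ev$onset_sample, ev$event_type, ev$condition, ev$rt_ms)
}
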