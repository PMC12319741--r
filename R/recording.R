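#' Continuous multichannel recording
#'
#' Container for a continuous EEG/ECG recording: a channels-by-samples matrix
#' in microvolts, a sampling rate, unique channel labels and a per-channel
#' role tag (`"eeg"`, `"ecg"` or `"other"`).
#'
#' @param data numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param channel_roles character vector of roles, recycled if length 1.
#' @return An object of class `continuous_recording`.
#' @examples
#' rec <- continuous_recording(matrix(rnorm(500), 1), 250, "Pz")
#' rec
#' @export
continuous_recording <- function(data, sampling_rate, channel_labels,
                                 channel_roles = "eeg") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop_hv("'data' must be a numeric channels x samples matrix")
  if (!all(is.finite(data))) stop_hv("recording contains non-finite samples")
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop_hv("number of channel labels does not match number of data rows")
  if (anyDuplicated(channel_labels))
    stop_hv("channel labels must be unique")
  if (length(channel_roles) == 1L)
    channel_roles <- rep(channel_roles, nrow(data))
  if (length(channel_roles) != nrow(data))
    stop_hv("channel_roles must have one entry per channel")
  if (!all(channel_roles %in% c("eeg", "ecg", "other")))
    stop_hv("channel roles must be one of 'eeg', 'ecg', 'other'")
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, channel_roles = channel_roles),
    class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat("  channels:", paste(sprintf("%s[%s]", x$channel_labels,
                                   substr(x$channel_roles, 1, 3)),
                           collapse = " "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Pick channels of a given role
#' @param rec a `continuous_recording`.
#' @param role role tag to select.
#' @return a `continuous_recording` restricted to the matching channels.
#' @export
channels_by_role <- function(rec, role = "eeg") {
  keep <- which(rec$channel_roles == role)
  if (!length(keep)) stop_hv(sprintf("recording has no '%s' channels", role))
  continuous_recording(rec$data[keep, , drop = FALSE], rec$sampling_rate,
                       rec$channel_labels[keep], rec$channel_roles[keep])
}

EVENT_TYPES <- c("stimulus", "rpeak", "pseudo", "simhep")

#' Typed event table
#'
#' Events are stored as 0-based integer sample onsets with a type tag and
#' optional per-event metadata (condition label, reaction time). Onsets are
#' kept sorted ascending within each type.
#'
#' @param onset_sample integer vector of 0-based sample onsets.
#' @param event_type character vector (recycled): one of
#'   `"stimulus"`, `"rpeak"`, `"pseudo"`, `"simhep"`.
#' @param condition optional per-event condition label (NA allowed).
#' @param rt_ms optional per-event reaction time in ms (NA allowed).
#' @return A `data.frame` of class `event_table`.
#' @examples
#' event_table(c(100, 500), "stimulus", condition = c("low", "high"))
#' @export
event_table <- function(onset_sample, event_type = "stimulus",
                        condition = NA_character_, rt_ms = NA_real_) {
  n <- length(onset_sample)
  if (n && (!is.numeric(onset_sample) || any(!is.finite(onset_sample)) ||
            any(onset_sample < 0) || any(onset_sample != round(onset_sample))))
    stop_hv("onset_sample must be non-negative integers (0-based samples)")
  event_type <- rep_len(as.character(event_type), n)
  if (n && !all(event_type %in% EVENT_TYPES))
    stop_hv("event_type must be one of: ", paste(EVENT_TYPES, collapse = ", "))
  df <- data.frame(onset_sample = as.integer(onset_sample),
                   event_type = event_type,
                   condition = rep_len(as.character(condition), n),
                   rt_ms = rep_len(as.numeric(rt_ms), n),
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$event_type, EVENT_TYPES), df$onset_sample), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s)\n", nrow(x)))
  if (nrow(x)) print(table(x$event_type))
  invisible(x)
}

events_of <- function(events, type) {
  events[events$event_type == type, , drop = FALSE]
}
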