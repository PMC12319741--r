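#' Write an event table as TSV
#'
#' Dialect: columns `onset_sample` (0-based integer), `event_type`,
#' `condition` (empty for NA), `rt_ms` (empty for NA), tab-separated with a
#' header row.
#'
#' @param events an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$condition[is.na(df$condition)] <- ""
  df$rt_ms <- ifelse(is.na(df$rt_ms), "", format(df$rt_ms, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an event table from TSV
#'
#' Validates the dialect of [write_events()]: unknown event types and
#' negative or non-integer onsets are rejected with the offending row
#' numbers; duplicate (onset, type) rows are deduplicated with a warning.
#' Events are returned sorted. An events file holding only the header yields
#' an empty table.
#'
#' @param path TSV path.
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character", "character",
                                         "character"),
                          na.strings = "", stringsAsFactors = FALSE)
  need <- c("onset_sample", "event_type", "condition", "rt_ms")
  if (!all(need %in% names(df)))
    stop_hv("events file must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df))
    return(event_table(integer(0)))
  bad <- which(!is.finite(df$onset_sample) | df$onset_sample < 0 |
                 df$onset_sample != round(df$onset_sample))
  if (length(bad))
    stop_hv("invalid onset_sample at row(s): ", paste(bad, collapse = ", "))
  bad <- which(!df$event_type %in% EVENT_TYPES)
  if (length(bad))
    stop_hv("unknown event_type at row(s): ", paste(bad, collapse = ", "))
  key <- paste(df$onset_sample, df$event_type)
  if (anyDuplicated(key)) {
    warning(sprintf("read_events: removed %d duplicate (onset, type) row(s)",
                    sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  event_table(df$onset_sample, df$event_type, df$condition,
              as.numeric(df$rt_ms))
}

#' Read a channel adjacency specification
#'
#' Either a two-column TSV edge list (`chan_a`, `chan_b`) or a montage
#' coordinate table (`label`, `x`, `y`\[, `z`\]) from which neighbours are
#' derived by a distance threshold (see [adjacency_from_coords()]).
#'
#' @param path TSV path.
#' @param channels channel labels (required for an edge list).
#' @return a `channel_adjacency` matrix.
#' @export
read_adjacency <- function(path, channels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (all(c("label", "x", "y") %in% names(df)))
    return(adjacency_from_coords(df))
  if (ncol(df) < 2L) stop_hv("adjacency file needs two columns")
  if (is.null(channels))
    channels <- sort(unique(c(df[[1]], df[[2]])))
  channel_adjacency(as.matrix(df[, 1:2]), channels)
}

#' Export a synthetic session to disk
#'
#' Writes `recording.edf`, `events.tsv` and `truth.json` into a directory.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edf(session$recording, file.path(dir, "recording.edf"))
  write_events(session$events, file.path(dir, "events.tsv"))
  truth <- session$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#' @param dir session directory.
#' @return list with `recording`, `events`, `truth`.
#' @export
read_session <- function(dir) {
  list(recording = read_edf(file.path(dir, "recording.edf")),
       events = read_events(file.path(dir, "events.tsv")),
       truth = if (file.exists(file.path(dir, "truth.json")))
         jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
       else NULL)
}

#' Persist an epoch set
#'
#' Epoch caches are stored as RDS (R's native serialisation); the object
#' round-trips bit-exactly.
#' @param epochs an `epoch_set`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  ep <- readRDS(path)
  stopifnot(inherits(ep, "epoch_set"))
  ep
}

serialize_cluster_result <- function(res) {
  list(
    n_perm = res$n_perm, cluster_alpha = res$cluster_alpha,
    max_abs_sum_t = res$max_abs_sum_t, seed = res$seed,
    clusters = lapply(res$clusters, function(cl) list(
      polarity = if (cl$polarity > 0) "positive" else "negative",
      sum_t = cl$sum_t,
      p_mc = cl$p_mc,
      channels = if (!is.null(res$channels))
        unique(res$channels[cl$members[, "channel"]]) else
          unique(cl$members[, "channel"]),
      time_span_ms = if (!is.null(res$time_ms))
        range(res$time_ms[cl$members[, "time"]]) else
          range(cl$members[, "time"]),
      n_samples = nrow(cl$members))))
}

#' Write a result bundle
#'
#' Serialises cluster results, surrogate nulls, equivalence outcomes and a
#' provenance block to `results.json` in `dir`. Timestamps and host
#' information are quarantined in the provenance field so the payload stays
#' byte-comparable across reruns with the same seed.
#'
#' @param bundle named list; `cluster_result` and `surrogate_null` members
#'   are serialised structurally, everything else is passed to JSON as-is.
#' @param dir output directory.
#' @param seed seed to record.
#' @param inputs character vector of input paths to digest (md5).
#' @return path of the written JSON, invisibly.
#' @export
write_results <- function(bundle, dir, seed = NULL, inputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- function(x) {
    if (inherits(x, "cluster_result")) return(serialize_cluster_result(x))
    if (inherits(x, "surrogate_null"))
      return(list(n_iter = x$n_iter, alpha_cutoff = x$alpha_cutoff,
                  max_abs_sum_t = x$max_abs_sum_t, seed = x$seed))
    if (inherits(x, "power_table")) return(x$table)
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, ser))
    x
  }
  payload <- list(
    results = lapply(bundle, ser),
    provenance = list(
      package = "hepvalid",
      version = as.character(utils::packageVersion("hepvalid")),
      seed = seed,
      input_digests = if (length(inputs))
        as.list(tools::md5sum(inputs)) else NULL,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  path <- file.path(dir, "results.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
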