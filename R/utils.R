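#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit substream seed derived from a master seed and a label.
# All randomness in the package flows through this so that a single session or
# study seed reproduces every draw bit-exactly.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(seed) * 48271 + h * 7919 + 17) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_hv <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hv(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lower || x > upper)
    stop_hv(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x))
  invisible(x)
}

ms_to_samples <- function(ms, sfreq) as.integer(round(ms * sfreq / 1000))

# Empirical level-q cutoff as an order statistic: a value is "larger than
# 100q% of the vector" iff it exceeds sorted[ceiling(q * n)]. This is the
# direct reading of the surrogate criterion and is conservative at small n,
# unlike interpolated quantiles.
empirical_cutoff <- function(x, q = 0.95) {
  sort(x)[ceiling(q * length(x))]
}

#' Indices of a time window on an epoch time axis
#'
#' Closed on both ends, matching the "within the time window" selection
#' conventions used throughout the package.
#' @param time_ms numeric time axis in ms.
#' @param window_ms length-2 numeric `c(from, to)` in ms.
#' @return integer indices.
#' @keywords internal
window_indices <- function(time_ms, window_ms) {
  stopifnot(length(window_ms) == 2L, window_ms[1] <= window_ms[2])
  idx <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  if (!length(idx)) stop_hv("window contains no samples on this time axis")
  idx
}
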