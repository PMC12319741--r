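#' Cohen's d for paired differences
#'
#' `d = mean(differences) / sd(differences)`.
#'
#' @param differences numeric vector of paired differences (n >= 2, sd > 0).
#' @return Cohen's d.
#' @export
cohens_d <- function(differences) {
  if (length(differences) < 2L || any(!is.finite(differences)))
    stop_hv("need >= 2 finite differences")
  s <- stats::sd(differences)
  if (s == 0) stop_hv("zero standard deviation: effect size undefined")
  mean(differences) / s
}

#' Hedges' g for paired differences
#'
#' Cohen's d with the small-sample bias correction
#' `J = 1 - 3 / (4 df - 1)`, `df = n - 1`.
#'
#' @inheritParams cohens_d
#' @return Hedges' g.
#' @export
hedges_g <- function(differences) {
  d <- cohens_d(differences)
  df <- length(differences) - 1
  d * (1 - 3 / (4 * df - 1))
}

#' TOST equivalence test for paired differences
#'
#' Two one-sided paired t tests against the effect bounds `+/- sesoi_g`
#' (a smallest effect size of interest on the standardised-difference scale,
#' converted to raw units via the SD of the differences). Equivalence —
#' the effect lying inside the bounds — is declared iff both one-sided tests
#' are significant at `alpha`.
#'
#' @param differences numeric vector of paired differences (n >= 3, sd > 0).
#' @param sesoi_g equivalence bound as a standardised effect (default 0.19).
#' @param alpha one-sided level (default 0.05).
#' @return list with `p_lower`, `p_upper`, `equivalent`, `t_lower`,
#'   `t_upper`, `df`, `g` (observed Hedges' g), `bound_raw`.
#' @examples
#' tost_equivalence(rnorm(200, 0, 1))
#' @export
tost_equivalence <- function(differences, sesoi_g = 0.19, alpha = 0.05) {
  n <- length(differences)
  if (n < 3L || any(!is.finite(differences)))
    stop_hv("need >= 3 finite differences")
  s <- stats::sd(differences)
  if (s == 0) stop_hv("zero standard deviation: TOST undefined")
  check_scalar(sesoi_g, "sesoi_g", lower = .Machine$double.eps)
  m <- mean(differences)
  se <- s / sqrt(n)
  delta <- sesoi_g * s
  df <- n - 1
  t_lower <- (m + delta) / se       # H0: effect <= -delta
  t_upper <- (m - delta) / se       # H0: effect >= +delta
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  list(p_lower = p_lower, p_upper = p_upper,
       equivalent = (p_lower < alpha) && (p_upper < alpha),
       t_lower = t_lower, t_upper = t_upper, df = df,
       g = hedges_g(differences), bound_raw = delta)
}
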