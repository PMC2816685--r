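# Independent numerical ground truth for the closed-form curves: the
# labeled fraction of a population with rate distribution f(p) is the
# expectation of the single-population kernel under f, evaluated here by
# adaptive quadrature or as a Monte-Carlo ensemble average. These routines
# deliberately share no algebra with the closed forms in curves.R beyond
# the single-population kernel itself.

validate_turnover_dist <- function(dist, tol_norm = 1e-8, tol_mom = 1e-6) {
  if (inherits(dist, "turnover_mixture")) {
    for (d in dist$components) validate_turnover_dist(d, tol_norm, tol_mom)
    return(invisible(TRUE))
  }
  if (dist$cont_weight > 0 && !is.null(dist$density)) {
    total <- stats::integrate(dist$density, dist$support[1], dist$support[2],
                              rel.tol = 1e-10, abs.tol = 1e-12,
                              subdivisions = 500L)$value
    if (abs(total - 1) > tol_norm)
      fail_dist(sprintf("density does not integrate to 1 (got %.10f)", total))
  }
  m <- dist_expect(dist, function(p) p)
  if (abs(m - dist$mean) > tol_mom * max(abs(dist$mean), 1e-12))
    fail_dist("stored mean does not match numeric first moment")
  v <- dist_expect(dist, function(p) p^2) - m^2
  if (abs(v - dist$var) > tol_mom * max(abs(dist$var), 1e-12))
    fail_dist("stored variance does not match numeric second moment")
  invisible(TRUE)
}

#' Labeled fraction by adaptive quadrature over a rate distribution
#'
#' Numerically evaluates the labeled-DNA fraction of a kinetically
#' heterogeneous population as the integral of the single-population
#' labeling kernel against the turnover-rate density. This is the
#' reference implementation against which the closed-form curves of
#' [label_fraction()] are validated; it works for any valid
#' [turnover_dist()].
#'
#' The continuous part of the distribution is integrated on the
#' probability scale (through the quantile function when available), which
#' retains full accuracy for singular densities such as the gamma with
#' shape below 1. Absolute tolerance is `1e-9` by default.
#'
#' @param dist a [turnover_dist()]; validated (normalization and moments)
#'   on entry.
#' @param t time(s) since start of labeling, days (vectorized).
#' @param T_label labeling duration in days, > 0.
#' @param abs.tol absolute quadrature tolerance.
#' @return Numeric vector of labeled fractions.
#' @examples
#' quadrature_label_fraction(dist_gamma(0.01, 0.5), t = 7, T_label = 7)
#' @export
quadrature_label_fraction <- function(dist, t, T_label, abs.tol = 1e-9) {
  stopifnot(inherits(dist, "turnover_dist"))
  check_times(t, T_label)
  validate_turnover_dist(dist)
  vapply(t, function(ti) {
    dist_expect(dist, function(p) label_kernel(ti, T_label, p),
                rel.tol = 1e-10, abs.tol = abs.tol / 10)
  }, 0)
}

#' Labeled fraction of a finite ensemble of subpopulations
#'
#' Equal-weight average of single-population labeling kernels over a
#' sample of turnover rates: the discrete many-subpopulation model, and a
#' Monte-Carlo estimator of [quadrature_label_fraction()] when the rates
#' are drawn from a distribution (see [sample_rates()]).
#'
#' @param rates numeric vector of per-day turnover rates, all >= 0.
#' @param t time(s) since start of labeling, days (vectorized).
#' @param T_label labeling duration in days, > 0.
#' @return Numeric vector of labeled fractions.
#' @export
ensemble_curve <- function(rates, t, T_label) {
  if (length(rates) == 0L)
    stop(errorCondition("'rates' must be non-empty",
                        class = c("invalid_input", "error", "condition")))
  if (any(!is.finite(rates)) || any(rates < 0))
    fail_param("'rates' must be finite and >= 0")
  check_times(t, T_label)
  vapply(t, function(ti) mean(label_kernel(ti, T_label, rates)), 0)
}
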