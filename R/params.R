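# Parameter containers for the labeling-curve models. Each constructor
# validates its inputs and returns a classed list; curves dispatch on the
# class via label_fraction().

fail_param <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("invalid_parameter", "error", "condition")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fail_param(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lower || (open_lower && x == lower))
    fail_param(sprintf("'%s' must be %s %g", name, if (open_lower) ">" else ">=", lower))
  if (x > upper || (open_upper && x == upper))
    fail_param(sprintf("'%s' must be %s %g", name, if (open_upper) "<" else "<=", upper))
  as.numeric(x)
}

#' Parameters of the asymptote (single-exponential) labeling model
#'
#' The classical two-parameter description of a labeling experiment: a
#' fraction `alpha` of cells turns over at per-day rate `d`, the remaining
#' `1 - alpha` does not turn over on the experimental timescale. During
#' labeling the labeled-DNA fraction saturates exponentially toward `alpha`;
#' after label cessation it decays exponentially at rate `d`. The product
#' `alpha * d` is the average turnover rate of the whole population.
#'
#' The historically distinct "source" and "kinetic heterogeneity"
#' parameterizations of labeling data are mathematically identical to this
#' model; see [fit_model()] (model ids `"source"` and `"heterogeneity"`).
#'
#' @param alpha fraction of cells turning over, in (0, 1].
#' @param d per-day turnover rate of the kinetic subpopulation, > 0.
#' @param tau delay (days, >= 0) before labeled cells appear in the
#'   sampled compartment; the whole curve is shifted by `tau`.
#' @return An object of class `c("asymptote_params", "kin_params")`.
#' @examples
#' p <- asymptote_params(alpha = 0.5, d = 0.02)
#' average_turnover(p)
#' @export
asymptote_params <- function(alpha, d, tau = 0) {
  structure(list(
    alpha = check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE),
    d     = check_scalar(d, "d", 0, Inf, open_lower = TRUE),
    tau   = check_scalar(tau, "tau", 0)
  ), class = c("asymptote_params", "kin_params"))
}

#' Parameters of the discrete multi-population labeling model
#'
#' The population is a mixture of subpopulations, each a fixed fraction
#' `alpha[i]` of the whole with constant per-day turnover rate `p[i]`. Any
#' remainder `1 - sum(alpha)` does not turn over. Rates of zero are allowed
#' (an explicit non-dividing subpopulation).
#'
#' @param alpha numeric vector of subpopulation fractions, each > 0 with
#'   `sum(alpha) <= 1`.
#' @param p numeric vector of per-day turnover rates, each >= 0, same
#'   length as `alpha`.
#' @param tau delay in days, >= 0.
#' @return An object of class `c("multipop_params", "kin_params")`.
#' @examples
#' p <- multipop_params(alpha = c(0.5, 0.0095), p = c(0.001, 1))
#' average_turnover(p)
#' @export
multipop_params <- function(alpha, p, tau = 0) {
  if (length(alpha) == 0L || length(p) == 0L)
    fail_param("at least one subpopulation is required")
  if (length(alpha) != length(p))
    fail_param("'alpha' and 'p' must have the same length")
  if (!all(is.finite(alpha)) || !all(is.finite(p)))
    fail_param("'alpha' and 'p' must be finite")
  if (any(alpha <= 0)) fail_param("all subpopulation fractions must be > 0")
  if (sum(alpha) > 1 + 1e-12) fail_param("sum(alpha) must be <= 1")
  if (any(p < 0)) fail_param("turnover rates must be >= 0")
  structure(list(
    alpha = as.numeric(alpha), p = as.numeric(p),
    tau = check_scalar(tau, "tau", 0)
  ), class = c("multipop_params", "kin_params"))
}

#' Parameters of the gamma kinetic-heterogeneity model
#'
#' Turnover rates across the (turning-over part of the) population follow a
#' gamma distribution with mean `pbar` and shape `k`; the implied rate
#' variance is `pbar^2 / k`. `k = 1` gives exponentially distributed rates;
#' `k -> Inf` recovers a kinetically homogeneous population. An optional
#' explicit asymptote `alpha < 1` leaves a fraction `1 - alpha` of cells
#' that never label.
#'
#' @param pbar mean per-day turnover rate of the turning-over cells, > 0.
#' @param k gamma shape parameter, > 0. Values below about 0.1 imply that
#'   much of the average turnover is carried by subpopulations with
#'   biologically implausible rates; see [fraction_above()].
#' @param alpha fraction of cells turning over, in (0, 1]; default 1.
#' @param tau delay in days, >= 0.
#' @return An object of class `c("gamma_params", "kin_params")`.
#' @export
gamma_params <- function(pbar, k, alpha = 1, tau = 0) {
  structure(list(
    pbar  = check_scalar(pbar, "pbar", 0, Inf, open_lower = TRUE),
    k     = check_scalar(k, "k", 0, Inf, open_lower = TRUE),
    alpha = check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE),
    tau   = check_scalar(tau, "tau", 0)
  ), class = c("gamma_params", "kin_params"))
}

#' Parameters of the exponential kinetic-heterogeneity model
#'
#' A fraction `alpha` of cells has turnover rates that are exponentially
#' distributed with mean `pbar_sub`; the rest undergo negligible turnover.
#' With `alpha = 1` a single parameter governs both uplabeling and
#' delabeling and the labeled fraction saturates at 100%. The whole-
#' population average turnover rate is `alpha * pbar_sub`.
#'
#' @param pbar_sub mean per-day turnover rate of the turning-over
#'   fraction, > 0.
#' @param alpha fraction of cells turning over, in (0, 1]; default 1.
#' @param tau delay in days, >= 0.
#' @return An object of class `c("exponential_params", "kin_params")`.
#' @export
exponential_params <- function(pbar_sub, alpha = 1, tau = 0) {
  structure(list(
    pbar_sub = check_scalar(pbar_sub, "pbar_sub", 0, Inf, open_lower = TRUE),
    alpha    = check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE),
    tau      = check_scalar(tau, "tau", 0)
  ), class = c("exponential_params", "kin_params"))
}

#' Parameters of the truncated-gamma kinetic-heterogeneity model
#'
#' As [gamma_params()], but the rate distribution is restricted to
#' `[0, pmax]` and renormalized, excluding biologically implausible very
#' fast subpopulations. The reported average turnover is the mean of the
#' truncated density, which is below `pbar`. As `pmax -> Inf` the model
#' converges to the untruncated gamma model.
#'
#' @param pbar mean of the untruncated gamma distribution, > 0.
#' @param k gamma shape parameter, > 0.
#' @param pmax per-day truncation bound, > 0.
#' @param tau delay in days, >= 0.
#' @return An object of class `c("trunc_gamma_params", "kin_params")`.
#' @export
trunc_gamma_params <- function(pbar, k, pmax, tau = 0) {
  structure(list(
    pbar = check_scalar(pbar, "pbar", 0, Inf, open_lower = TRUE),
    k    = check_scalar(k, "k", 0, Inf, open_lower = TRUE),
    pmax = check_scalar(pmax, "pmax", 0, Inf, open_lower = TRUE),
    tau  = check_scalar(tau, "tau", 0)
  ), class = c("trunc_gamma_params", "kin_params"))
}

#' @export
print.kin_params <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  flat <- vapply(x, function(v) paste(signif(v, 6), collapse = ", "), "")
  for (nm in names(flat)) cat(" ", nm, "=", flat[[nm]], "\n")
  cat("  average turnover:", signif(average_turnover(x), 6), "/day\n")
  invisible(x)
}

#' Average turnover rate of a parameterized population
#'
#' The population mean of per-capita turnover rates, weighted by
#' subpopulation fractions: `alpha * d` for the asymptote model,
#' `sum(alpha_i * p_i)` for the multi-population model, `alpha * pbar`
#' (resp. `alpha * pbar_sub`) for the gamma and exponential heterogeneity
#' models, and the mean of the truncated density for the truncated-gamma
#' model. This rate equals the initial slope of the labeling curve and is
#' the key quantity estimated from labeling data.
#'
#' @param params a `kin_params` object.
#' @return Average per-day turnover rate of the whole population.
#' @export
average_turnover <- function(params) UseMethod("average_turnover")

#' @export
average_turnover.asymptote_params <- function(params) params$alpha * params$d

#' @export
average_turnover.multipop_params <- function(params) sum(params$alpha * params$p)

#' @export
average_turnover.gamma_params <- function(params) params$alpha * params$pbar

#' @export
average_turnover.exponential_params <- function(params) params$alpha * params$pbar_sub

#' @export
average_turnover.trunc_gamma_params <- function(params) {
  # mean of the gamma density restricted to [0, pmax]:
  # pbar * P(pmax; k+1, r) / P(pmax; k, r) with rate r = k / pbar
  r <- params$k / params$pbar
  params$pbar * stats::pgamma(params$pmax, params$k + 1, rate = r) /
    stats::pgamma(params$pmax, params$k, rate = r)
}

#' Initial uplabeling rate of a labeling curve
#'
#' The right-derivative of the labeled-DNA fraction at `t = 0` (delay
#' ignored for this limit). For every model in the package this equals the
#' average turnover rate of the population, which is why the early labeling
#' slope identifies average turnover regardless of the assumed rate
#' distribution.
#'
#' @inheritParams average_turnover
#' @return Per-day initial slope of the labeling curve.
#' @seealso [average_turnover()]
#' @export
initial_uplabeling_rate <- function(params) {
  stopifnot(inherits(params, "kin_params"))
  average_turnover(params)
}
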