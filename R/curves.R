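# Closed-form labeling/delabeling curves. All models share the single-
# population kernel: a subpopulation with rate p labels as 1 - exp(-p t)
# while label is administered and loses label as exp(-p (t - T)) afterwards.
# Written in the unified form exp(-p * max(t - T, 0)) - exp(-p t), which is
# continuous at t = T by construction.

label_kernel <- function(t, T_label, p) {
  exp(-p * pmax(t - T_label, 0)) - exp(-p * t)
}

# Delay convention: the whole curve is shifted, L(t) = L0(max(t - tau, 0)),
# with the labeling/delabeling switch at shifted time T_label. Isolated here
# so an alternative convention (e.g. delay on uplabeling only) could be
# swapped in one place.
shift_delay <- function(t, tau) pmax(t - tau, 0)

check_times <- function(t, T_label) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    fail_param("'t' must be finite and >= 0")
  check_scalar(T_label, "T_label", 0, Inf, open_lower = TRUE)
}

#' Fraction of labeled DNA predicted by a labeling model
#'
#' Evaluates the closed-form labeled-DNA fraction L(t) for a labeling
#' experiment in which label is administered from time 0 to `T_label` days.
#' The model is selected by the class of `params`; see
#' [asymptote_params()], [multipop_params()], [gamma_params()],
#' [exponential_params()] and [trunc_gamma_params()].
#'
#' All curves are 0 for `t <= tau`, rise monotonically during labeling,
#' decline monotonically after label cessation, are continuous at
#' `t = tau + T_label`, and stay in `[0, 1]`.
#'
#' @param params a `kin_params` object.
#' @param t time(s) since start of labeling, in days (vectorized).
#' @param T_label duration of the labeling period in days, > 0.
#' @return Numeric vector of labeled-DNA fractions in `[0, 1]`.
#' @examples
#' label_fraction(asymptote_params(0.5, 0.02), t = c(7, 14), T_label = 7)
#' label_fraction(gamma_params(pbar = 0.01, k = 0.5), t = 0:50, T_label = 7)
#' @export
label_fraction <- function(params, t, T_label) UseMethod("label_fraction")

#' @export
label_fraction.asymptote_params <- function(params, t, T_label) {
  check_times(t, T_label)
  te <- shift_delay(t, params$tau)
  params$alpha * label_kernel(te, T_label, params$d)
}

#' @export
label_fraction.multipop_params <- function(params, t, T_label) {
  check_times(t, T_label)
  te <- shift_delay(t, params$tau)
  out <- numeric(length(te))
  for (i in seq_along(params$p))
    out <- out + params$alpha[i] * label_kernel(te, T_label, params$p[i])
  out
}

# (1 + pbar * t / k)^(-k), computed as exp(-k * log1p(.)) so the k -> Inf
# homogeneous limit exp(-pbar * t) is reached without overflow or
# cancellation.
gamma_survival <- function(t, pbar, k) {
  exp(-k * log1p(pbar * t / k))
}

#' @export
label_fraction.gamma_params <- function(params, t, T_label) {
  check_times(t, T_label)
  te <- shift_delay(t, params$tau)
  params$alpha * (gamma_survival(pmax(te - T_label, 0), params$pbar, params$k) -
                    gamma_survival(te, params$pbar, params$k))
}

#' @export
label_fraction.exponential_params <- function(params, t, T_label) {
  check_times(t, T_label)
  te <- shift_delay(t, params$tau)
  surv <- function(x) 1 / (1 + params$pbar_sub * x)
  params$alpha * (surv(pmax(te - T_label, 0)) - surv(te))
}

#' @export
label_fraction.trunc_gamma_params <- function(params, t, T_label) {
  check_times(t, T_label)
  te <- shift_delay(t, params$tau)
  r <- params$k / params$pbar
  z <- stats::pgamma(params$pmax, params$k, rate = r)
  # E[exp(-p s)] under the truncated, renormalized gamma density:
  # (r / (r + s))^k * P(pmax; k, r + s) / P(pmax; k, r)
  surv <- function(s) {
    exp(params$k * (log(r) - log(r + s))) *
      stats::pgamma(params$pmax, params$k, rate = r + s) / z
  }
  surv(pmax(te - T_label, 0)) - surv(te)
}
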