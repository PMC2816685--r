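# Model selection for nested and non-nested labeling fits.

fail_compare <- function(msg) {
  stop(errorCondition(msg, class = c("invalid_comparison", "error", "condition")))
}

#' Partial F-test for nested labeling fits
#'
#' Compares a restricted fit (some parameters fixed or shared) with a full
#' fit of the same data on the same residual scale:
#' `F = ((rss_r - rss_f) / (df_r - df_f)) / (rss_f / df_f)`, with the
#' p-value from the F distribution. Used to search for the minimal number
#' of parameters that describe a set of labeling curves.
#'
#' @param restricted,full `labeling_fit` objects on the same datasets and
#'   transform; `restricted` must have fewer free parameters, and its RSS
#'   may not be below the full model's (beyond tolerance `1e-10`).
#' @return An object of class `htest` with the F statistic, numerator and
#'   denominator degrees of freedom, and p-value.
#' @export
f_test_nested <- function(restricted, full) {
  stopifnot(inherits(restricted, "labeling_fit"), inherits(full, "labeling_fit"))
  if (restricted$n_obs != full$n_obs)
    fail_compare("fits are not on the same observations")
  if (restricted$transform != full$transform)
    fail_compare("fits use different residual transforms")
  if (restricted$n_params >= full$n_params)
    fail_compare("the restricted model must have fewer free parameters")
  if (restricted$rss < full$rss - 1e-10)
    fail_compare("restricted RSS is below the full model's; fits are not nested")
  df1 <- restricted$df - full$df
  df2 <- full$df
  if (df2 <= 0) fail_compare("full model has no residual degrees of freedom")
  Fstat <- max((restricted$rss - full$rss), 0) / df1 / (full$rss / df2)
  structure(list(statistic = c(F = Fstat),
                 parameter = c(num.df = df1, den.df = df2),
                 p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 method = "Partial F-test for nested labeling models",
                 data.name = sprintf("%s (restricted) vs %s (full)",
                                     restricted$model, full$model)),
            class = "htest")
}

#' Akaike Information Criterion for a labeling fit
#'
#' Gaussian least-squares AIC, `n * log(rss / n) + 2 * k`, where `rss` is
#' the residual sum of squares on the transformed scale, `n` the number of
#' observations and `k` the number of free parameters. Lower is better;
#' only differences between fits of the same data are meaningful.
#'
#' @param fit a `labeling_fit`.
#' @return The AIC score.
#' @seealso [aicc()] for the small-sample corrected variant.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "labeling_fit"))
  fit$n_obs * log(fit$rss / fit$n_obs) + 2 * fit$n_params
}

#' Small-sample corrected AIC
#'
#' `aic(fit) + 2k(k+1) / (n - k - 1)`; preferable when the number of
#' observations per parameter is small, as in typical labeling time
#' courses.
#'
#' @inheritParams aic
#' @return The AICc score (infinite when `n <= k + 1`).
#' @export
aicc <- function(fit) {
  k <- fit$n_params; n <- fit$n_obs
  if (n <= k + 1) return(Inf)
  aic(fit) + 2 * k * (k + 1) / (n - k - 1)
}
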