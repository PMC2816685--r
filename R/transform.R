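# Variance stabilization for proportion data. Residuals are always formed
# on the transformed scale, applied identically to data and predictions.

transforms <- list(
  asinsqrt = list(fwd = function(f) asin(sqrt(f)),
                  inv = function(y) sin(pmin(pmax(y, 0), pi / 2))^2),
  identity = list(fwd = function(f) f,
                  inv = function(y) pmin(pmax(y, 0), 1)),
  logit    = list(fwd = function(f) stats::qlogis(f),
                  inv = function(y) stats::plogis(y))
)

#' Variance-stabilizing transform for labeled fractions
#'
#' Transforms a fraction in `[0, 1]` before residuals are formed, so that
#' measurement noise on proportions is closer to homoscedastic. The
#' default is the arcsine-square-root transform,
#' `g(f) = asin(sqrt(f))`, the standard variance stabilizer for
#' proportions; `"identity"` and `"logit"` are available alternatives
#' (note the logit is unbounded at 0 and 1).
#'
#' @param f numeric vector of fractions in `[0, 1]`.
#' @param method one of `"asinsqrt"`, `"identity"`, `"logit"`.
#' @return Transformed values; strictly increasing in `f`.
#' @examples
#' transform_fraction(c(0, 0.25, 1))  # 0, pi/6, pi/2
#' @export
transform_fraction <- function(f, method = "asinsqrt") {
  method <- match.arg(method, names(transforms))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop(errorCondition("'f' must lie in [0, 1]",
                        class = c("invalid_input", "error", "condition")))
  transforms[[method]]$fwd(f)
}

#' Inverse of [transform_fraction()]
#'
#' Back-transforms values to the fraction scale, clipping to the range of
#' the forward transform so that bootstrap-perturbed values remain valid
#' fractions.
#'
#' @param y numeric vector on the transformed scale.
#' @param method one of `"asinsqrt"`, `"identity"`, `"logit"`.
#' @return Fractions in `[0, 1]`.
#' @export
inverse_transform_fraction <- function(y, method = "asinsqrt") {
  method <- match.arg(method, names(transforms))
  transforms[[method]]$inv(y)
}
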