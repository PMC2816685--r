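# Turnover-rate distributions. A turnover_dist describes the frequency
# distribution of per-day turnover rates across subpopulations: a continuous
# part (density/cdf/quantile, carrying weight cont_weight) plus optional
# point masses (atoms), e.g. a non-dividing fraction at rate 0.

fail_dist <- function(msg) {
  stop(errorCondition(msg, class = c("invalid_distribution", "error", "condition")))
}

#' Construct a turnover-rate distribution
#'
#' Low-level constructor for a probability distribution over per-day
#' turnover rates, consisting of a continuous component (weight
#' `cont_weight`) and optional point masses (`atoms`). Most users should
#' use the ready-made constructors [dist_gamma()], [dist_exponential()],
#' [dist_trunc_gamma()], [dist_point()] or [dist_mixture()], or derive a
#' distribution from model parameters with [as_turnover_dist()].
#'
#' @param mean mean per-day turnover rate of the whole distribution.
#' @param var variance of the whole distribution.
#' @param density vectorized density of the continuous component
#'   (normalized to integrate to 1 over `support`), or `NULL` if the
#'   distribution is purely atomic.
#' @param cdf vectorized CDF of the continuous component.
#' @param sf vectorized survival function (upper tail) of the continuous
#'   component; defaults to `1 - cdf(p)` but should be supplied when far
#'   tails matter.
#' @param quantile vectorized quantile function of the continuous
#'   component; used for accurate quadrature and inverse-CDF sampling.
#' @param sampler function of `n` drawing from the continuous component.
#' @param support numeric length-2 support of the continuous component;
#'   the upper end may be `Inf`.
#' @param atoms `data.frame` with columns `p` (rate) and `w` (weight), or
#'   `NULL`.
#' @param cont_weight weight of the continuous component; atom weights
#'   must sum to `1 - cont_weight`.
#' @param label short human-readable description.
#' @return An object of class `turnover_dist`.
#' @export
turnover_dist <- function(mean, var, density = NULL, cdf = NULL, quantile = NULL,
                          sf = NULL, sampler = NULL, support = c(0, Inf), atoms = NULL,
                          cont_weight = if (is.null(atoms)) 1 else 1 - sum(atoms$w),
                          label = "custom") {
  if (!is.null(atoms)) {
    stopifnot(is.data.frame(atoms), all(c("p", "w") %in% names(atoms)))
    if (any(atoms$p < 0) || any(atoms$w < 0)) fail_dist("atoms must have p >= 0, w >= 0")
  }
  w_atoms <- if (is.null(atoms)) 0 else sum(atoms$w)
  if (abs(w_atoms + cont_weight - 1) > 1e-10)
    fail_dist("atom weights plus cont_weight must sum to 1")
  if (cont_weight > 0 && is.null(density) && is.null(quantile))
    fail_dist("a continuous component needs a density or a quantile function")
  if (is.null(sf) && !is.null(cdf)) sf <- function(p) 1 - cdf(p)
  structure(list(mean = mean, var = var, density = density, cdf = cdf,
                 quantile = quantile, sf = sf, sampler = sampler,
                 support = as.numeric(support), atoms = atoms,
                 cont_weight = cont_weight, label = label),
            class = "turnover_dist")
}

#' @export
print.turnover_dist <- function(x, ...) {
  cat("<turnover_dist>", x$label, "\n")
  cat("  mean:", signif(x$mean, 6), "/day  variance:", signif(x$var, 6), "\n")
  if (!is.null(x$atoms))
    cat("  atoms at p =", paste(signif(x$atoms$p, 4), collapse = ", "),
        " (weights", paste(signif(x$atoms$w, 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Gamma distribution of turnover rates
#'
#' @param pbar mean per-day rate, > 0.
#' @param k shape parameter, > 0 (`k = 1` is the exponential
#'   distribution; large `k` approaches a homogeneous population).
#' @return A `turnover_dist`.
#' @export
dist_gamma <- function(pbar, k) {
  pbar <- check_scalar(pbar, "pbar", 0, Inf, open_lower = TRUE)
  k <- check_scalar(k, "k", 0, Inf, open_lower = TRUE)
  r <- k / pbar
  turnover_dist(
    mean = pbar, var = pbar^2 / k,
    density = function(p) stats::dgamma(p, shape = k, rate = r),
    cdf = function(p) stats::pgamma(p, shape = k, rate = r),
    sf = function(p) stats::pgamma(p, shape = k, rate = r, lower.tail = FALSE),
    quantile = function(u) stats::qgamma(u, shape = k, rate = r),
    sampler = function(n) stats::rgamma(n, shape = k, rate = r),
    support = c(0, Inf),
    label = sprintf("gamma(pbar=%g, k=%g)", pbar, k)
  )
}

#' Exponential distribution of turnover rates
#'
#' @param pbar mean per-day rate, > 0.
#' @return A `turnover_dist` (gamma with shape 1).
#' @export
dist_exponential <- function(pbar) {
  d <- dist_gamma(pbar, 1)
  d$label <- sprintf("exponential(pbar=%g)", pbar)
  d
}

#' Truncated gamma distribution of turnover rates
#'
#' Gamma density restricted to `[0, pmax]` and renormalized. The stored
#' `mean` and `var` are those of the truncated density.
#'
#' @param pbar mean of the untruncated gamma, > 0.
#' @param k shape, > 0.
#' @param pmax truncation bound in per-day rate, > 0.
#' @return A `turnover_dist`.
#' @export
dist_trunc_gamma <- function(pbar, k, pmax) {
  pbar <- check_scalar(pbar, "pbar", 0, Inf, open_lower = TRUE)
  k <- check_scalar(k, "k", 0, Inf, open_lower = TRUE)
  pmax_ <- check_scalar(pmax, "pmax", 0, Inf, open_lower = TRUE)
  r <- k / pbar
  z <- stats::pgamma(pmax_, k, rate = r)
  if (z <= 0) fail_dist("truncation bound leaves no probability mass")
  m1 <- pbar * stats::pgamma(pmax_, k + 1, rate = r) / z
  m2 <- pbar^2 * (k + 1) / k * stats::pgamma(pmax_, k + 2, rate = r) / z
  turnover_dist(
    mean = m1, var = m2 - m1^2,
    density = function(p) ifelse(p <= pmax_, stats::dgamma(p, k, rate = r) / z, 0),
    cdf = function(p) pmin(stats::pgamma(p, k, rate = r) / z, 1),
    sf = function(p) pmax(1 - stats::pgamma(p, k, rate = r) / z, 0),
    quantile = function(u) stats::qgamma(u * z, k, rate = r),
    sampler = function(n) stats::qgamma(stats::runif(n) * z, k, rate = r),
    support = c(0, pmax_),
    label = sprintf("truncated gamma(pbar=%g, k=%g, pmax=%g)", pbar, k, pmax_)
  )
}

#' Point-mass (homogeneous population) turnover distribution
#'
#' @param p the single per-day turnover rate, >= 0.
#' @return A `turnover_dist` with zero variance.
#' @export
dist_point <- function(p) {
  p <- check_scalar(p, "p", 0)
  turnover_dist(mean = p, var = 0, atoms = data.frame(p = p, w = 1),
                cont_weight = 0, label = sprintf("point mass at %g", p))
}

#' Mixture of turnover-rate distributions
#'
#' @param components list of `turnover_dist` objects.
#' @param weights mixture weights, summing to 1.
#' @return A `turnover_dist` of class `c("turnover_mixture", "turnover_dist")`.
#' @examples
#' # half the cells non-dividing, half with exponentially distributed rates:
#' dist_mixture(list(dist_point(0), dist_exponential(0.02)), c(0.5, 0.5))
#' @export
dist_mixture <- function(components, weights) {
  stopifnot(is.list(components), all(vapply(components, inherits, TRUE, "turnover_dist")))
  if (length(weights) != length(components) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-10)
    fail_dist("weights must be non-negative and sum to 1")
  m <- sum(weights * vapply(components, `[[`, 0, "mean"))
  e2 <- sum(weights * vapply(components, function(d) d$var + d$mean^2, 0))
  structure(list(mean = m, var = e2 - m^2, components = components,
                 weights = as.numeric(weights),
                 label = "mixture"),
            class = c("turnover_mixture", "turnover_dist"))
}

# ---- expectations -----------------------------------------------------------

# Integrate fun over [lo, hi] on the probability scale, splitting the
# interval into panels crowded toward both ends. Heavily truncated
# distributions concentrate a wide range of rates into a sliver of
# probability just below 1, and singular densities (gamma shape < 1) put
# integrand boundary layers just above 0; panelizing keeps the adaptive
# rule from stepping over either layer.
quad_prob <- function(fun, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12) {
  frac <- c(0, 1e-8, 1e-6, 1e-4, 0.01, 0.1, 0.5,
            0.9, 0.99, 0.9999, 0.999999, 1)
  pts <- lo + (hi - lo) * frac
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    total <- total + stats::integrate(fun, pts[i], pts[i + 1L],
                                      rel.tol = rel.tol,
                                      abs.tol = abs.tol / (length(pts) - 1L),
                                      subdivisions = 500L)$value
  }
  total
}

# E[g(p)] under the distribution. g must be vectorized. The continuous part
# is integrated over the probability scale (u -> g(quantile(u))) when a
# quantile function is available, which keeps quadrature accurate even for
# densities with an integrable singularity at 0 (gamma with k < 1);
# otherwise the density is integrated over its support.
dist_expect <- function(dist, g, rel.tol = 1e-10, abs.tol = 1e-12) {
  UseMethod("dist_expect")
}

#' @export
dist_expect.turnover_dist <- function(dist, g, rel.tol = 1e-10, abs.tol = 1e-12) {
  out <- 0
  if (!is.null(dist$atoms) && nrow(dist$atoms) > 0)
    out <- out + sum(dist$atoms$w * g(dist$atoms$p))
  if (dist$cont_weight > 0) {
    if (!is.null(dist$quantile)) {
      # clamp u away from 1 where quantiles of unbounded supports diverge;
      # the excluded probability mass is below machine precision
      v <- quad_prob(function(u) g(dist$quantile(pmin(u, 1 - 1e-16))), 0, 1,
                     rel.tol = rel.tol, abs.tol = abs.tol)
    } else {
      v <- stats::integrate(function(p) g(p) * dist$density(p),
                            dist$support[1], dist$support[2],
                            rel.tol = rel.tol, abs.tol = abs.tol,
                            subdivisions = 500L)$value
    }
    out <- out + dist$cont_weight * v
  }
  out
}

#' @export
dist_expect.turnover_mixture <- function(dist, g, rel.tol = 1e-10, abs.tol = 1e-12) {
  sum(dist$weights * vapply(dist$components, dist_expect, 0, g = g,
                            rel.tol = rel.tol, abs.tol = abs.tol))
}

# lower partial moment: E[p * 1{p <= p0}], via the probability transform
# int_0^{F(p0)} quantile(u) du for the continuous part.
partial_mean <- function(dist, p0) UseMethod("partial_mean")

#' @export
partial_mean.turnover_dist <- function(dist, p0) {
  out <- 0
  if (!is.null(dist$atoms) && nrow(dist$atoms) > 0) {
    sel <- dist$atoms$p <= p0
    out <- out + sum(dist$atoms$w[sel] * dist$atoms$p[sel])
  }
  if (dist$cont_weight > 0) {
    if (is.null(dist$cdf)) fail_dist("continuous component needs a cdf")
    u0 <- dist$cdf(p0)
    if (u0 > 0) {
      if (!is.null(dist$quantile)) {
        v <- quad_prob(function(u) dist$quantile(pmin(u, 1 - 1e-16)), 0, u0,
                       rel.tol = 1e-10, abs.tol = 1e-13)
      } else {
        v <- stats::integrate(function(p) p * dist$density(p),
                              dist$support[1], min(p0, dist$support[2]),
                              rel.tol = 1e-10, abs.tol = 1e-13,
                              subdivisions = 500L)$value
      }
      out <- out + dist$cont_weight * v
    }
  }
  out
}

#' @export
partial_mean.turnover_mixture <- function(dist, p0) {
  sum(dist$weights * vapply(dist$components, partial_mean, 0, p0 = p0))
}

upper_tail <- function(dist, p0) UseMethod("upper_tail")

#' @export
upper_tail.turnover_dist <- function(dist, p0) {
  out <- 0
  if (!is.null(dist$atoms) && nrow(dist$atoms) > 0)
    out <- out + sum(dist$atoms$w[dist$atoms$p > p0])
  if (dist$cont_weight > 0) {
    if (is.null(dist$sf)) fail_dist("continuous component needs a cdf")
    out <- out + dist$cont_weight * dist$sf(p0)
  }
  out
}

#' @export
upper_tail.turnover_mixture <- function(dist, p0) {
  sum(dist$weights * vapply(dist$components, upper_tail, 0, p0 = p0))
}

# ---- derived kinetic quantities --------------------------------------------

#' Per-capita initial delabeling rate after label cessation
#'
#' The rate `-(dL/dt) / L` evaluated just after the end of a labeling
#' period of duration `T_label`, for a population whose turnover rates
#' follow `dist`. In a kinetically heterogeneous population this rate
#' depends on the labeling duration: after a very short labeling period it
#' approaches `mean + var/mean` (rapidly turning-over subpopulations are
#' over-represented among labeled cells), while after a very long labeling
#' period it approaches the population mean. For exponentially distributed
#' rates (`var = mean^2`) the short-labeling rate is exactly twice the
#' long-labeling rate.
#'
#' @param dist a [turnover_dist()].
#' @param T_label labeling duration in days, > 0.
#' @return Per-capita per-day rate of loss of labeled DNA at
#'   `t = T_label+`.
#' @examples
#' d <- dist_exponential(0.01)
#' initial_delabeling_rate(d, 1e-8) / initial_delabeling_rate(d, 1e8)  # ~2
#' @export
initial_delabeling_rate <- function(dist, T_label) {
  stopifnot(inherits(dist, "turnover_dist"))
  T_label <- check_scalar(T_label, "T_label", 0, Inf, open_lower = TRUE)
  if (!is.finite(dist$mean) || dist$mean <= 0)
    fail_param("distribution must have a positive mean turnover rate")
  # L(T) = E[1 - exp(-p T)], -L'(T+) = E[p (1 - exp(-p T))]; both integrands
  # are scaled by 1/T so the short-labeling limit stays well-conditioned,
  # and the absolute tolerance is kept far below the integrand scale so
  # extreme labeling durations remain accurate.
  atol <- 1e-12 * min(1, 1 / T_label)
  num <- dist_expect(dist, function(p) p * (-expm1(-p * T_label)) / T_label,
                     rel.tol = 1e-10, abs.tol = atol)
  den <- dist_expect(dist, function(p) (-expm1(-p * T_label)) / T_label,
                     rel.tol = 1e-10, abs.tol = atol)
  num / den
}

#' Cumulative contribution of slow subpopulations to average turnover
#'
#' The fraction of the population's average turnover rate contributed by
#' subpopulations with turnover rates at most `p`:
#' `(1/mean) * integral_0^p x f(x) dx`. Non-decreasing in `p`, reaching 1
#' as `p -> Inf`. For skewed rate distributions (gamma shape well below 1)
#' most of the average turnover is carried by rare, very fast
#' subpopulations, which is the basis of the biological-plausibility screen
#' on the gamma shape parameter.
#'
#' @inheritParams initial_delabeling_rate
#' @param p per-day rate threshold(s), >= 0 (vectorized).
#' @return Cumulative contribution(s) in `[0, 1]`.
#' @export
contribution_cdf <- function(dist, p) {
  stopifnot(inherits(dist, "turnover_dist"))
  if (any(p < 0)) fail_param("'p' must be >= 0")
  if (dist$mean <= 0) fail_param("distribution must have a positive mean")
  vapply(p, function(pi) partial_mean(dist, pi), 0) / dist$mean
}

#' Fraction of cells with turnover rate above a threshold
#'
#' Upper-tail probability of the turnover-rate distribution. Used to screen
#' fitted rate distributions for biological plausibility: if an appreciable
#' fraction of cells would need to turn over faster than about 1/day, the
#' fitted distribution should be viewed with suspicion (for the gamma
#' model this corresponds to the rule of thumb that the shape parameter
#' should exceed 0.1).
#'
#' @inheritParams initial_delabeling_rate
#' @param p0 per-day rate threshold(s), >= 0 (vectorized).
#' @return Probability(ies) in `[0, 1]`.
#' @export
fraction_above <- function(dist, p0) {
  stopifnot(inherits(dist, "turnover_dist"))
  if (any(p0 < 0)) fail_param("'p0' must be >= 0")
  vapply(p0, function(pi) upper_tail(dist, pi), 0)
}

#' Draw turnover rates from a distribution
#'
#' @inheritParams initial_delabeling_rate
#' @param n number of draws.
#' @param seed optional integer; when supplied, sampling is performed
#'   under a local RNG state so the caller's random stream is untouched.
#' @return Numeric vector of `n` per-day rates.
#' @export
sample_rates <- function(dist, n, seed = NULL) {
  draw <- function() {
    if (inherits(dist, "turnover_mixture")) {
      idx <- sample.int(length(dist$components), n, replace = TRUE,
                        prob = dist$weights)
      out <- numeric(n)
      for (j in unique(idx)) {
        nj <- sum(idx == j)
        out[idx == j] <- sample_rates(dist$components[[j]], nj)
      }
      return(out)
    }
    n_cont <- stats::rbinom(1, n, dist$cont_weight)
    out <- numeric(0)
    if (n_cont > 0) {
      if (!is.null(dist$sampler)) out <- dist$sampler(n_cont)
      else if (!is.null(dist$quantile)) out <- dist$quantile(stats::runif(n_cont))
      else fail_dist("continuous component has no sampler or quantile function")
    }
    if (n_cont < n) {
      idx <- sample.int(nrow(dist$atoms), n - n_cont, replace = TRUE,
                        prob = dist$atoms$w / sum(dist$atoms$w))
      out <- c(out, dist$atoms$p[idx])
    }
    sample(out)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Turnover-rate distribution implied by model parameters
#'
#' Maps a `kin_params` object to the [turnover_dist()] it implies: the
#' asymptote model becomes a two-atom distribution (rate `d` with weight
#' `alpha`, rate 0 with weight `1 - alpha`), the multi-population model a
#' discrete distribution with an explicit non-turning-over remainder, and
#' the continuous heterogeneity models their respective densities (with an
#' atom at 0 when `alpha < 1`).
#'
#' @param params a `kin_params` object.
#' @return A `turnover_dist` whose mean equals
#'   `average_turnover(params)`.
#' @export
as_turnover_dist <- function(params) UseMethod("as_turnover_dist")

#' @export
as_turnover_dist.asymptote_params <- function(params) {
  as_turnover_dist(multipop_params(alpha = params$alpha, p = params$d,
                                   tau = params$tau))
}

#' @export
as_turnover_dist.multipop_params <- function(params) {
  p <- params$p; w <- params$alpha
  rest <- 1 - sum(w)
  if (rest > 1e-12) { p <- c(p, 0); w <- c(w, rest) }
  atoms <- stats::aggregate(w ~ p, data.frame(p = p, w = w), sum)
  m <- sum(atoms$w * atoms$p)
  turnover_dist(mean = m, var = sum(atoms$w * atoms$p^2) - m^2,
                atoms = atoms, cont_weight = 0, label = "discrete")
}

#' @export
as_turnover_dist.gamma_params <- function(params) {
  base <- dist_gamma(params$pbar, params$k)
  if (params$alpha == 1) return(base)
  dist_mixture(list(dist_point(0), base), c(1 - params$alpha, params$alpha))
}

#' @export
as_turnover_dist.exponential_params <- function(params) {
  base <- dist_exponential(params$pbar_sub)
  if (params$alpha == 1) return(base)
  dist_mixture(list(dist_point(0), base), c(1 - params$alpha, params$alpha))
}

#' @export
as_turnover_dist.trunc_gamma_params <- function(params) {
  dist_trunc_gamma(params$pbar, params$k, params$pmax)
}
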