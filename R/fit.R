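# Least-squares fitting of labeling curves on a variance-stabilized scale,
# with box bounds, multi-start optimization, parameter fixing and sharing
# across subjects.

`%||%` <- function(a, b) if (is.null(a)) b else a

fail_fit <- function(msg) {
  stop(errorCondition(msg, class = c("fit_failure", "error", "condition")))
}

# ---- model registry ---------------------------------------------------------

par_row <- function(name, lower, upper, log, default)
  data.frame(name = name, lower = lower, upper = upper, log = log,
             default = default, stringsAsFactors = FALSE)

# Default bounds: rates in (1e-6, 10] /day, gamma shape in (1e-3, 1e3],
# fractions in (0, 1], delay in [0, 5] days. Rate-like and shape parameters
# are optimized and multi-started on the log scale.
kin_model_def <- function(model) {
  switch(model,
    asymptote = list(
      id = "asymptote",
      pars = rbind(par_row("alpha", 1e-6, 1, FALSE, 0.5),
                   par_row("d", 1e-6, 10, TRUE, 0.01),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) asymptote_params(v[["alpha"]], v[["d"]], v[["tau"]]),
      penalty = function(v) 0),
    # Mohri-style "source" parameterization of the same curve: a homogeneous
    # population with death rate d and a source producing unlabeled cells;
    # u is the unlabeled-source fraction, so the asymptote is 1 - u.
    source = list(
      id = "source",
      pars = rbind(par_row("u", 1e-6, 1 - 1e-6, FALSE, 0.5),
                   par_row("d", 1e-6, 10, TRUE, 0.01),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) asymptote_params(1 - v[["u"]], v[["d"]], v[["tau"]]),
      penalty = function(v) 0),
    # Asquith-style "heterogeneity" parameterization: average turnover pavg
    # plus the excess of the labeled-cell death rate over it; the asymptote
    # is pavg / (pavg + excess).
    heterogeneity = list(
      id = "heterogeneity",
      pars = rbind(par_row("pavg", 1e-6, 10, TRUE, 0.01),
                   par_row("excess", 0, 10, FALSE, 0.01),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) {
        d <- v[["pavg"]] + v[["excess"]]
        asymptote_params(v[["pavg"]] / d, d, v[["tau"]])
      },
      penalty = function(v) 0),
    gamma = list(
      id = "gamma",
      pars = rbind(par_row("pbar", 1e-6, 10, TRUE, 0.01),
                   par_row("k", 1e-3, 1e3, TRUE, 1),
                   par_row("alpha", 1e-6, 1, FALSE, 1),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(alpha = 1, tau = 0),
      make = function(v) gamma_params(v[["pbar"]], v[["k"]], v[["alpha"]], v[["tau"]]),
      penalty = function(v) 0),
    exponential = list(
      id = "exponential",
      pars = rbind(par_row("pbar_sub", 1e-6, 10, TRUE, 0.01),
                   par_row("alpha", 1e-6, 1, FALSE, 0.5),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) exponential_params(v[["pbar_sub"]], v[["alpha"]], v[["tau"]]),
      penalty = function(v) 0),
    twopop = list(
      id = "twopop",
      pars = rbind(par_row("alpha1", 1e-6, 1, FALSE, 0.4),
                   par_row("p1", 1e-6, 10, TRUE, 0.005),
                   par_row("alpha2", 1e-6, 1, FALSE, 0.1),
                   par_row("p2", 1e-6, 10, TRUE, 0.5),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) {
        a <- c(v[["alpha1"]], v[["alpha2"]])
        if (sum(a) > 1) a <- a / sum(a)  # infeasible points are penalized
        multipop_params(a, c(v[["p1"]], v[["p2"]]), v[["tau"]])
      },
      penalty = function(v) 1e4 * max(v[["alpha1"]] + v[["alpha2"]] - 1, 0)^2),
    trunc_gamma = list(
      id = "trunc_gamma",
      pars = rbind(par_row("pbar", 1e-6, 10, TRUE, 0.01),
                   par_row("k", 1e-3, 1e3, TRUE, 1),
                   par_row("pmax", 1e-3, 1e3, TRUE, 1),
                   par_row("tau", 0, 5, FALSE, 0)),
      default_fixed = list(tau = 0),
      make = function(v) trunc_gamma_params(v[["pbar"]], v[["k"]], v[["pmax"]], v[["tau"]]),
      penalty = function(v) 0),
    fail_param(sprintf("unknown model id '%s'", model))
  )
}

#' Model identifiers available for fitting
#'
#' @return Character vector of model ids accepted by [fit_model()]:
#'   `"asymptote"`, `"source"` and `"heterogeneity"` (three
#'   parameterizations of the mathematically identical single-exponential
#'   curve), `"exponential"`, `"gamma"`, `"trunc_gamma"` and `"twopop"`.
#' @export
kin_models <- function() {
  c("asymptote", "source", "heterogeneity", "exponential", "gamma",
    "trunc_gamma", "twopop")
}

# ---- problem setup ----------------------------------------------------------

to_internal <- function(x, is_log) ifelse(is_log, log(x), x)
from_internal <- function(x, is_log) ifelse(is_log, exp(x), x)

prepare_problem <- function(datasets, model, fixed, share, lower, upper,
                            transform) {
  datasets <- as_dataset_list(datasets)
  def <- kin_model_def(model)
  pars <- def$pars
  if (is.null(fixed)) fixed <- def$default_fixed
  if (length(fixed) && (is.null(names(fixed)) ||
                        !all(names(fixed) %in% pars$name)))
    fail_param("'fixed' must be a named list of model parameters")
  free_names <- setdiff(pars$name, names(fixed))
  if (length(free_names) == 0L) fail_param("no free parameters to fit")
  if (is.null(share)) share <- free_names
  if (!all(share %in% free_names))
    fail_param("'share' must name free parameters of the model")
  subj_names <- setdiff(free_names, share)
  n_sub <- length(datasets)
  subjects <- vapply(datasets, `[[`, "", "subject")
  if (anyDuplicated(subjects)) subjects <- make.unique(subjects)

  theta_names <- c(intersect(pars$name, share),
                   if (n_sub > 0 && length(subj_names))
                     as.vector(t(outer(subjects, intersect(pars$name, subj_names),
                                       function(s, p) paste0(p, "|", s)))))
  base_of <- sub("\\|.*$", "", theta_names)
  row_of <- match(base_of, pars$name)
  lo <- pars$lower[row_of]; hi <- pars$upper[row_of]
  if (!is.null(lower)) {
    idx <- match(names(lower), pars$name)
    for (j in seq_along(lower)) lo[base_of == pars$name[idx[j]]] <- lower[[j]]
  }
  if (!is.null(upper)) {
    idx <- match(names(upper), pars$name)
    for (j in seq_along(upper)) hi[base_of == pars$name[idx[j]]] <- upper[[j]]
  }
  is_log <- pars$log[row_of]

  n_obs <- sum(vapply(datasets, function(d) length(d$times), 0L))
  npar <- length(theta_names)
  if (npar >= n_obs)
    fail_param(sprintf("model has %d free parameters but only %d observations",
                       npar, n_obs))

  # indices of theta entries relevant to subject s (shared + own)
  subject_sel <- lapply(subjects, function(s) {
    which(!grepl("\\|", theta_names) | endsWith(theta_names, paste0("|", s)))
  })

  list(datasets = datasets, def = def, fixed = fixed, share = share,
       subj_names = subj_names, subjects = subjects,
       theta_names = theta_names, base_of = base_of,
       lower = lo, upper = hi, is_log = is_log,
       lower_int = to_internal(lo, is_log), upper_int = to_internal(hi, is_log),
       subject_sel = subject_sel, transform = transform,
       n_obs = n_obs, npar = npar)
}

subject_param_vec <- function(prob, theta_nat, s) {
  sel <- prob$subject_sel[[s]]
  v <- theta_nat[sel]
  names(v) <- prob$base_of[sel]
  c(v, unlist(prob$fixed))
}

problem_objective <- function(prob, g_obs_list) {
  g <- function(f) transform_fraction(f, prob$transform)
  function(theta_int) {
    theta_nat <- from_internal(theta_int, prob$is_log)
    total <- 0
    for (s in seq_along(prob$datasets)) {
      v <- subject_param_vec(prob, theta_nat, s)
      params <- tryCatch(prob$def$make(v), error = function(e) NULL)
      if (is.null(params)) return(1e10)
      ds <- prob$datasets[[s]]
      pred <- label_fraction(params, ds$times, ds$T_label)
      pred <- pmin(pmax(pred, 0), 1)
      total <- total + sum((g_obs_list[[s]] - g(pred))^2) + prob$def$penalty(v)
    }
    if (!is.finite(total)) 1e10 else total
  }
}

default_starts <- function(prob, n_starts, seed) {
  npar <- prob$npar
  ctr <- to_internal(prob$def$pars$default[match(prob$base_of, prob$def$pars$name)],
                     prob$is_log)
  if (n_starts <= 1L) return(matrix(ctr, nrow = 1L))
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1L, npar))
  span <- sweep(u, 2, prob$upper_int - prob$lower_int, `*`)
  rbind(matrix(ctr, nrow = 1L),
        sweep(span, 2, prob$lower_int, `+`))
}

solve_problem <- function(prob, g_obs_list, starts_int, factr = 1e2,
                          maxit = 1000L) {
  obj <- problem_objective(prob, g_obs_list)
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts_int))) {
    res <- tryCatch(
      stats::optim(starts_int[i, ], obj, method = "L-BFGS-B",
                   lower = prob$lower_int, upper = prob$upper_int,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    fail_fit(sprintf("optimizer failed to converge from all %d starts",
                     nrow(starts_int)))
  list(theta_int = best$par, value = best$value,
       convergence = best$convergence, n_fail = n_fail)
}

# ---- user-facing fit --------------------------------------------------------

#' Fit a labeling-curve model to one or more subjects
#'
#' Estimates model parameters by minimizing the sum of squared residuals
#' between observed and predicted labeled-DNA fractions on a
#' variance-stabilized scale (arcsine-square-root by default), using
#' bounded multi-start optimization (Latin-hypercube starting points,
#' L-BFGS-B refinement). Several subjects can be fitted simultaneously
#' with any subset of parameters shared across subjects, as when searching
#' for the minimal number of parameters that describe a cohort.
#'
#' @param datasets a [labeling_dataset()] or list of them.
#' @param model model id, see [kin_models()].
#' @param fixed named list of parameters to hold fixed. `NULL` (default)
#'   applies the model's conventional fixings (`tau = 0` everywhere;
#'   additionally `alpha = 1` for the gamma model). Supply `list()` to
#'   free everything.
#' @param share character vector of free parameter names shared across all
#'   subjects; the remaining free parameters get one copy per subject.
#'   Default: all free parameters shared.
#' @param lower,upper optional named lists overriding the default box
#'   bounds.
#' @param n_starts number of optimization starts (default 20).
#' @param starts optional matrix (rows = starts) or vector of
#'   natural-scale starting values for the free-parameter vector,
#'   overriding the Latin-hypercube design.
#' @param seed integer seed making the start design reproducible.
#' @param transform residual scale, see [transform_fraction()].
#' @return An object of class `labeling_fit` with elements `estimates`
#'   (per-subject named parameter vectors), `params` (per-subject
#'   `kin_params`), `avg_turnover`, `rss` (transformed scale), `n_obs`,
#'   `n_params`, `df`, `at_bounds`, `k_plausible` (gamma-family shape
#'   screen `k > 0.1`), and bookkeeping needed by [bootstrap_ci()].
#' @examples
#' ds <- generate_dataset(synthetic_config(gamma_params(0.01, 0.5),
#'                                         T_label = 7, seed = 1))
#' fit <- fit_model(ds, "gamma", n_starts = 5)
#' fit$avg_turnover
#' @export
fit_model <- function(datasets, model, fixed = NULL, share = NULL,
                      lower = NULL, upper = NULL, n_starts = 20L,
                      starts = NULL, seed = 1L, transform = "asinsqrt") {
  prob <- prepare_problem(datasets, model, fixed, share, lower, upper,
                          transform)
  g_obs <- lapply(prob$datasets, function(d)
    transform_fraction(d$fractions, transform))
  if (is.null(starts)) {
    starts_int <- default_starts(prob, n_starts, seed)
  } else {
    if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1L)
    if (ncol(starts) != prob$npar)
      fail_param("'starts' must have one column per free parameter")
    starts_int <- t(apply(starts, 1L, to_internal, is_log = prob$is_log))
    if (prob$npar == 1L) starts_int <- t(starts_int)
  }
  sol <- solve_problem(prob, g_obs, starts_int)
  build_fit(prob, sol, seed)
}

build_fit <- function(prob, sol, seed) {
  theta_nat <- from_internal(sol$theta_int, prob$is_log)
  names(theta_nat) <- prob$theta_names
  estimates <- list(); params <- list(); avg <- numeric(length(prob$datasets))
  for (s in seq_along(prob$datasets)) {
    v <- subject_param_vec(prob, theta_nat, s)
    estimates[[s]] <- v
    params[[s]] <- prob$def$make(v)
    avg[s] <- average_turnover(params[[s]])
  }
  names(estimates) <- names(params) <- names(avg) <- prob$subjects
  # recompute rss without feasibility penalty
  rss <- 0; fitted <- list(); resid <- list()
  for (s in seq_along(prob$datasets)) {
    ds <- prob$datasets[[s]]
    pred <- pmin(pmax(label_fraction(params[[s]], ds$times, ds$T_label), 0), 1)
    fitted[[s]] <- pred
    resid[[s]] <- transform_fraction(ds$fractions, prob$transform) -
      transform_fraction(pred, prob$transform)
    rss <- rss + sum(resid[[s]]^2)
  }
  names(fitted) <- names(resid) <- prob$subjects
  eps <- 1e-7 * pmax(abs(prob$upper_int - prob$lower_int), 1)
  at_b <- prob$theta_names[sol$theta_int <= prob$lower_int + eps |
                             sol$theta_int >= prob$upper_int - eps]
  k_plaus <- if (prob$def$id %in% c("gamma", "trunc_gamma")) {
    all(vapply(estimates, function(v) v[["k"]] > 0.1, TRUE))
  } else NA
  structure(list(model = prob$def$id, estimates = estimates, params = params,
                 avg_turnover = avg, rss = rss, n_obs = prob$n_obs,
                 n_params = prob$npar, df = prob$n_obs - prob$npar,
                 theta = theta_nat, at_bounds = at_b, k_plausible = k_plaus,
                 transform = prob$transform, convergence = sol$convergence,
                 n_start_failures = sol$n_fail, fitted = fitted,
                 residuals_trans = resid, seed = seed,
                 problem = prob, boot = NULL),
            class = "labeling_fit")
}

#' @export
print.labeling_fit <- function(x, ...) {
  cat("<labeling_fit> model:", x$model, "\n")
  cat("  subjects:", paste(names(x$estimates), collapse = ", "), "\n")
  cat("  rss (transformed scale):", signif(x$rss, 6),
      " n_obs:", x$n_obs, " free parameters:", x$n_params, "\n")
  for (s in names(x$estimates)) {
    cat("  ", s, ": ",
        paste(sprintf("%s=%.5g", names(x$estimates[[s]]), x$estimates[[s]]),
              collapse = ", "),
        "  avg turnover=", signif(x$avg_turnover[[s]], 5), "/day\n", sep = "")
  }
  if (isFALSE(x$k_plausible))
    cat("  note: fitted gamma shape k <= 0.1; the implied rate distribution",
        "puts appreciable turnover in implausibly fast subpopulations\n")
  if (length(x$at_bounds))
    cat("  note: parameter(s) at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  if (!is.null(x$boot)) {
    cat("  bootstrap (", x$boot$n_boot, " resamples, seed ", x$boot$seed,
        "):\n", sep = "")
    print(x$boot$ci, digits = 4)
  }
  invisible(x)
}

#' Predicted labeled fractions from a fit
#'
#' @param object a `labeling_fit`.
#' @param times optional numeric vector of times (days); defaults to each
#'   subject's observation times.
#' @param ... unused.
#' @return Named list (per subject) of predicted fractions.
#' @export
predict.labeling_fit <- function(object, times = NULL, ...) {
  out <- lapply(seq_along(object$params), function(s) {
    ds <- object$problem$datasets[[s]]
    tt <- times %||% ds$times
    label_fraction(object$params[[s]], tt, ds$T_label)
  })
  names(out) <- names(object$params)
  out
}
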