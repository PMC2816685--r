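#' Residual-bootstrap confidence intervals for a labeling fit
#'
#' Resamples the fitted residuals on the variance-stabilized scale (with
#' replacement, within each subject across all of that subject's
#' timepoints), adds them to the fitted transformed predictions,
#' back-transforms (clipped to the valid fraction range) and refits the
#' model. Percentile intervals are reported for every free parameter and
#' for each subject's average turnover rate. Refits start from the point
#' estimate, so the procedure is fully reproducible given `seed`.
#'
#' @param fit a `labeling_fit` from [fit_model()].
#' @param datasets the datasets that produced `fit`; defaults to those
#'   stored in the fit.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @param level confidence level (default 0.95).
#' @return `fit` with a `boot` element: `ci` (data.frame of lower/upper
#'   percentile bounds per quantity), `estimates` (matrix of bootstrap
#'   replicate values), `n_fail` (refits that failed; a warning status is
#'   set when more than 20% fail), `n_boot`, `seed`, `level`.
#' @examples
#' ds <- generate_dataset(synthetic_config(asymptote_params(0.5, 0.02),
#'                                         T_label = 7, seed = 1))
#' fit <- fit_model(ds, "asymptote", n_starts = 5)
#' fit <- bootstrap_ci(fit, n_boot = 50, seed = 2)
#' fit$boot$ci
#' @export
bootstrap_ci <- function(fit, datasets = NULL, n_boot = 1000L, seed = 1L,
                         level = 0.95) {
  stopifnot(inherits(fit, "labeling_fit"), n_boot >= 1L)
  prob <- fit$problem
  if (!is.null(datasets)) {
    datasets <- as_dataset_list(datasets)
    stopifnot(length(datasets) == length(prob$datasets))
    prob$datasets <- datasets
  }
  g <- function(f) transform_fraction(f, fit$transform)
  pred_trans <- lapply(seq_along(prob$datasets), function(s)
    g(fit$fitted[[s]]))
  resid <- fit$residuals_trans
  start_int <- matrix(to_internal(fit$theta, prob$is_log), nrow = 1L)

  qty_names <- c(prob$theta_names,
                 paste0("avg_turnover|", prob$subjects))
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(qty_names),
                 dimnames = list(NULL, qty_names))
  n_fail <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      g_star <- vector("list", length(prob$datasets))
      for (s in seq_along(prob$datasets)) {
        r <- resid[[s]]
        y <- pred_trans[[s]] + sample(r, length(r), replace = TRUE)
        g_star[[s]] <- g(inverse_transform_fraction(y, fit$transform))
      }
      sol <- tryCatch(solve_problem(prob, g_star, start_int),
                      error = function(e) NULL)
      if (is.null(sol)) { n_fail <- n_fail + 1L; next }
      theta_nat <- from_internal(sol$theta_int, prob$is_log)
      names(theta_nat) <- prob$theta_names
      avg <- vapply(seq_along(prob$datasets), function(s)
        average_turnover(prob$def$make(subject_param_vec(prob, theta_nat, s))), 0)
      reps[b, ] <- c(theta_nat, avg)
    }
  })
  ok <- stats::complete.cases(reps)
  if (!any(ok)) fail_fit("all bootstrap refits failed")
  a <- (1 - level) / 2
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  ci <- data.frame(quantity = qty_names,
                   estimate = c(fit$theta, unname(fit$avg_turnover)),
                   lower = qs[1, ], upper = qs[2, ],
                   row.names = NULL, stringsAsFactors = FALSE)
  status <- if (n_fail > 0.2 * n_boot) "warning: >20% of refits failed" else "ok"
  fit$boot <- list(ci = ci, estimates = reps[ok, , drop = FALSE],
                   n_boot = n_boot, n_fail = n_fail, seed = seed,
                   level = level, status = status)
  fit
}
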