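# Transform, least-squares fitting, parameter sharing, model selection.

test_that("arcsine-square-root transform stabilizes and inverts correctly", {
  expect_identical(transform_fraction(0), 0)
  expect_equal(transform_fraction(0.25), pi / 6, tolerance = 1e-14)
  expect_equal(transform_fraction(1), pi / 2, tolerance = 1e-14)
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(transform_fraction(f)) > 0))
  expect_equal(inverse_transform_fraction(transform_fraction(f)), f,
               tolerance = 1e-12)
  # clipping keeps bootstrap-perturbed values valid
  expect_identical(inverse_transform_fraction(c(-0.3, 2)), c(0, 1))
  expect_error(transform_fraction(1.2), class = "invalid_input")
  expect_error(transform_fraction(-0.1), class = "invalid_input")
  expect_equal(transform_fraction(0.3, "identity"), 0.3)
  expect_equal(transform_fraction(0.3, "logit"), stats::qlogis(0.3))
})

test_that("noiseless data are recovered exactly by the generating model", {
  truth <- asymptote_params(alpha = 0.2, d = 0.05)
  ds <- noiseless_dataset(truth, 7)
  fit <- fit_model(ds, "asymptote", n_starts = 10)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(fit$theta[["alpha"]]), 0.2, tolerance = 1e-4)
  expect_equal(unname(fit$theta[["d"]]), 0.05, tolerance = 1e-4)
  # and for the gamma model
  gtruth <- gamma_params(0.01, 0.5)
  gfit <- fit_model(noiseless_dataset(gtruth, 7), "gamma", n_starts = 10)
  expect_lt(gfit$rss, 1e-10)
  expect_equal(unname(gfit$avg_turnover), 0.01, tolerance = 1e-3)
})

test_that("the three historical parameterizations give one curve and one average turnover", {
  # same underlying curve by construction
  grid <- expand.grid(alpha = c(0.2, 0.5, 0.9), d = c(0.005, 0.02, 0.1))
  tt <- seq(0, 120, by = 3)
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]; d <- grid$d[i]
    asym <- kinlabel:::kin_model_def("asymptote")$make(
      c(alpha = a, d = d, tau = 0))
    src <- kinlabel:::kin_model_def("source")$make(c(u = 1 - a, d = d, tau = 0))
    het <- kinlabel:::kin_model_def("heterogeneity")$make(
      c(pavg = a * d, excess = d - a * d, tau = 0))
    expect_equal(label_fraction(asym, tt, 7), label_fraction(src, tt, 7),
                 tolerance = 1e-14)
    expect_equal(label_fraction(asym, tt, 7), label_fraction(het, tt, 7),
                 tolerance = 1e-14)
  }
  # when the parameter conversion is exact in binary the curves are
  # byte-identical: all three are the same function of (alpha, d)
  asym <- kinlabel:::kin_model_def("asymptote")$make(c(alpha = 0.5, d = 0.02, tau = 0))
  src <- kinlabel:::kin_model_def("source")$make(c(u = 0.5, d = 0.02, tau = 0))
  expect_identical(label_fraction(asym, tt, 7), label_fraction(src, tt, 7))
  # fitted to the same noisy data they deliver identical rss and alpha*d
  ds <- generate_dataset(synthetic_config(asymptote_params(0.35, 0.03),
                                          T_label = 7, seed = 5))
  fits <- lapply(c("asymptote", "source", "heterogeneity"), function(m)
    fit_model(ds, m, n_starts = 15))
  rss <- vapply(fits, `[[`, 0, "rss")
  avg <- vapply(fits, function(f) unname(f$avg_turnover), 0)
  expect_equal(rss[2], rss[1], tolerance = 1e-6)
  expect_equal(rss[3], rss[1], tolerance = 1e-6)
  expect_equal(avg[2], avg[1], tolerance = 1e-4)
  expect_equal(avg[3], avg[1], tolerance = 1e-4)
})

test_that("fits are deterministic given identical inputs and seed", {
  ds <- generate_dataset(synthetic_config(gamma_params(0.01, 0.5),
                                          T_label = 7, seed = 9))
  f1 <- fit_model(ds, "gamma", n_starts = 8, seed = 3)
  f2 <- fit_model(ds, "gamma", n_starts = 8, seed = 3)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$avg_turnover, f2$avg_turnover)
})

test_that("parameters can be shared or subject-specific across a cohort", {
  d_true <- 0.03
  ds <- list(
    generate_dataset(synthetic_config(asymptote_params(0.3, d_true), 7,
                                      noise_sd = 0.05, seed = 1, subject = "a")),
    generate_dataset(synthetic_config(asymptote_params(0.6, d_true), 7,
                                      noise_sd = 0.05, seed = 2, subject = "b")))
  fit <- fit_model(ds, "asymptote", share = "d", n_starts = 10)
  expect_equal(fit$n_params, 3L)  # one shared d, two subject alphas
  expect_equal(fit$df, 22L - 3L)
  expect_equal(unname(fit$estimates$a[["d"]]), unname(fit$estimates$b[["d"]]))
  expect_equal(unname(fit$estimates$a[["d"]]), d_true, tolerance = 0.3)
  expect_false(fit$estimates$a[["alpha"]] == fit$estimates$b[["alpha"]])
  # the fully shared fit is nested in the shared-d fit
  fit_r <- fit_model(ds, "asymptote", n_starts = 10)
  ft <- f_test_nested(fit_r, fit)
  expect_gt(ft$statistic, 0)
  expect_lt(ft$p.value, 0.05)  # alphas truly differ two-fold
})

test_that("estimates at the feasible boundary are flagged", {
  ds <- noiseless_dataset(asymptote_params(0.9, 0.05), 7)
  fit <- fit_model(ds, "asymptote", upper = list(alpha = 0.5), n_starts = 6)
  expect_true("alpha" %in% fit$at_bounds)
})

test_that("ill-posed fitting requests are rejected", {
  ds <- noiseless_dataset(asymptote_params(0.5, 0.02), 7)
  expect_error(fit_model(ds, "nosuchmodel"), class = "invalid_parameter")
  tiny <- labeling_dataset("s", c(1, 5, 9), c(0.01, 0.02, 0.03), 7)
  expect_error(fit_model(tiny, "twopop"), class = "invalid_parameter")
  expect_error(fit_model(ds, "gamma", fixed = list(zzz = 1)),
               class = "invalid_parameter")
})

test_that("F statistic and p-value follow the partial-F formula", {
  mk <- function(rss, n_params, n_obs = 14L) {
    structure(list(rss = rss, n_params = n_params, n_obs = n_obs,
                   df = n_obs - n_params, transform = "asinsqrt",
                   model = "stub"), class = "labeling_fit")
  }
  ft <- f_test_nested(mk(2, 3L), mk(1, 4L))  # df_f = 10, one extra parameter
  expect_equal(unname(ft$statistic), 10)
  expect_equal(ft$p.value, stats::pf(10, 1, 10, lower.tail = FALSE))
  ft0 <- f_test_nested(mk(1, 3L), mk(1, 4L))
  expect_equal(unname(ft0$statistic), 0)
  expect_equal(ft0$p.value, 1)
  expect_error(f_test_nested(mk(0.5, 3L), mk(1, 4L)),
               class = "invalid_comparison")
  expect_error(f_test_nested(mk(2, 4L), mk(1, 4L)),
               class = "invalid_comparison")
})

test_that("least-squares AIC and AICc follow their closed forms", {
  mk <- function(rss, k, n = 11L)
    structure(list(rss = rss, n_params = k, n_obs = n, df = n - k),
              class = "labeling_fit")
  expect_equal(aic(mk(1, 3L)) - aic(mk(1, 2L)), 2)
  expect_equal(aic(mk(1, 3L)) - aic(mk(2, 3L)), -11 * log(2))
  expect_equal(aicc(mk(1, 3L)), aic(mk(1, 3L)) + 2 * 3 * 4 / (11 - 3 - 1))
  expect_identical(aicc(mk(1, 10L)), Inf)
})

test_that("fixing a parameter at its unconstrained optimum yields F near zero", {
  ds <- generate_dataset(synthetic_config(asymptote_params(0.4, 0.02), 7,
                                          seed = 3))
  full <- fit_model(ds, "asymptote", fixed = list(), n_starts = 10)
  tau_hat <- unname(full$theta[["tau"]])
  restr <- fit_model(ds, "asymptote", fixed = list(tau = tau_hat),
                     n_starts = 10)
  ft <- f_test_nested(restr, full)
  expect_lt(unname(ft$statistic), 0.05)
})
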