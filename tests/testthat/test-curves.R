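# Closed-form labeling curves: frozen reference values, structural
# invariants, and analytic limits.

test_that("asymptote model matches its closed form at reference points", {
  p <- asymptote_params(alpha = 0.5, d = 0.02)
  expect_identical(label_fraction(p, 0, 7), 0)
  # values frozen from high-precision evaluation of the closed form
  expect_equal(label_fraction(p, 7, 7), 0.0653208823005971, tolerance = 1e-12)
  expect_equal(label_fraction(p, 14, 7), 0.0567872469715402, tolerance = 1e-12)
  # delabeling value is the peak value decayed at rate d
  expect_equal(label_fraction(p, 14, 7),
               label_fraction(p, 7, 7) * exp(-0.02 * 7), tolerance = 1e-14)
})

test_that("multi-population curve reduces to its building blocks", {
  one <- multipop_params(alpha = 0.5, p = 0.02)
  asym <- asymptote_params(alpha = 0.5, d = 0.02)
  tt <- c(0, 1, 3.5, 7, 10, 30, 100)
  expect_equal(label_fraction(one, tt, 7), label_fraction(asym, tt, 7),
               tolerance = 1e-15)
  # a rate-zero subpopulation never labels
  z <- multipop_params(alpha = c(0.4, 0.3), p = c(0, 0.05))
  nz <- multipop_params(alpha = 0.3, p = 0.05)
  expect_equal(label_fraction(z, tt, 7), label_fraction(nz, tt, 7),
               tolerance = 1e-15)
  # frozen two-subpopulation value at t = T = 7
  both <- multipop_params(alpha = c(0.5, 0.5), p = c(0.001, 1.0))
  expect_equal(label_fraction(both, 7, 7), 0.503031837550605, tolerance = 1e-12)
})

test_that("gamma curve matches frozen values and its exponential special case", {
  g <- gamma_params(pbar = 0.01, k = 0.5)
  expect_equal(label_fraction(g, 7, 7), 0.0634141884183038, tolerance = 1e-12)
  # k = 1 is exactly the exponential-distribution model
  tt <- seq(0, 150, by = 2.5)
  for (Tl in c(3, 7, 15, 40)) {
    expect_equal(label_fraction(gamma_params(0.01, k = 1), tt, Tl),
                 label_fraction(exponential_params(0.01), tt, Tl),
                 tolerance = 1e-12)
    expect_equal(label_fraction(gamma_params(0.01, k = 1, alpha = 0.5), tt, Tl),
                 label_fraction(exponential_params(0.01, alpha = 0.5), tt, Tl),
                 tolerance = 1e-12)
  }
})

test_that("large-k gamma curve reaches the homogeneous single-exponential limit", {
  g <- gamma_params(pbar = 0.01, k = 1e6)
  hom <- asymptote_params(alpha = 1 - 1e-12, d = 0.01)  # alpha = 1 limit
  tt <- seq(0, 200, by = 5)
  expect_lt(max(abs(label_fraction(g, tt, 15) -
                      label_fraction(hom, tt, 15) / (1 - 1e-12))), 1e-4)
  expect_equal(label_fraction(g, 50, 60), 1 - exp(-0.5), tolerance = 1e-4)
})

test_that("exponential curve saturates without asymptote and scales with alpha", {
  e <- exponential_params(pbar_sub = 0.01)
  expect_equal(label_fraction(e, 100, 200), 0.5, tolerance = 1e-14)
  expect_identical(label_fraction(e, 0, 7), 0)
  tt <- c(1, 5, 7, 20, 80)
  expect_equal(label_fraction(exponential_params(0.01, alpha = 0.5), tt, 7),
               0.5 * label_fraction(e, tt, 7), tolerance = 1e-14)
})

test_that("truncated gamma matches quadrature value and its limits", {
  tg <- trunc_gamma_params(pbar = 0.01, k = 0.1, pmax = 1)
  # frozen from quadrature of the kernel against the renormalized density
  expect_equal(label_fraction(tg, 10, 7), 0.0410717679097551, tolerance = 1e-10)
  expect_equal(average_turnover(tg), 0.00999939922099403, tolerance = 1e-10)
  # huge truncation bound: converges to the untruncated gamma curve
  tt <- c(2, 7, 10, 30, 100)
  expect_lt(max(abs(label_fraction(trunc_gamma_params(0.01, 0.5, 1e6), tt, 7) -
                      label_fraction(gamma_params(0.01, 0.5), tt, 7))), 1e-6)
  # tiny truncation bound: essentially no turnover on experiment timescale
  expect_lt(max(label_fraction(trunc_gamma_params(0.01, 0.5, 1e-9), tt, 7)), 1e-8)
})

test_that("all curves respect range, delay, continuity and monotonicity", {
  tt <- seq(0, 160, by = 0.5)
  for (nm in names(param_battery())) {
    params <- param_battery()[[nm]]
    tau <- params$tau
    for (Tl in c(7, 15)) {
      L <- label_fraction(params, tt, Tl)
      expect_true(all(L >= 0 & L <= 1), info = nm)
      expect_true(all(L[tt <= tau] == 0), info = nm)
      # continuity at the up/down switch t = tau + T
      ts <- tau + Tl
      expect_lt(abs(label_fraction(params, ts - 1e-9, Tl) -
                      label_fraction(params, ts + 1e-9, Tl)), 1e-8)
      # monotone rise while labeling, monotone fall after
      up <- L[tt <= ts]; down <- L[tt >= ts]
      expect_true(all(diff(up) >= -1e-14), info = nm)
      expect_true(all(diff(down) <= 1e-14), info = nm)
    }
  }
})

test_that("initial uplabeling slope equals the average turnover rate", {
  for (nm in names(param_battery())) {
    params <- param_battery()[[nm]]
    params$tau <- 0  # slope limit is defined without delay
    slope <- num_deriv(function(t) label_fraction(params, t, 30), 1e-7,
                       h = 1e-7)
    expect_equal(slope, average_turnover(params),
                 tolerance = 1e-6, info = nm)
    expect_identical(initial_uplabeling_rate(params), average_turnover(params))
  }
})

test_that("average turnover follows the fraction-weighted rate mean", {
  expect_identical(average_turnover(asymptote_params(0.5, 0.02)), 0.01)
  expect_identical(
    average_turnover(multipop_params(c(0.5, 0.5), c(0.001, 1.0))), 0.5005)
  expect_identical(average_turnover(gamma_params(0.02, 2, alpha = 0.5)), 0.01)
  expect_identical(average_turnover(exponential_params(0.02, alpha = 0.5)), 0.01)
})

test_that("invalid parameters are rejected", {
  expect_error(asymptote_params(alpha = 0, d = 0.02), class = "invalid_parameter")
  expect_error(asymptote_params(alpha = 1.2, d = 0.02), class = "invalid_parameter")
  expect_error(asymptote_params(0.5, d = -1), class = "invalid_parameter")
  expect_error(asymptote_params(0.5, d = NaN), class = "invalid_parameter")
  expect_error(gamma_params(pbar = 0.01, k = 0), class = "invalid_parameter")
  expect_error(gamma_params(pbar = -0.01, k = 1), class = "invalid_parameter")
  expect_error(trunc_gamma_params(0.01, 0.5, pmax = 0), class = "invalid_parameter")
  expect_error(multipop_params(numeric(0), numeric(0)), class = "invalid_parameter")
  expect_error(multipop_params(c(0.7, 0.7), c(0.1, 0.2)), class = "invalid_parameter")
  expect_error(label_fraction(asymptote_params(0.5, 0.02), -1, 7),
               class = "invalid_parameter")
  expect_error(label_fraction(asymptote_params(0.5, 0.02), 1, 0),
               class = "invalid_parameter")
})
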