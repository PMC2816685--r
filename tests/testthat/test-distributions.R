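# Turnover-rate distributions and the kinetic quantities derived from them.

test_that("distribution constructors store correct moments", {
  cases <- list(dist_gamma(0.01, 0.5), dist_exponential(0.02),
                dist_trunc_gamma(0.01, 0.3, 1), dist_point(0.05),
                dist_mixture(list(dist_point(0), dist_exponential(0.02)),
                             c(0.5, 0.5)))
  for (d in cases) {
    m <- kinlabel:::dist_expect(d, function(p) p)
    v <- kinlabel:::dist_expect(d, function(p) p^2) - m^2
    expect_equal(m, d$mean, tolerance = 1e-8, info = d$label)
    expect_equal(v, d$var, tolerance = 1e-6, info = d$label)
  }
  expect_equal(dist_gamma(0.01, 4)$var, 0.01^2 / 4)
  expect_equal(dist_mixture(list(dist_point(0), dist_exponential(0.02)),
                            c(0.5, 0.5))$mean, 0.01)
})

test_that("initial delabeling rate interpolates between its two limits", {
  # homogeneous population: the rate is the single rate, for any T
  for (Tl in c(0.01, 1, 7, 100))
    expect_equal(initial_delabeling_rate(dist_point(0.03), Tl), 0.03,
                 tolerance = 1e-12)
  # exponential rates: short labeling gives twice the long-labeling rate
  d <- dist_exponential(0.01)
  expect_equal(initial_delabeling_rate(d, 1e-8), 0.02, tolerance = 1e-6)
  # the long-labeling limit is approached like (pbar T)^(-1) for shape 1
  expect_equal(initial_delabeling_rate(d, 1e12), 0.01, tolerance = 1e-6)
  # gamma shape k: short-labeling limit is mean * (k + 1) / k
  g <- dist_gamma(0.01, 3)
  expect_equal(initial_delabeling_rate(g, 1e-6), 0.01 * 4 / 3,
               tolerance = 1e-4)
  # monotone non-increasing in T, bounded by mean and mean + var/mean
  for (d in list(dist_gamma(0.01, 0.5), dist_exponential(0.02),
                 dist_trunc_gamma(0.02, 0.3, 1))) {
    rates <- vapply(c(0.1, 1, 5, 15, 60, 300, 3000), function(Tl)
      initial_delabeling_rate(d, Tl), 0)
    expect_true(all(diff(rates) <= 1e-10), info = d$label)
    expect_true(all(rates <= d$mean + d$var / d$mean + 1e-10), info = d$label)
    expect_true(all(rates >= d$mean - 1e-10), info = d$label)
  }
  expect_error(initial_delabeling_rate(dist_point(0), 7),
               class = "invalid_parameter")
})

test_that("delabeling rate agrees with finite differences on the curve", {
  params <- gamma_params(0.01, 0.5)
  Tl <- 7
  Lf <- function(t) label_fraction(params, t, Tl)
  h <- 1e-6
  fd <- -(Lf(Tl + h) - Lf(Tl)) / h / Lf(Tl)
  expect_equal(initial_delabeling_rate(as_turnover_dist(params), Tl), fd,
               tolerance = 1e-4)
})

test_that("contribution_cdf is a normalized monotone contribution profile", {
  g <- dist_gamma(0.01, 10)
  expect_identical(contribution_cdf(g, 0), 0)
  expect_equal(contribution_cdf(g, 1e4), 1, tolerance = 1e-8)
  # frozen: regularized lower incomplete gamma with shape k+1 at argument k
  expect_equal(contribution_cdf(g, 0.01), 0.416960249807015, tolerance = 1e-8)
  grid <- contribution_cdf(g, seq(0, 0.05, by = 0.002))
  expect_true(all(diff(grid) >= 0))
  # discrete distribution: steps at the atoms
  d <- as_turnover_dist(multipop_params(c(0.5, 0.0095), c(0.001, 1)))
  expect_equal(contribution_cdf(d, 0.5), 0.5 * 0.001 / 0.01, tolerance = 1e-12)
  expect_equal(contribution_cdf(d, 2), 1, tolerance = 1e-12)
})

test_that("fraction_above is a proper upper tail", {
  g <- dist_gamma(0.01, 0.5)
  expect_equal(fraction_above(g, 0), 1, tolerance = 1e-12)
  expect_equal(fraction_above(g, 1e6), 0, tolerance = 1e-12)
  # frozen far-tail value by quadrature of the gamma density
  expect_equal(fraction_above(g, 1), 1.52397060483263e-23, tolerance = 1e-5)
  grid <- fraction_above(g, seq(0, 0.1, by = 0.005))
  expect_true(all(diff(grid) <= 0))
  # mixture with a non-dividing atom
  mx <- dist_mixture(list(dist_point(0), dist_exponential(0.02)), c(0.5, 0.5))
  expect_equal(fraction_above(mx, 0), 0.5, tolerance = 1e-12)
})

test_that("rate sampling is reproducible and matches the distribution mean", {
  d <- dist_gamma(0.01, 0.5)
  s1 <- sample_rates(d, 1000, seed = 7)
  s2 <- sample_rates(d, 1000, seed = 7)
  expect_identical(s1, s2)
  expect_equal(mean(sample_rates(d, 2e5, seed = 1)), 0.01, tolerance = 0.02)
  mx <- dist_mixture(list(dist_point(0), dist_exponential(0.02)), c(0.5, 0.5))
  sm <- sample_rates(mx, 2e5, seed = 2)
  expect_equal(mean(sm == 0), 0.5, tolerance = 0.02)
  expect_equal(mean(sm), 0.01, tolerance = 0.02)
})

test_that("as_turnover_dist preserves the average turnover rate", {
  for (nm in names(param_battery())) {
    params <- param_battery()[[nm]]
    expect_equal(as_turnover_dist(params)$mean, average_turnover(params),
                 tolerance = 1e-12, info = nm)
  }
})
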