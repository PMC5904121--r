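test_that("OD to CDW conversion uses the correlation factor", {
  expect_equal(od_to_cdw(1.0), 0.33)
  expect_equal(od_to_cdw(0), 0)
  expect_equal(od_to_cdw(2.0, factor = 0.25), 0.5)
  expect_error(od_to_cdw(-1), "od")
})

test_that("time series constructor enforces its invariants", {
  expect_error(time_series(c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(time_series(c(1, 1), c(1, 2)), "strictly increasing")
  expect_error(time_series(0, 1), "two points")
})

test_that("noise-free exponential data is recovered exactly", {
  t <- seq(0, 20, length.out = 5)
  od <- 0.1 * exp(0.1 * t)
  fit <- fit_exponential_growth(time_series(t, od, "od"))
  expect_equal(fit$mu, 0.1, tolerance = 1e-10)
  expect_equal(fit$X0, 0.1 * 0.33, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant OD: zero growth
  flat <- fit_exponential_growth(time_series(t, rep(0.5, 5), "od"))
  expect_equal(flat$mu, 0, tolerance = 1e-12)
  expect_error(fit_exponential_growth(time_series(t, c(-1, od[-1]), "od")),
               "positive")
  expect_error(fit_exponential_growth(time_series(c(0, 1), od[1:2], "od")),
               "3 points")
})

test_that("noisy growth-rate recovery stays within three standard errors", {
  spec <- simulation_spec(seed = 19, mu = 0.081, noise_cv = 0.01)
  sim <- simulate_culture(spec)
  fit <- fit_exponential_growth(sim$od)
  expect_lt(abs(fit$mu - 0.081), 3 * fit$sigma_mu)
})

test_that("substrate rates are finite differences with interpolation", {
  s <- time_series(c(0, 5, 10), c(500, 490, 480), "substrate")
  expect_equal(substrate_rate(s, 0, 10), -2)
  expect_equal(substrate_rate(s, 2.5, 7.5), -2)  # interpolated endpoints
  flat <- time_series(c(0, 10), c(100, 100), "substrate")
  expect_equal(substrate_rate(flat, 0, 10), 0)
  expect_error(substrate_rate(s, -1, 5), "outside")
  expect_error(substrate_rate(s, 5, 5), "t1 must be smaller")
  # interpolation agrees with a dense grid on linear data
  dense <- time_series(seq(0, 10, 0.1), 500 - 2 * seq(0, 10, 0.1),
                       "substrate")
  expect_equal(substrate_rate(s, 1.3, 8.7),
               substrate_rate(dense, 1.3, 8.7), tolerance = 1e-9)
})

test_that("uptake estimation recovers the generating rate without noise", {
  spec <- simulation_spec(seed = 1, q_true = 13, mu = 0.081, noise_cv = 0)
  sim <- simulate_culture(spec)
  fit <- fit_exponential_growth(sim$od)
  est <- specific_uptake_rate(sim$substrate, sim$evap_control, fit, 0, 40)
  expect_equal(est$q, 13, tolerance = 1e-6)
  reg <- fit_uptake_rate(sim$substrate, sim$evap_control, fit)
  expect_equal(reg$q, 13, tolerance = 1e-6)
  expect_equal(reg$evap_rate, spec$evap_rate, tolerance = 1e-6)
})

test_that("uptake is zero without net substrate change or for identical series", {
  t <- seq(0, 10, length.out = 6)
  flat <- time_series(t, rep(400, 6), "substrate")
  fit <- fit_exponential_growth(time_series(t, 0.1 * exp(0.1 * t), "od"))
  expect_equal(specific_uptake_rate(flat, flat, fit, 0, 10)$q, 0)
  decaying <- time_series(t, 400 - 3 * t, "substrate")
  expect_equal(specific_uptake_rate(decaying, decaying, fit, 0, 10)$q, 0)
})

test_that("identical linear loss in culture and control cancels exactly", {
  spec <- simulation_spec(seed = 4, noise_cv = 0)
  for (evap in c(0, 0.5, 2)) {
    sim <- simulate_culture(simulation_spec(seed = 4, noise_cv = 0,
                                            evap_rate = evap))
    fit <- fit_exponential_growth(sim$od)
    est <- specific_uptake_rate(sim$substrate, sim$evap_control, fit, 0, 40)
    expect_equal(est$q, spec$q_true, tolerance = 1e-6)
  }
})

test_that("integral and midpoint denominators agree as the window shrinks", {
  sim <- simulate_culture(simulation_spec(seed = 5, noise_cv = 0,
                                          n_points = 81))
  fit <- fit_exponential_growth(sim$od)
  gap <- sapply(c(20, 10, 2, 0.5), function(w) {
    qi <- specific_uptake_rate(sim$substrate, sim$evap_control, fit,
                               20 - w / 2, 20 + w / 2, "integral")$q
    qm <- specific_uptake_rate(sim$substrate, sim$evap_control, fit,
                               20 - w / 2, 20 + w / 2, "midpoint")$q
    abs(qi - qm)
  })
  expect_true(all(diff(gap) < 0))  # shrinking window: estimates converge
  expect_lt(gap[length(gap)], 1e-3)
})

test_that("a non-positive growth window falls back with a warning", {
  t <- seq(0, 10, length.out = 5)
  fit <- fit_exponential_growth(time_series(t, rep(0.2, 5), "od"))
  s <- time_series(t, 100 - 2 * t, "substrate")
  e <- time_series(t, rep(100, 5), "substrate")
  expect_warning(est <- specific_uptake_rate(s, e, fit, 0, 10),
                 "mean-biomass")
  expect_equal(est$q, 20 / (fit$X0 * 10), tolerance = 1e-9)
})

test_that("variance propagation matches the analytic formula and Monte Carlo", {
  expect_equal(propagate_variance(1, 4), 4)
  expect_equal(propagate_variance(c(1, 1), c(1, 1)), 2)
  expect_equal(propagate_variance(c(2, -3), c(0.5, 2)), 4 * 0.5 + 9 * 2)
  # Monte-Carlo agreement for a linear function
  set.seed(99)
  n <- 1e5
  a <- c(1.5, -2, 0.7)
  vars <- c(0.4, 0.9, 0.25)
  draws <- cbind(rnorm(n, 0, sqrt(vars[1])), rnorm(n, 0, sqrt(vars[2])),
                 rnorm(n, 0, sqrt(vars[3])))
  f <- draws %*% a
  expect_equal(var(as.numeric(f)), propagate_variance(a, vars),
               tolerance = 0.02)
})
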