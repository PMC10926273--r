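test_that("noiseless series recover the break parameters exactly", {
  s <- simulate_mortality(level_shift = -0.01, slope_shift = -0.002, noise_sd = 0)
  f <- fit_its(s, horizon = 10)
  dev <- longrun_deviation(f)
  expect_equal(dev$point, -0.03, tolerance = 1e-10)
  expect_equal(dev$upper95 - dev$lower95, 0, tolerance = 1e-8)
  expect_equal(unname(coef(f)[1, ]),
               c(log(80), -0.03, -0.01, -0.002), tolerance = 1e-10)

  # null effect: deviation exactly 0 with zero-width interval
  s0 <- simulate_mortality(level_shift = 0, slope_shift = 0, noise_sd = 0)
  dev0 <- longrun_deviation(fit_its(s0, horizon = 10))
  expect_equal(dev0$point, 0, tolerance = 1e-12)
  expect_equal(dev0$se, 0, tolerance = 1e-10)
})

test_that("long-run deviation is the linear combination level + slope * horizon", {
  s <- simulate_mortality(level_shift = -0.02, slope_shift = 0, noise_sd = 0)
  f <- fit_its(s, horizon = 10)
  # pure level break: deviation equals the level shift at any horizon
  expect_equal(longrun_deviation(f, horizon = 3)$point, -0.02, tolerance = 1e-10)
  expect_equal(longrun_deviation(f, horizon = 10)$point, -0.02, tolerance = 1e-10)

  s2 <- simulate_mortality(level_shift = 0, slope_shift = -0.003, noise_sd = 0)
  f2 <- fit_its(s2, horizon = 5)
  # pure slope break: doubling the horizon doubles the deviation
  expect_equal(longrun_deviation(f2, horizon = 10)$point,
               2 * longrun_deviation(f2, horizon = 5)$point, tolerance = 1e-10)
})

test_that("deviation equals the brute-force prediction difference at the horizon", {
  s <- simulate_mortality(level_shift = -0.015, slope_shift = -0.001,
                          noise_sd = 0.03, seed = 21)
  f <- fit_its(s, horizon = 10)
  b <- coef(f)[1, ]
  # fitted post value minus extrapolated pre-trend at t = 10
  pred_post <- b[1] + b[2] * 10 + b[3] + b[4] * 10
  pred_counterfactual <- b[1] + b[2] * 10
  expect_equal(longrun_deviation(f)$point,
               unname(pred_post - pred_counterfactual), tolerance = 1e-12)
})

test_that("unusable series are excluded and reported, not fatal", {
  good <- simulate_mortality(country = "AAA", noise_sd = 0.01, seed = 1)
  short <- simulate_mortality(country = "BBB", years_post = 2, noise_sd = 0.01,
                              seed = 2)  # only 2 post-transition years
  expect_message(f <- fit_its(rbind(good, short)), "excluded.*BBB")
  expect_equal(f$failed, "BBB")
  expect_equal(longrun_deviation(f)$country, "AAA")
  expect_error(longrun_deviation(f, country = "BBB"), "not in fit")
  expect_error(fit_its(short), "no country could be fitted")
})

test_that("partial pooling with shrinkage forced to 0 equals no pooling", {
  pan <- simulate_mortality_panel(n_countries = 25, noise_sd = 0.03, seed = 6)
  f_none <- fit_its(pan, pooling = "none")
  f_zero <- fit_its(pan, pooling = "partial", shrinkage = 0)
  expect_equal(longrun_deviation(f_none), longrun_deviation(f_zero),
               tolerance = 1e-12)
})

test_that("partial pooling shrinks the spread of break estimates", {
  pan <- simulate_mortality_panel(n_countries = 40, level_shift = -0.01,
                                  slope_shift = -0.002, noise_sd = 0.04, seed = 9)
  f_none <- fit_its(pan, pooling = "none")
  f_part <- fit_its(pan, pooling = "partial")
  expect_lt(sd(longrun_deviation(f_part)$point),
            sd(longrun_deviation(f_none)$point))
  # grand mean is essentially preserved
  expect_lt(abs(mean(longrun_deviation(f_part)$point) -
                  mean(longrun_deviation(f_none)$point)), 5e-3)
})

test_that("parameter recovery is unbiased with near-nominal interval coverage", {
  truth <- -0.01 + -0.002 * 10
  pan <- simulate_mortality_panel(n_countries = 200, level_shift = -0.01,
                                  slope_shift = -0.002, noise_sd = 0.02, seed = 13)
  dev <- longrun_deviation(fit_its(pan, pooling = "none"))
  mc_se <- sd(dev$point) / sqrt(nrow(dev))
  expect_lt(abs(mean(dev$point) - truth), 4 * mc_se)
  coverage <- mean(dev$lower95 <= truth & dev$upper95 >= truth)
  expect_gt(coverage, 0.90)
  expect_lt(coverage, 0.99)
})
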