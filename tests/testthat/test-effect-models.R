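test_that("bivariate coefficient equals the group-mean difference exactly", {
  # constructed noiseless two-group data
  d <- toy_dataset(mean_protest = -0.017, mean_violent = 0, mean_other = 0)
  fit <- suppressWarnings(fit_bivariate(d, "protest_led"))  # zero-residual fit
  expect_equal(fit$beta, -0.017, tolerance = 1e-12)

  # property: on arbitrary data the identity holds to machine precision
  for (s in 1:5) {
    sim <- simulate_transitions(sim_config(seed = s))
    for (pred in c("protest_led", "violence_led")) {
      fit <- fit_bivariate(sim$data, pred)
      expect_equal(fit$beta, group_mean_diff(sim$data, pred), tolerance = 1e-12)
      expect_gte(fit$r_squared, 0)
      expect_lte(fit$r_squared, 1)
      expect_gt(fit$se, 0)
    }
  }
})

test_that("multivariate fit with no covariates reduces to the bivariate fit", {
  sim <- simulate_transitions(sim_config(seed = 3))
  f1 <- fit_bivariate(sim$data, "violence_led")
  f2 <- fit_multivariate(sim$data, "violence_led", character(0))
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$se, f2$se)
  expect_equal(f1$p_value, f2$p_value)
})

test_that("coloniser enters as two dummies with 'none' as reference", {
  sim <- simulate_transitions(sim_config(seed = 10))
  fit <- fit_multivariate(sim$data, "protest_led", "coloniser")
  cf <- coef(fit)
  expect_true(all(c("colonisernorthwest_european", "coloniseriberian") %in% names(cf)))
  expect_false("colonisernone" %in% names(cf))
})

test_that("degenerate designs are flagged non-estimable without crashing", {
  sim <- simulate_transitions(sim_config(seed = 11))
  d <- sim$data
  d$constant_col <- 1
  fit <- fit_multivariate(d, "protest_led", "constant_col")
  expect_false(fit$estimable)
  expect_match(fit$reason, "collinearity")
  expect_true(is.na(fit$beta))

  # a duplicate of the predictor is also perfectly collinear
  d$dup <- d$protest_led
  expect_false(fit_multivariate(d, "protest_led", "dup")$estimable)

  # too few complete cases
  d$mostly_na <- NA_real_
  d$mostly_na[1:3] <- rnorm(3)
  expect_false(
    suppressMessages(fit_multivariate(d, "protest_led", "mostly_na"))$estimable)

  # constant predictor is a hard error naming the column
  d2 <- d; d2$violence_led <- 0
  expect_error(fit_bivariate(d2, "violence_led"), "violence_led.*constant")
})

test_that("listwise deletion of incomplete rows is logged", {
  sim <- simulate_transitions(sim_config(seed = 12))
  d <- sim$data
  d$gdp_change_5y[1] <- NA
  expect_message(fit <- fit_multivariate(d, "protest_led", "gdp_change_5y"),
                 "1 case.*dropped")
  expect_equal(fit$n, nrow(d) - 1)
})

test_that("a pure-noise covariate leaves the coefficient unchanged in expectation", {
  deltas <- vapply(1:30, function(s) {
    sim <- simulate_transitions(sim_config(seed = 300 + s))
    d <- sim$data
    set.seed(s)
    d$noise <- rnorm(nrow(d))
    fit_multivariate(d, "protest_led", "noise")$beta -
      fit_bivariate(d, "protest_led")$beta
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 4 * sd(deltas) / sqrt(length(deltas)))
})

test_that("uncertainty propagation collapses to the baseline when widths are 0", {
  d <- toy_dataset(halfwidth = 0)
  # the noiseless fit is exact, so lm warns about a perfect fit
  pu <- suppressWarnings(propagate_uncertainty(d, "protest_led", n_reps = 50, seed = 1))
  base <- suppressWarnings(fit_bivariate(d, "protest_led"))
  expect_equal(pu$p_values, rep(base$p_value, 50), tolerance = 1e-12)
  expect_equal(pu$betas, rep(base$beta, 50), tolerance = 1e-12)
})

test_that("uncertainty propagation is seed-reproducible and matches per-rep OLS", {
  sim <- simulate_transitions(sim_config(seed = 14))
  a <- propagate_uncertainty(sim$data, "violence_led", n_reps = 200, seed = 7)
  b <- propagate_uncertainty(sim$data, "violence_led", n_reps = 200, seed = 7)
  expect_identical(a$p_values, b$p_values)
  expect_equal(a$share_below_05, mean(a$p_values < 0.05))
  expect_equal(length(a$p_values), 200)

  # oracle: replicate the first draw with lm() directly
  set.seed(7)
  hw <- (sim$data$upper95 - sim$data$lower95) / 2
  eps1 <- matrix(rnorm(nrow(sim$data) * 200, 0, hw / 1.96),
                 nrow = nrow(sim$data))[, 1]
  fit1 <- lm(I(point + eps1) ~ violence_led, data = sim$data)
  expect_equal(a$betas[1], unname(coef(fit1)[2]), tolerance = 1e-10)
  expect_equal(a$p_values[1],
               summary(fit1)$coefficients["violence_led", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("narrower intervals shrink the replicate p-value spread", {
  base <- simulate_transitions(sim_config(seed = 15))$data
  wide <- base
  narrow <- base
  narrow$lower95 <- narrow$point - 1e-4
  narrow$upper95 <- narrow$point + 1e-4
  v_wide <- var(propagate_uncertainty(wide, "protest_led", 300, seed = 2)$p_values)
  v_narrow <- var(propagate_uncertainty(narrow, "protest_led", 300, seed = 2)$p_values)
  expect_lt(v_narrow, v_wide)
  expect_error(propagate_uncertainty(base, "protest_led", n_reps = 0), "n_reps")
})

test_that("robust standard errors differ from classical but keep the estimate", {
  sim <- simulate_transitions(sim_config(seed = 16))
  f_cl <- fit_bivariate(sim$data, "protest_led")
  f_rb <- fit_bivariate(sim$data, "protest_led", robust = TRUE)
  expect_equal(f_cl$beta, f_rb$beta)
  expect_false(isTRUE(all.equal(f_cl$se, f_rb$se)))
})
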