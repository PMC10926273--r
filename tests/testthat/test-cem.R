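test_that("coarsening assigns identical cases to the same stratum", {
  d <- data.frame(gdp_pc = c(1000, 1000, 9000), u5mr_at_transition = c(50, 50, 200),
                  pct_years_democracy = c(10, 10, 60))
  lab <- coarsen(d)
  expect_identical(lab[1], lab[2])
  expect_false(lab[1] == lab[3])
})

test_that("Sturges coarsening yields ceiling(log2(n)) + 1 bins at n = 51", {
  sim <- simulate_transitions(sim_config(seed = 31))
  lab <- coarsen(sim$data, "gdp_pc")
  expect_equal(length(attr(lab, "scheme")$gdp_pc) - 1, 7)  # 7 bins -> 8 edges
})

test_that("a binary split at the median produces two strata", {
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12))
  lab <- coarsen(d, "x", method = "fixed_edges",
                 edges = list(x = c(0, median(d$x), 13)))
  expect_equal(nlevels(lab), 2)
  expect_identical(as.integer(lab), c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("edge validation catches bad schemes and out-of-range cases", {
  d <- data.frame(x = c(1, 5, 9))
  expect_error(coarsen(d, "x", method = "fixed_edges", edges = list(x = c(3, 2, 10))),
               "strictly increasing")
  expect_error(coarsen(d, "x", method = "fixed_edges", edges = list(x = c(2, 6, 10))),
               "outside bin range.*x")
  expect_error(coarsen(d, "missing_col"), "not in data")
  d$x[2] <- NA
  expect_error(coarsen(d, "x"), "missing values")
})

test_that("CEM weights satisfy the stratum weight identity", {
  sim <- simulate_transitions(sim_config(seed = 32))
  cm <- cem_match(sim$data, "protest_led", method = "quantile", bins = 2)
  tr <- sim$data$protest_led
  for (s in levels(cm$strata)) {
    idx <- cm$strata == s
    if (any(cm$weights[idx] > 0)) {
      expect_equal(sum(cm$weights[idx & tr == 0]), sum(idx & tr == 1))
      expect_true(all(cm$weights[idx & tr == 1] == 1))
    }
  }
  expect_equal(cm$n_matched + cm$n_pruned, nrow(sim$data))
  # weighted L1 imbalance on the coarsened covariates is 0 among retained cases
  expect_equal(cm$imbalance, 0, tolerance = 1e-12)
})

test_that("strata lacking a treatment level are pruned; single-level data error", {
  d <- toy_dataset(n_protest = 4, n_violent = 4, n_other = 0)
  d$x <- c(1, 1, 2, 2, 1, 1, 1, 1)  # stratum 2 holds only protest-led cases
  lab <- coarsen(d, "x", method = "fixed_edges", edges = list(x = c(0, 1.5, 3)))
  cm <- suppressWarnings(cem_match(d, "protest_led", labels = lab))  # exact toy fit
  expect_equal(cm$n_pruned, 2)
  expect_true(all(cm$weights[d$x == 2] == 0))

  d1 <- d; d1$protest_led <- 1; d1$violence_led <- 0
  expect_error(cem_match(d1, "protest_led"), "both treatment levels")
  # all strata pruned: treated and controls never share a stratum
  d2 <- d
  d2$x <- ifelse(d2$protest_led == 1, 1, 2)
  lab2 <- coarsen(d2, "x", method = "fixed_edges", edges = list(x = c(0, 1.5, 3)))
  expect_error(cem_match(d2, "protest_led", labels = lab2), "coarser bins")
})

test_that("one all-inclusive stratum reproduces the bivariate OLS estimate exactly", {
  sim <- simulate_transitions(sim_config(seed = 33))
  lab <- coarsen(sim$data, "gdp_pc", method = "fixed_edges",
                 edges = list(gdp_pc = c(0, 1e6)))
  cm <- cem_match(sim$data, "protest_led", labels = lab)
  expect_equal(cm$n_pruned, 0)
  expect_equal(cm$estimate$beta, fit_bivariate(sim$data, "protest_led")$beta,
               tolerance = 1e-12)
})

test_that("matching moves a confounded estimate toward the generator truth", {
  errs <- vapply(1:12, function(s) {
    cfg <- sim_config(confound_treat = 2, confound_outcome = 0.025,
                      effect_sd = 0.01, seed = 600 + s)
    sim <- simulate_transitions(cfg)
    truth <- implied_contrast(cfg, "protest_led")
    raw <- fit_bivariate(sim$data, "protest_led")$beta
    cm <- cem_match(sim$data, "protest_led", covariates = "u5mr_at_transition",
                    method = "quantile", bins = 4)
    c(abs(raw - truth), abs(cm$estimate$beta - truth))
  }, numeric(2))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})
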