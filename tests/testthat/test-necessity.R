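test_that("outcomes are classified by whether the interval excludes zero", {
  # Grenada-style estimate: 0.043 [0.028, 0.057] is higher-than-expected
  expect_identical(classify_outcome(0.028, 0.057), "higher")
  expect_identical(classify_outcome(-0.01, 0.01), "null")
  expect_identical(classify_outcome(-0.03, -0.01), "lower")
  # boundary: an interval touching zero still contains it
  expect_identical(classify_outcome(0, 0.01), "null")
  expect_identical(classify_outcome(-0.01, 0), "null")
  expect_error(classify_outcome(NaN, 1), "finite")
  expect_error(classify_outcome(0.02, 0.01), "exceeds")
  # data-frame interface classifies each row
  d <- toy_dataset(halfwidth = 0.001)
  expect_identical(classify_outcome(d),
                   ifelse(d$point > 0.001, "higher",
                          ifelse(d$point < -0.001, "lower", "null")))
})

test_that("classification tables reproduce the published 2x2 cells", {
  fx <- transition_fixture()
  t4 <- classification_table(fx, "protest_led", "higher")
  expect_equal(t4$n_condition, 33)
  expect_equal(t4$n_deviant, 2)
  expect_setequal(t4$cells$condition_violating, c("ARG", "CHL"))
  expect_equal(unname(t4$counts), matrix(c(31, 13, 2, 5), 2, byrow = TRUE))
  expect_equal(sum(t4$counts), 51)

  t5 <- classification_table(fx, "violence_led", "lower")
  expect_equal(t5$n_condition, 14)
  expect_equal(t5$n_deviant, 2)
  expect_setequal(t5$cells$condition_violating, c("ROM", "SLE"))
  expect_equal(unname(t5$counts), matrix(c(12, 22, 2, 15), 2, byrow = TRUE))

  # country lists are disjoint and exhaustive
  for (tb in list(t4, t5)) {
    all_countries <- unname(unlist(tb$cells))
    expect_equal(sort(all_countries), sort(fx$country))
  }
})

test_that("tables can be built from intervals when no outcome_class is shipped", {
  d <- toy_dataset(n_protest = 3, n_violent = 2, n_other = 1,
                   mean_protest = -0.02, mean_violent = 0.03, halfwidth = 0.005)
  tb <- classification_table(d, "violence_led", "lower")
  expect_equal(tb$n_condition, 2)
  expect_equal(tb$n_deviant, 0)
  d0 <- d; d0$violence_led <- 0
  expect_warning(classification_table(d0, "violence_led", "lower"), "no case")
})

test_that("one-sided exact lower bound matches closed forms and printed values", {
  # x = 1: the tail inverts in closed form to 1 - (1 - alpha)^(1/n)
  expect_equal(binomial_lower_bound(1, 10), 1 - 0.95^(1 / 10), tolerance = 1e-12)
  expect_equal(binomial_lower_bound(0, 33), 0)
  # the two published bounds, to 4 decimal places
  expect_equal(round(binomial_lower_bound(2, 33), 4), 0.0109)
  expect_equal(round(binomial_lower_bound(2, 14), 3), 0.026)
  expect_error(binomial_lower_bound(5, 4), "x <= n")
  expect_error(binomial_lower_bound(1, 0), "n must be")
  expect_error(binomial_lower_bound(1, 10, alpha = 1), "alpha")
})

test_that("exact bound agrees with the bisection oracle for all x <= n <= 60", {
  for (n in c(1:15, 20, 33, 47, 60)) {
    x <- 0:n
    oracle <- vapply(x, bisect_lower_bound, numeric(1), n = n)
    expect_equal(binomial_lower_bound(x, n), oracle, tolerance = 1e-6)
  }
})

test_that("bound is monotone in x and n, and the tail round-trips to alpha", {
  for (n in c(10, 33)) {
    bounds <- binomial_lower_bound(0:n, n)
    expect_true(all(diff(bounds) > 0))
  }
  expect_true(all(diff(binomial_lower_bound(2, 10:60)) < 0))
  for (x in c(1, 2, 5)) {
    b <- binomial_lower_bound(x, 33)
    expect_equal(pbinom(x - 1, 33, b, lower.tail = FALSE), 0.05, tolerance = 1e-9)
  }
})

test_that("the necessity decision compares the bound to the error rate", {
  fx <- transition_fixture()
  t4 <- classification_table(fx, "protest_led", "higher")
  res <- necessity_test(t4, assumed_error_rate = 0.02)
  expect_equal(res$p_hat, 2 / 33)
  expect_equal(round(res$lower_bound, 4), 0.0109)
  expect_identical(res$decision, "cannot_reject_necessity")

  t5 <- classification_table(fx, "violence_led", "lower")
  res5 <- necessity_test(t5, assumed_error_rate = 0.03)
  expect_equal(round(res5$lower_bound, 3), 0.026)
  expect_identical(res5$decision, "cannot_reject_necessity")

  # many deviant cases: the bound clears any low error rate
  res_many <- necessity_test(c(10, 20), assumed_error_rate = 0.02)
  expect_gt(res_many$lower_bound, 0.02)
  expect_identical(res_many$decision, "reject_necessity")
  expect_error(necessity_test(c(0, 0)), "no case has the condition")
  expect_error(necessity_test(c(1, 10), assumed_error_rate = 2), "error_rate")
})

test_that("necessity results print the proportion-and-percent format", {
  fx <- transition_fixture()
  res <- necessity_test(classification_table(fx, "protest_led", "higher"))
  out <- paste(capture.output(print(res)), collapse = "\n")
  expect_match(out, "0.0109 (1.09%)", fixed = TRUE)
  expect_match(out, "0.0606 (6.06%)", fixed = TRUE)
})
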