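# Small deterministic transition datasets used across tests.

# n cases with given group means and no noise: estimates equal the group mean,
# intervals have the given half-width.
toy_dataset <- function(n_protest = 6, n_violent = 3, n_other = 2,
                        mean_protest = -0.017, mean_violent = 0.02,
                        mean_other = 0, halfwidth = 0.01) {
  n <- n_protest + n_violent + n_other
  group <- rep(c("protest", "violent", "other"), c(n_protest, n_violent, n_other))
  point <- rep(c(mean_protest, mean_violent, mean_other),
               c(n_protest, n_violent, n_other))
  validate_transition_data(data.frame(
    country = sprintf("T%02d", seq_len(n)),
    protest_led = as.integer(group == "protest"),
    violence_led = as.integer(group == "violent"),
    point = point, lower95 = point - halfwidth, upper95 = point + halfwidth,
    stringsAsFactors = FALSE))
}

# brute-force group-mean difference, the oracle for the bivariate coefficient
group_mean_diff <- function(data, predictor) {
  mean(data$point[data[[predictor]] == 1]) - mean(data$point[data[[predictor]] == 0])
}

# bisection on the exact binomial upper tail: the independent oracle for the
# Clopper-Pearson one-sided lower bound (p solving P(X >= x | n, p) = alpha)
bisect_lower_bound <- function(x, n, alpha = 0.05, tol = 1e-12) {
  if (x == 0) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbinom(x - 1, n, mid, lower.tail = FALSE) < alpha) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
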