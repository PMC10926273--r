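#' Bivariate regression of mortality deviations on movement type
#'
#' Ordinary least squares of the country-specific deviation point estimates on
#' a binary movement indicator. With a single binary regressor the coefficient
#' is exactly the difference in group means. Classical standard errors by
#' default; a heteroskedasticity-robust (HC1) switch is available.
#'
#' @param data A `transition_data` frame with `point` and the predictor column.
#' @param predictor `"protest_led"` or `"violence_led"`.
#' @param robust Use HC1 robust standard errors (default `FALSE`: classical,
#'   matching the headline presentation).
#' @return An object of class `effect_fit` with elements `beta`, `se`,
#'   `p_value`, `r_squared`, `n`, `predictor`, `covariates` (empty), and the
#'   underlying `lm` fit.
#' @export
fit_bivariate <- function(data, predictor = c("protest_led", "violence_led"),
                          robust = FALSE) {
  predictor <- match.arg(predictor)
  fit_multivariate(data, predictor, covariates = character(0), robust = robust)
}

#' Multivariate regression of mortality deviations on movement type
#'
#' Adds adjustment covariates to the bivariate model. `coloniser` enters as a
#' factor with `none` as the reference (two dummies). Rows with missing values
#' in any used column are dropped listwise and the drop is logged. Perfectly
#' collinear designs, or designs with fewer complete cases than parameters + 1,
#' are returned flagged `estimable = FALSE` rather than raising an error, so
#' that specification sweeps can consume them.
#'
#' @inheritParams fit_bivariate
#' @param covariates Character vector of covariate names (subset of
#'   [transition_covariates()], or other numeric columns present in `data`).
#' @return An `effect_fit`; if the design is degenerate its `estimable` field
#'   is `FALSE` and `beta`/`se`/`p_value` are `NA`.
#' @export
fit_multivariate <- function(data, predictor = c("protest_led", "violence_led"),
                             covariates = character(0), robust = FALSE) {
  predictor <- match.arg(predictor)
  validate_transition_data(data)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0)
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  if (length(unique(data[[predictor]])) < 2)
    stop("predictor '", predictor, "' is constant; both levels required",
         call. = FALSE)
  used <- c("point", predictor, covariates)
  d <- complete_for(as.data.frame(data), used, quiet = TRUE)
  n_dropped <- nrow(data) - nrow(d)
  if (n_dropped > 0)
    message(n_dropped, " case(s) dropped listwise (missing covariates)")
  if ("coloniser" %in% covariates)
    d$coloniser <- factor(d$coloniser, levels = .coloniser_levels)

  not_estimable <- function(reason) {
    structure(list(predictor = predictor, beta = NA_real_, se = NA_real_,
                   p_value = NA_real_, r_squared = NA_real_, n = nrow(d),
                   covariates = covariates, estimable = FALSE, reason = reason,
                   robust = robust, fit = NULL),
              class = "effect_fit")
  }

  form <- stats::reformulate(c(predictor, covariates), response = "point")
  n_par <- 2L + length(setdiff(covariates, "coloniser")) +
    if ("coloniser" %in% covariates) 2L else 0L
  if (nrow(d) < n_par + 1) return(not_estimable("insufficient complete cases"))
  if (nrow(d) < 3) stop("need at least 3 cases", call. = FALSE)
  if (length(unique(d[[predictor]])) < 2)
    return(not_estimable("predictor constant among complete cases"))

  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit)))
    return(not_estimable("perfect collinearity among regressors"))

  vc <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  structure(list(predictor = predictor,
                 beta = unname(ct[predictor, "Estimate"]),
                 se = unname(ct[predictor, "Std. Error"]),
                 p_value = unname(ct[predictor, "Pr(>|t|)"]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d), covariates = covariates,
                 estimable = TRUE, reason = NULL, robust = robust, fit = fit),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("Effect regression (%s): not estimable (%s)\n", x$predictor, x$reason))
    return(invisible(x))
  }
  stars <- if (x$p_value < 0.01) "**" else if (x$p_value < 0.05) "*" else ""
  cat(sprintf("Effect of %s on deviation of log child mortality:\n", x$predictor))
  cat(sprintf("  beta = %.4g%s (SE %.4g, p = %.3g), n = %d, R^2 = %.2f\n",
              x$beta, stars, x$se, x$p_value, x$n, x$r_squared))
  if (length(x$covariates) > 0)
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.effect_fit <- function(object, ...) {
  if (is.null(object$fit)) return(NA_real_)
  stats::coef(object$fit)
}

#' @export
summary.effect_fit <- function(object, ...) {
  if (is.null(object$fit)) return(object)
  summary(object$fit)
}

#' @export
residuals.effect_fit <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::residuals(object$fit)
}

#' Propagate credible-interval uncertainty through the bivariate regression
#'
#' Re-estimates the bivariate regression `n_reps` times, each time adding a
#' normally distributed, country-specific error to the dependent variable with
#' SD equal to each country's 95%-interval half-width divided by 1.96 (so the
#' injected noise replicates the reported intervals under a symmetric-normal
#' reading). Collects the replicate p-values for the movement coefficient and
#' reports the share below 0.05. All replicates share one fixed design matrix,
#' so the replicate fits are computed in a single least-squares solve.
#'
#' @inheritParams fit_bivariate
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return An object of class `uncertainty_propagation` with the replicate
#'   `p_values` and `betas`, `share_below_05`, `n_reps`, `seed`, and the
#'   baseline point-estimate fit.
#' @export
propagate_uncertainty <- function(data, predictor = c("protest_led", "violence_led"),
                                  n_reps = 1000, seed = 1L) {
  predictor <- match.arg(predictor)
  validate_transition_data(data)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  hw <- (data$upper95 - data$lower95) / 2
  if (any(!is.finite(hw)) || any(hw < 0))
    stop("interval bounds must be finite with non-negative width", call. = FALSE)
  sd_i <- hw / 1.96
  n <- nrow(data)
  set.seed(as.integer(seed))

  X <- cbind(1, data[[predictor]])
  qrX <- qr(X)
  XtXinv22 <- chol2inv(qr.R(qrX))[2, 2]
  eps <- matrix(stats::rnorm(n * n_reps, 0, sd_i), nrow = n)  # sd recycles by row
  Y <- data$point + eps
  B <- qr.coef(qrX, Y)                       # 2 x n_reps
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / (n - 2)
  se <- sqrt(sigma2 * XtXinv22)
  tval <- B[2, ] / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)

  structure(list(predictor = predictor, n_reps = as.integer(n_reps),
                 betas = unname(B[2, ]), p_values = unname(p),
                 share_below_05 = mean(p < 0.05), seed = as.integer(seed),
                 baseline = fit_bivariate(data, predictor)),
            class = "uncertainty_propagation")
}

#' @export
print.uncertainty_propagation <- function(x, ...) {
  cat(sprintf("Uncertainty propagation (%s): %d replicates\n", x$predictor, x$n_reps))
  cat(sprintf("  baseline beta = %.4g (p = %.3g)\n", x$baseline$beta, x$baseline$p_value))
  cat(sprintf("  share of replicate p-values < 0.05: %.1f%%\n", 100 * x$share_below_05))
  invisible(x)
}

#' Kernel-density view of the replicate p-values
#'
#' @param x An [propagate_uncertainty()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.uncertainty_propagation <- function(x, ...) {
  dens <- stats::density(x$p_values, from = 0, to = max(x$p_values))
  graphics::plot(dens, main = sprintf("Replicate p-values (%s)", x$predictor),
                 xlab = "p-value", ...)
  graphics::abline(v = 0.05, lty = 2)
  invisible(x)
}
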