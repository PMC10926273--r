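#' Enumerate all covariate-subset specifications
#'
#' All `2^K` subsets of `K` candidate covariates, including the empty subset
#' (the bivariate model), in a deterministic order: by subset size, then
#' lexicographically within size.
#'
#' @param covariates Character vector of unique covariate names.
#' @return A list of character vectors (the first is `character(0)`).
#' @export
enumerate_specifications <- function(covariates) {
  if (anyDuplicated(covariates))
    stop("duplicate covariate names", call. = FALSE)
  K <- length(covariates)
  if (K == 0) return(list(character(0)))
  subsets <- list(character(0))
  for (size in seq_len(K)) {
    combs <- utils::combn(sort(covariates), size, simplify = FALSE)
    ord <- order(vapply(combs, paste, character(1), collapse = "\r"))
    subsets <- c(subsets, combs[ord])
  }
  subsets
}

#' Multiverse analysis over all covariate subsets
#'
#' Fits the movement-type regression under every covariate subset (the full
#' specification curve: `2^K` models for `K` candidates) and summarises
#' robustness: sign stability (share of estimable models whose coefficient has
#' the preferred estimate's sign), significance rates at p < 0.05 and p < 0.1,
#' and the robustness ratio — the preferred (bivariate) estimate divided by a
#' spread measure of the estimates across all models. The default denominator
#' is the Young-Holsteen total standard error,
#' `sqrt(mean(se^2) + var(beta))`, combining average sampling variance with
#' between-model variance; `denominator = "sd-of-estimates"` uses the plain SD
#' of the coefficients instead. Non-estimable specifications are excluded from
#' the summaries and counted.
#'
#' @inheritParams fit_multivariate
#' @param covariates Candidate covariates (default: all eight in
#'   [transition_covariates()]).
#' @param denominator `"total-se"` (Young-Holsteen, default) or
#'   `"sd-of-estimates"`.
#' @return An object of class `multiverse_result`: `per_model` (one row per
#'   specification with indicator columns, beta, se, p, estimable flag),
#'   `sign_stability`, `sig_rate_05`, `sig_rate_10`, `robustness_ratio`,
#'   `preferred` (the bivariate `effect_fit`), `n_models`, `n_estimable`.
#' @export
run_multiverse <- function(data, predictor = c("protest_led", "violence_led"),
                           covariates = transition_covariates(),
                           denominator = c("total-se", "sd-of-estimates"),
                           robust = FALSE) {
  predictor <- match.arg(predictor)
  denominator <- match.arg(denominator)
  validate_transition_data(data)
  covariates <- intersect(covariates, names(data))
  specs <- enumerate_specifications(covariates)

  fits <- suppressMessages(
    lapply(specs, function(cs) fit_multivariate(data, predictor, cs, robust = robust)))
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  se <- vapply(fits, `[[`, numeric(1), "se")
  p <- vapply(fits, `[[`, numeric(1), "p_value")
  estimable <- vapply(fits, `[[`, logical(1), "estimable")
  if (!any(estimable)) stop("no estimable specification", call. = FALSE)

  ind <- vapply(covariates, function(cv)
    vapply(specs, function(cs) cv %in% cs, logical(1)), logical(length(specs)))
  per_model <- data.frame(spec_id = seq_along(specs),
                          n_covariates = lengths(specs))
  if (length(covariates) > 0) per_model <- cbind(per_model, ind)
  per_model$beta <- beta
  per_model$se <- se
  per_model$p_value <- p
  per_model$estimable <- estimable

  preferred <- fits[[1]]  # empty subset: the bivariate model
  b <- beta[estimable]
  s <- se[estimable]
  pe <- p[estimable]
  between_var <- if (length(b) > 1) stats::var(b) else 0
  denom <- switch(denominator,
                  "total-se" = sqrt(mean(s^2) + between_var),
                  "sd-of-estimates" = sqrt(between_var))
  structure(list(predictor = predictor, covariates = covariates,
                 per_model = per_model,
                 n_models = length(specs), n_estimable = sum(estimable),
                 sign_stability = 100 * mean(sign(b) == sign(preferred$beta)),
                 sig_rate_05 = 100 * mean(pe < 0.05),
                 sig_rate_10 = 100 * mean(pe < 0.1),
                 robustness_ratio = preferred$beta / denom,
                 denominator = denominator, preferred = preferred),
            class = "multiverse_result")
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat(sprintf("Multiverse analysis (%s): %d specifications over %d covariates (%d estimable)\n",
              x$predictor, x$n_models, length(x$covariates), x$n_estimable))
  cat(sprintf("  preferred (bivariate) beta = %.4g\n", x$preferred$beta))
  cat(sprintf("  sign stability        %.0f%%\n", x$sign_stability))
  cat(sprintf("  significance (p<0.05) %.0f%%\n", x$sig_rate_05))
  cat(sprintf("  significance (p<0.1)  %.0f%%\n", x$sig_rate_10))
  cat(sprintf("  robustness ratio      %.2f  (denominator: %s)\n",
              x$robustness_ratio, x$denominator))
  invisible(x)
}

#' @export
summary.multiverse_result <- function(object, ...) {
  pm <- object$per_model[object$per_model$estimable, ]
  structure(list(result = object,
                 beta_quantiles = stats::quantile(pm$beta, c(0, .25, .5, .75, 1))),
            class = "summary.multiverse_result")
}

#' @export
print.summary.multiverse_result <- function(x, ...) {
  print(x$result)
  cat("  beta quantiles across estimable models:\n")
  print(round(x$beta_quantiles, 5))
  invisible(x)
}

#' Specification-curve plot
#'
#' Estimable specifications ordered by coefficient, with pointwise 95%
#' confidence bars; the dashed line marks zero and the solid line the
#' preferred (bivariate) estimate.
#'
#' @param x A [run_multiverse()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.multiverse_result <- function(x, ...) {
  pm <- x$per_model[x$per_model$estimable, ]
  ord <- order(pm$beta)
  b <- pm$beta[ord]; s <- pm$se[ord]
  idx <- seq_along(b)
  graphics::plot(idx, b, pch = 16, cex = 0.5,
                 ylim = range(b - 1.96 * s, b + 1.96 * s),
                 xlab = "specification (ordered by estimate)",
                 ylab = sprintf("coefficient on %s", x$predictor), ...)
  graphics::segments(idx, b - 1.96 * s, idx, b + 1.96 * s, col = "grey60")
  graphics::points(idx, b, pch = 16, cex = 0.5)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(h = x$preferred$beta, col = 2)
  invisible(x)
}
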