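#' Coarsen covariates into stratum signatures
#'
#' Bins each matching covariate and assigns every case the tuple of its bin
#' indices: cases sharing a signature are exact matches on the coarsened
#' covariates. Continuous covariates use Sturges bins by default
#' (`ceiling(log2(n)) + 1` equal-width bins over the observed range, 7 bins at
#' n = 51); alternatively quantile bins or user-supplied edges. Categorical
#' and binary covariates use their levels as-is.
#'
#' @param data A data frame containing the matching covariates.
#' @param covariates Covariate names to match on (default
#'   `gdp_pc`, `u5mr_at_transition`, `pct_years_democracy`).
#' @param method `"sturges"` (default), `"quantile"`, or `"fixed_edges"`.
#' @param edges For `method = "fixed_edges"`: a named list of strictly
#'   increasing numeric edge vectors spanning each covariate's values.
#' @param bins Number of bins for `"quantile"` (default: the Sturges count).
#' @return A factor of stratum labels, one per row, with the bin definitions
#'   in attribute `"scheme"`.
#' @export
coarsen <- function(data, covariates = c("gdp_pc", "u5mr_at_transition",
                                         "pct_years_democracy"),
                    method = c("sturges", "quantile", "fixed_edges"),
                    edges = NULL, bins = NULL) {
  method <- match.arg(method)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0)
    stop("matching covariate(s) not in data: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  n <- nrow(data)
  n_bins <- if (is.null(bins)) ceiling(log2(n)) + 1 else bins
  scheme <- list()
  sig <- vector("list", length(covariates))
  for (k in seq_along(covariates)) {
    cv <- covariates[k]
    x <- data[[cv]]
    if (anyNA(x))
      stop("missing values in matching covariate '", cv, "'", call. = FALSE)
    if (is.numeric(x) && length(unique(x)) > 2) {
      br <- switch(method,
                   sturges = seq(min(x), max(x), length.out = n_bins + 1),
                   quantile = unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))),
                   fixed_edges = {
                     if (is.null(edges[[cv]]))
                       stop("no edges supplied for '", cv, "'", call. = FALSE)
                     edges[[cv]]
                   })
      if (any(diff(br) <= 0))
        stop("bin edges for '", cv, "' must be strictly increasing", call. = FALSE)
      if (min(x) < br[1] || max(x) > br[length(br)])
        stop("case outside bin range for covariate '", cv, "' (row ",
             which(x < br[1] | x > br[length(br)])[1], ")", call. = FALSE)
      b <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
      scheme[[cv]] <- br
      sig[[k]] <- b
    } else {
      f <- factor(x)
      scheme[[cv]] <- levels(f)
      sig[[k]] <- as.integer(f)
    }
  }
  lab <- do.call(paste, c(sig, sep = "."))
  out <- factor(lab)
  attr(out, "scheme") <- scheme
  out
}

#' Coarsened exact matching and weighted effect estimation
#'
#' Assigns cases to coarsened strata, prunes strata lacking either treatment
#' level, and computes the standard CEM weights: treated cases get weight 1;
#' control cases in stratum *s* get weight `treated_s / control_s`, so the
#' control weights in each retained stratum sum to that stratum's treated
#' count. The movement-type effect is then re-estimated by weighted least
#' squares over the retained cases, with heteroskedasticity-robust (HC1)
#' standard errors since the weights induce heteroskedasticity.
#'
#' @inheritParams fit_bivariate
#' @param treatment `"protest_led"` or `"violence_led"`.
#' @param covariates Matching covariates, passed to [coarsen()].
#' @param labels Optional precomputed stratum labels (bypasses [coarsen()]).
#' @param ... Further arguments to [coarsen()] (`method`, `edges`, `bins`).
#' @return An object of class `cem_match`: per-case `weights` (0 for pruned
#'   cases) and `strata`, `n_matched`, `n_pruned`, the weighted `estimate`
#'   (beta, robust SE, p), and the multivariate L1 imbalance on the coarsened
#'   covariates among retained cases (0 by construction).
#' @export
cem_match <- function(data, treatment = c("protest_led", "violence_led"),
                      covariates = c("gdp_pc", "u5mr_at_transition",
                                     "pct_years_democracy"),
                      labels = NULL, ...) {
  treatment <- match.arg(treatment)
  validate_transition_data(data)
  tr <- data[[treatment]]
  if (length(unique(tr)) < 2)
    stop("both treatment levels required", call. = FALSE)
  if (is.null(labels)) labels <- coarsen(data, covariates, ...)
  stopifnot(length(labels) == nrow(data))

  n_t <- tapply(tr == 1, labels, sum)
  n_c <- tapply(tr == 0, labels, sum)
  retained_strata <- names(n_t)[n_t > 0 & n_c > 0]
  if (length(retained_strata) == 0)
    stop("every stratum was pruned; use coarser bins", call. = FALSE)

  w <- numeric(nrow(data))
  keep <- as.character(labels) %in% retained_strata
  w[keep & tr == 1] <- 1
  for (s in retained_strata) {
    idx <- keep & tr == 0 & as.character(labels) == s
    w[idx] <- n_t[[s]] / n_c[[s]]
  }

  d <- as.data.frame(data)[keep, , drop = FALSE]
  fit <- stats::lm(stats::reformulate(treatment, "point"), data = d,
                   weights = w[keep])
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC1"))
  est <- list(beta = unname(ct[treatment, "Estimate"]),
              se = unname(ct[treatment, "Std. Error"]),
              p_value = unname(ct[treatment, "Pr(>|t|)"]))

  structure(list(treatment = treatment, covariates = covariates,
                 strata = labels, weights = w,
                 n_matched = sum(keep), n_pruned = sum(!keep),
                 n_strata = length(retained_strata),
                 estimate = est, fit = fit,
                 imbalance = cem_imbalance(labels[keep], tr[keep], w[keep])),
            class = "cem_match")
}

#' Multivariate L1 imbalance on coarsened strata
#'
#' Half the sum of absolute differences between the treated and (weighted)
#' control distributions over strata. Zero means the coarsened covariate
#' distributions coincide exactly; CEM weighting makes it zero by construction
#' among retained cases.
#'
#' @param labels Stratum labels.
#' @param treated 0/1 treatment vector.
#' @param weights Case weights (default all 1: the unweighted imbalance).
#' @return A single number in \[0, 1\].
#' @export
cem_imbalance <- function(labels, treated, weights = rep(1, length(labels))) {
  stopifnot(length(labels) == length(treated), length(weights) == length(labels))
  wt <- weights * (treated == 1)
  wc <- weights * (treated == 0)
  ft <- tapply(wt, labels, sum, default = 0) / sum(wt)
  fc <- tapply(wc, labels, sum, default = 0) / sum(wc)
  0.5 * sum(abs(ft - fc))
}

#' @export
print.cem_match <- function(x, ...) {
  cat(sprintf("Coarsened exact matching on %s:\n  matched %d, pruned %d (%d strata retained)\n",
              paste(x$covariates, collapse = ", "),
              x$n_matched, x$n_pruned, x$n_strata))
  cat(sprintf("  weighted effect of %s: beta = %.4g (robust SE %.4g, p = %.3g)\n",
              x$treatment, x$estimate$beta, x$estimate$se, x$estimate$p_value))
  cat(sprintf("  L1 imbalance after weighting: %.3g\n", x$imbalance))
  invisible(x)
}

#' @export
coef.cem_match <- function(object, ...) stats::coef(object$fit)
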