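#' Classify each country's mortality outcome from its interval
#'
#' `higher` if the 95% interval lies strictly above zero (lower bound > 0),
#' `lower` if strictly below (upper bound < 0), `null` if the interval
#' contains zero.
#'
#' @param lower95,upper95 Numeric vectors of interval bounds (or a
#'   `transition_data` frame as the first argument, in which case its bound
#'   columns are used).
#' @return A character vector of `"higher"` / `"lower"` / `"null"`.
#' @export
classify_outcome <- function(lower95, upper95 = NULL) {
  if (is.data.frame(lower95)) {
    upper95 <- lower95$upper95
    lower95 <- lower95$lower95
  }
  if (any(!is.finite(lower95)) || any(!is.finite(upper95)))
    stop("interval bounds must be finite", call. = FALSE)
  if (any(lower95 > upper95))
    stop("lower95 exceeds upper95", call. = FALSE)
  ifelse(lower95 > 0, "higher", ifelse(upper95 < 0, "lower", "null"))
}

#' Build a movement-type by outcome-direction classification table
#'
#' Cross-classifies the cases by presence of the condition (a movement-type
#' flag) and by whether they show the hypothesis-violating outcome. The
#' deviant cell holds condition-present cases with the violating outcome —
#' e.g. protest-led transitions followed by higher-than-expected child
#' mortality. Cases whose interval contains zero count as
#' "not higher-/not lower-than-expected", i.e. non-deviant.
#'
#' @param data A `transition_data` frame carrying either an `outcome_class`
#'   column or `lower95`/`upper95` bounds (classified on the fly).
#' @param condition `"protest_led"` or `"violence_led"`.
#' @param violating The outcome direction that would contradict necessity:
#'   `"higher"` (natural for protest-led) or `"lower"` (for violence-led).
#' @return An object of class `classification_table` with the 2x2 `counts`,
#'   per-cell country lists, `n_condition`, and `n_deviant`.
#' @export
classification_table <- function(data,
                                 condition = c("protest_led", "violence_led"),
                                 violating = c("higher", "lower")) {
  condition <- match.arg(condition)
  violating <- match.arg(violating)
  validate_transition_data(data, require_estimates = FALSE)
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  oc <- if ("outcome_class" %in% names(data)) data$outcome_class
  else classify_outcome(data)

  present <- data[[condition]] == 1
  viol <- oc == violating
  cells <- list(
    condition_violating = data$country[present & viol],
    condition_ok = data$country[present & !viol],
    other_violating = data$country[!present & viol],
    other_ok = data$country[!present & !viol])
  counts <- matrix(lengths(cells)[c("condition_ok", "other_ok",
                                    "condition_violating", "other_violating")],
                   nrow = 2, byrow = TRUE,
                   dimnames = list(outcome = c(paste0("not_", violating), violating),
                                   condition = c(condition, paste0("not_", condition))))
  if (sum(present) == 0)
    warning("no case has condition '", condition, "': empty condition column",
            call. = FALSE)
  structure(list(condition = condition, violating = violating,
                 counts = counts, cells = cells,
                 n_condition = sum(present),
                 n_deviant = length(cells$condition_violating),
                 n_total = nrow(data)),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Classification table: %s vs %s-than-expected mortality (N = %d)\n",
              x$condition, x$violating, x$n_total))
  print(x$counts)
  cat(sprintf("Deviant cases (%d of %d with the condition): %s\n",
              x$n_deviant, x$n_condition,
              if (x$n_deviant > 0) paste(x$cells$condition_violating, collapse = ", ")
              else "none"))
  invisible(x)
}

#' One-sided exact binomial lower confidence bound
#'
#' The Clopper-Pearson one-sided lower bound on a binomial proportion: for
#' `x >= 1` deviant cases out of `n`, the proportion `p` solving
#' `P(X >= x | n, p) = alpha`, i.e. the `alpha` quantile of `Beta(x, n - x + 1)`;
#' 0 when `x = 0`. At level 0.05 this is the value the population proportion
#' exceeds with 95% confidence.
#'
#' @param x Deviant-case count.
#' @param n Number of condition-present cases (`n >= 1`).
#' @param alpha One-sided level in (0, 1); default 0.05.
#' @return The lower bound, a proportion in \[0, 1\]. Vectorised over `x`.
#' @export
binomial_lower_bound <- function(x, n, alpha = 0.05) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(x < 0) || any(x > n)) stop("need 0 <= x <= n", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  ifelse(x == 0, 0, stats::qbeta(alpha, x, n - x + 1))
}

#' Test of necessity under measurement error
#'
#' The Braumoeller-Goertz procedure: treat the deviant-case proportion
#' `p_hat = n_deviant / n_condition` as a binomial sample, compute its
#' one-sided exact lower confidence bound, and reject the hypothesis that the
#' condition is necessary only if that lower bound exceeds the assumed
#' classification error rate — i.e. only if there are more deviant cases than
#' measurement error could plausibly account for. The 2% literature benchmark
#' for an "enviably low" error rate is recorded alongside the result.
#'
#' @param table A [classification_table()], or a length-2 numeric
#'   `c(deviant, n_condition)`.
#' @param assumed_error_rate Assumed probability that a case is misclassified
#'   (default 0.02, the literature benchmark; supply your own estimate when
#'   available).
#' @param alpha One-sided level (default 0.05).
#' @return An object of class `necessity_test` with `p_hat`, `lower_bound`,
#'   `assumed_error_rate`, `decision` (`"reject_necessity"` or
#'   `"cannot_reject_necessity"`), `alpha`, and the source table if given.
#' @export
necessity_test <- function(table, assumed_error_rate = 0.02, alpha = 0.05) {
  if (inherits(table, "classification_table")) {
    x <- table$n_deviant
    n <- table$n_condition
    src <- table
  } else if (is.numeric(table) && length(table) == 2) {
    x <- table[1]
    n <- table[2]
    src <- NULL
  } else stop("supply a classification_table or c(deviant, n_condition)",
              call. = FALSE)
  if (n == 0) stop("undefined test: no case has the condition", call. = FALSE)
  if (assumed_error_rate < 0 || assumed_error_rate > 1)
    stop("assumed_error_rate must lie in [0, 1]", call. = FALSE)
  lb <- binomial_lower_bound(x, n, alpha)
  structure(list(p_hat = x / n, lower_bound = lb,
                 n_deviant = x, n_condition = n,
                 assumed_error_rate = assumed_error_rate,
                 benchmark_error_rate = 0.02,
                 alpha = alpha,
                 decision = if (lb > assumed_error_rate) "reject_necessity"
                 else "cannot_reject_necessity",
                 table = src),
            class = "necessity_test")
}

fmt_prop <- function(p) sprintf("%.4f (%.2f%%)", p, 100 * p)

#' @export
print.necessity_test <- function(x, ...) {
  cat("Test of necessity under measurement error\n")
  if (!is.null(x$table))
    cat(sprintf("  condition: %s; violating outcome: %s-than-expected mortality\n",
                x$table$condition, x$table$violating))
  cat(sprintf("  deviant cases: %d of %d; p_hat = %s\n",
              x$n_deviant, x$n_condition, fmt_prop(x$p_hat)))
  cat(sprintf("  one-sided %d%% lower bound: %s\n",
              round(100 * (1 - x$alpha)), fmt_prop(x$lower_bound)))
  cat(sprintf("  assumed error rate: %s (benchmark for 'enviably low': %s)\n",
              fmt_prop(x$assumed_error_rate), fmt_prop(x$benchmark_error_rate)))
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}
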