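#' @keywords internal
"_PACKAGE"

# Canonical column sets shared across the package. `point`, `lower95`, `upper95`
# carry each country's long-run deviation of log under-5 mortality from the
# pre-transition counterfactual trend, with its 95% interval.
.flag_cols <- c("protest_led", "violence_led")
.estimate_cols <- c("point", "lower95", "upper95")
.coloniser_levels <- c("none", "northwest_european", "iberian")

#' Candidate adjustment covariates
#'
#' The eight covariates used by the multivariate and multiverse stages:
#' GDP per capita at transition (constant PPP), 5-year post-transition GDP
#' change (percent), under-5 mortality at transition (per 1000 live births),
#' post-communist indicator, percent of years 1960 to transition spent as a
#' democracy, resource rents 5 years post-transition (percent of GDP), net
#' ODA (percent of GNI), and coloniser (none / northwest European / Iberian).
#'
#' @return Character vector of the eight covariate column names.
#' @export
transition_covariates <- function() {
  c("gdp_pc", "gdp_change_5y", "u5mr_at_transition", "post_communist",
    "pct_years_democracy", "resource_rents", "oda_pct_gni", "coloniser")
}

#' Validate a transition dataset
#'
#' Checks the invariants every downstream stage relies on: movement flags are
#' 0/1 and never both 1 on the same row (protest-led transitions are a species
#' of nonviolent transition, so a case cannot be both protest-led and
#' violence-led); interval bounds bracket the point estimate; mortality at
#' transition is positive; coloniser, when present, uses the three recognised
#' levels. Rows violating an invariant are reported with their row numbers.
#'
#' @param data A data frame of transition cases.
#' @param require_estimates If `TRUE` (default), the `point`/`lower95`/`upper95`
#'   columns must be present and valid; set `FALSE` for classification-only
#'   tables that carry an `outcome_class` column instead.
#' @return `data`, invisibly, with class `transition_data` prepended.
#' @export
validate_transition_data <- function(data, require_estimates = TRUE) {
  stopifnot(is.data.frame(data))
  required <- c("country", .flag_cols)
  if (require_estimates) required <- c(required, .estimate_cols)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("dataset has no rows", call. = FALSE)

  problems <- character(0)
  bad_rows <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems,
                     sprintf("%s (row%s %s)", msg,
                             if (length(idx) > 1) "s" else "",
                             paste(idx, collapse = ", ")))
    }
  }
  for (fl in .flag_cols) {
    if (!is.numeric(data[[fl]]))
      stop("column '", fl, "' must be numeric 0/1", call. = FALSE)
    bad_rows(!data[[fl]] %in% c(0, 1), paste0(fl, " not in {0,1}"))
  }
  bad_rows(data$protest_led == 1 & data$violence_led == 1,
           "protest_led and violence_led both 1")
  bad_rows(duplicated(data$country), "duplicate country code")

  if (require_estimates) {
    for (cl in .estimate_cols) {
      if (!is.numeric(data[[cl]]))
        stop("column '", cl, "' is non-numeric; offending values: ",
             paste(utils::head(data[[cl]][!is.na(data[[cl]])], 3), collapse = ", "),
             call. = FALSE)
    }
    bad_rows(!is.finite(data$point) | !is.finite(data$lower95) |
               !is.finite(data$upper95), "non-finite estimate or bound")
    bad_rows(data$lower95 > data$point | data$point > data$upper95,
             "interval does not bracket point (need lower95 <= point <= upper95)")
  }
  if ("u5mr_at_transition" %in% names(data)) {
    bad_rows(!is.na(data$u5mr_at_transition) & data$u5mr_at_transition <= 0,
             "u5mr_at_transition must be > 0")
  }
  if ("coloniser" %in% names(data)) {
    bad_rows(!is.na(data$coloniser) & !data$coloniser %in% .coloniser_levels,
             paste0("coloniser outside {", paste(.coloniser_levels, collapse = ", "), "}"))
  }
  if ("outcome_class" %in% names(data)) {
    bad_rows(!data$outcome_class %in% c("higher", "lower", "null"),
             "outcome_class outside {higher, lower, null}")
  }
  if (length(problems) > 0) {
    stop("invalid transition dataset:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(data) <- unique(c("transition_data", class(data)))
  invisible(data)
}

#' Read a transition dataset from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and `.` decimals.
#' Column names can be remapped through `schema` (a named character vector,
#' `c(point = "estimate", ...)`, mapping canonical names to file names).
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector renaming file columns to the
#'   canonical schema.
#' @param require_estimates Passed to [validate_transition_data()].
#' @return A validated `transition_data` data frame.
#' @export
read_transition_data <- function(path, schema = NULL, require_estimates = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(data) == 0 && ncol(data) == 0)
    stop("empty file: ", path, call. = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(data))
        stop("schema column '", src, "' not found in ", path, call. = FALSE)
      names(data)[names(data) == src] <- canonical
    }
  }
  out <- validate_transition_data(data, require_estimates = require_estimates)
  # validate_* returns invisibly; reading should return visibly
  out
}

#' Write a transition dataset to CSV
#'
#' Writes with full numeric precision so that `read_transition_data()` on the
#' result reproduces the dataset field for field (round-trip identity).
#'
#' @param data A `transition_data` data frame (or anything passing validation).
#' @param path Output path.
#' @param require_estimates Passed to [validate_transition_data()].
#' @return `path`, invisibly.
#' @export
write_transition_data <- function(data, path, require_estimates = TRUE) {
  validate_transition_data(data, require_estimates = require_estimates)
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  # format() at 17 significant digits keeps doubles exact through the text round-trip
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    out
  })
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' The 51-country movement-type and outcome classification table
#'
#' The packaged classification of 51 democratic transitions: a 3-letter country
#' code, the protest-led and violence-led movement flags, and each country's
#' outcome class (`higher` / `lower` / `null`) — whether post-transition under-5
#' mortality was higher-than-expected, lower-than-expected, or indistinguishable
#' from the pre-transition counterfactual trend (95% interval containing zero).
#' Counts: 33 protest-led (2 of them with higher-than-expected mortality:
#' ARG, CHL), 14 violence-led (2 with lower-than-expected mortality: ROM, SLE).
#'
#' @return A validated `transition_data` data frame with 51 rows and columns
#'   `country`, `protest_led`, `violence_led`, `outcome_class`.
#' @export
transition_fixture <- function() {
  path <- system.file("extdata", "tables_4_5_classifications.csv",
                      package = "demotransit", mustWork = TRUE)
  read_transition_data(path, require_estimates = FALSE)
}

#' @export
print.transition_data <- function(x, ...) {
  cat(sprintf("Transition dataset: %d cases (%d protest-led, %d violence-led)\n",
              nrow(x), sum(x$protest_led), sum(x$violence_led)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# Listwise-complete subset for a model frame; logs the drop count via message().
complete_for <- function(data, cols, quiet = FALSE) {
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (!all(keep) && !quiet) {
    message(sum(!keep), " case(s) dropped listwise (missing covariates)")
  }
  data[keep, , drop = FALSE]
}
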