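#' Exclude incomplete or unrealistic records
#'
#' Mirrors the listwise data-quality screen applied to self-administered
#' questionnaires: a record is dropped if any required field is missing
#' (`"incomplete"`) or if any numeric value falls outside its declared
#' plausibility range (`"unrealistic"`). No imputation is performed.
#'
#' @param data A cohort tibble (see [as_cohort()]).
#' @param schema A [cohort_schema()]; defaults to the schema attached to
#'   `data`. Plausibility bounds come from its `range_lo`/`range_hi` columns.
#' @param required Character vector of fields whose missingness excludes a
#'   record; defaults to all schema variables.
#' @return The retained rows, with a cleaning report attached as attribute
#'   `"cleaning_report"` (retrieve it with [cleaning_report()]).
#' @examples
#' sch <- cohort_schema("glucose", "numeric", range_lo = 40, range_hi = 500)
#' coh <- as_cohort(data.frame(glucose = c(90, NA, 9)), sch)
#' cleaned <- apply_exclusions(coh)
#' cleaning_report(cleaned)
#' @export
apply_exclusions <- function(data, schema = cohort_schema_of(data),
                             required = schema$name) {
  if (is.null(schema)) rlang::abort("no schema attached to data and none supplied")
  validate_schema(schema)
  n_input <- nrow(data)
  exclusions <- list()
  keep <- rep(TRUE, n_input)
  for (r in seq_len(n_input)) {
    reason <- NULL
    miss <- required[purrr::map_lgl(required, function(v) is.na(data[[v]][r]))]
    if (length(miss) > 0) {
      reason <- paste0("incomplete: missing ", paste(miss, collapse = ", "))
    } else {
      for (i in seq_len(nrow(schema))) {
        if (schema$level[i] != "numeric") next
        lo <- schema$range_lo[i]; hi <- schema$range_hi[i]
        if (is.na(lo) && is.na(hi)) next
        val <- data[[schema$name[i]]][r]
        if (is.na(val)) next
        if ((!is.na(lo) && val < lo) || (!is.na(hi) && val > hi)) {
          reason <- paste0("unrealistic: ", schema$name[i], "=", val,
                           " outside [", lo, ", ", hi, "]")
          break
        }
      }
    }
    if (!is.null(reason)) {
      keep[r] <- FALSE
      exclusions[[length(exclusions) + 1]] <-
        tibble::tibble(row_id = data$row_id[r], reason = reason)
    }
  }
  out <- data[keep, , drop = FALSE]
  report <- list(
    n_input = n_input,
    n_retained = nrow(out),
    exclusions = if (length(exclusions) > 0) {
      dplyr::bind_rows(exclusions)
    } else {
      tibble::tibble(row_id = integer(), reason = character())
    }
  )
  stopifnot(report$n_input == report$n_retained + nrow(report$exclusions))
  attr(out, "schema") <- schema
  attr(out, "cleaning_report") <- report
  out
}

#' @rdname apply_exclusions
#' @export
cleaning_report <- function(data) attr(data, "cleaning_report", exact = TRUE)

#' Standardize numeric columns to z scores
#'
#' Centers and scales the named columns to mean 0 and standard deviation 1,
#' so that each variable carries the same weight in distance-based
#' classification. The denominator convention defaults to the sample standard
#' deviation (n - 1), the usual descriptive convention; population scaling
#' (n) is available via `denom`.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric column names; defaults to all
#'   numeric columns.
#' @param denom `"n-1"` (default) or `"n"`: denominator of the variance.
#' @return A tibble of the standardized columns (same names and row order).
#' @examples
#' zscore_columns(data.frame(x = c(0, 2)))  # -1, +1
#' @export
zscore_columns <- function(data, vars = NULL, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  if (is.null(vars)) {
    vars <- names(data)[purrr::map_lgl(data, is.numeric)]
  }
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v) > 0) {
    rlang::abort(paste0("column(s) not found: ", paste(missing_v, collapse = ", ")))
  }
  n <- nrow(data)
  out <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) rlang::abort(paste0("column '", v, "' is not numeric"))
    if (anyNA(x)) rlang::abort(paste0("column '", v, "' contains missing values"))
    s <- sd(x)
    if (denom == "n") s <- s * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0) {
      rlang::abort(paste0("zero variance in column '", v, "'"))
    }
    (x - mean(x)) / s
  })
  tibble::as_tibble(setNames(out, vars))
}
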