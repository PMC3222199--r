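#' Read a cohort CSV against a schema
#'
#' Reads per-respondent records from a delimited text file (RFC-4180 CSV with
#' a header row), validates every value against the declared measurement
#' levels, and coerces columns: nominal variables become factors, ordinal
#' variables ordered factors with the declared category order, numeric
#' variables doubles. Category labels are matched case-sensitively after
#' whitespace trimming. A `row_id` column is added (1..N) if the file does
#' not supply one.
#'
#' @param path Path to the CSV file.
#' @param schema A [cohort_schema()] tibble, or a path to a schema file
#'   readable by [read_schema()].
#' @return A tibble of validated records with a `row_id` column; the schema is
#'   attached as attribute `"schema"`.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) rlang::abort(paste0("cohort file not found: ", path))
  if (is.character(schema)) schema <- read_schema(schema)
  validate_schema(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) rlang::abort("no records: the cohort file has no data rows")
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("cohort file is missing column(s) declared in schema: ",
                        paste(missing_cols, collapse = ", ")))
  }
  as_cohort(raw, schema)
}

#' Validate and coerce a raw record table against a schema
#'
#' @param data A data frame of records; categorical columns may be character
#'   or factor, numeric columns character or numeric.
#' @param schema A [cohort_schema()] tibble.
#' @return A validated tibble with typed columns, `row_id`, and the schema
#'   attached as attribute `"schema"`.
#' @export
as_cohort <- function(data, schema) {
  validate_schema(schema)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) rlang::abort("no records")
  if (!"row_id" %in% names(data)) {
    data <- dplyr::mutate(data, row_id = dplyr::row_number(), .before = 1)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(data)) {
      rlang::abort(paste0("cohort is missing variable '", nm, "'"))
    }
    col <- data[[nm]]
    if (schema$level[i] == "numeric") {
      if (is.character(col)) {
        parsed <- suppressWarnings(as.numeric(trimws(col)))
        bad <- which(!is.na(col) & trimws(col) != "" & is.na(parsed))
        if (length(bad) > 0) {
          rlang::abort(paste0("numeric field '", nm, "' unparsable at row ",
                              data$row_id[bad[1]], ": '", col[bad[1]], "'"))
        }
        parsed[!is.na(col) & trimws(col) == ""] <- NA_real_
        col <- parsed
      }
      data[[nm]] <- as.double(col)
    } else {
      cats <- schema$categories[[i]]
      vals <- trimws(as.character(col))
      vals[!is.na(vals) & vals == ""] <- NA_character_
      unknown <- which(!is.na(vals) & !(vals %in% cats))
      if (length(unknown) > 0) {
        rlang::abort(paste0("unknown category '", vals[unknown[1]],
                            "' for variable '", nm, "' at row ",
                            data$row_id[unknown[1]]))
      }
      data[[nm]] <- factor(vals, levels = cats,
                           ordered = schema$level[i] == "ordinal")
    }
  }
  attr(data, "schema") <- schema
  data
}

#' @rdname read_cohort
#' @param data A cohort tibble (as returned by [read_cohort()] or
#'   [as_cohort()]).
#' @export
write_cohort <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Retrieve the schema attached to a cohort tibble
#' @param data A cohort tibble.
#' @return The `cohort_schema` attribute, or `NULL` if none is attached.
#' @export
cohort_schema_of <- function(data) attr(data, "schema", exact = TRUE)
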