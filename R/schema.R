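#' Build a cohort schema
#'
#' A schema declares, for every questionnaire variable, its measurement level
#' and -- for categorical variables -- the ordered list of admissible category
#' labels. The measurement level drives both validation of raw records and the
#' optimal-scaling transform applied during nonlinear PCA: nominal variables
#' are quantified by the centroid principle, ordinal variables by weighted
#' monotone regression, and numeric variables are simply standardized.
#'
#' @param name Character vector of variable names (unique).
#' @param level Character vector, one of `"nominal"`, `"ordinal"`, `"numeric"`,
#'   recycled to the length of `name`.
#' @param categories List of character vectors giving the admissible category
#'   labels in their declared order (ignored, and must be empty, for numeric
#'   variables). A single vector is recycled.
#' @param units Optional character vector of measurement units (free text).
#' @param range_lo,range_hi Optional numeric plausibility bounds for numeric
#'   variables; values outside `[range_lo, range_hi]` are treated as
#'   unrealistic by [apply_exclusions()].
#' @return A tibble with class `cohort_schema` and columns `name`, `level`,
#'   `categories` (list-column), `units`, `range_lo`, `range_hi`.
#' @examples
#' cohort_schema(
#'   name  = c("smoking", "glucose"),
#'   level = c("ordinal", "numeric"),
#'   categories = list(c("never", "former", "current"), character()),
#'   range_lo = c(NA, 40), range_hi = c(NA, 500)
#' )
#' @export
cohort_schema <- function(name, level,
                          categories = vector("list", length(name)),
                          units = NA_character_,
                          range_lo = NA_real_, range_hi = NA_real_) {
  if (!is.list(categories)) categories <- list(categories)
  schema <- tibble::tibble(
    name = as.character(name),
    level = rep_len(as.character(level), length(name)),
    categories = rep_len(categories, length(name)),
    units = rep_len(as.character(units), length(name)),
    range_lo = rep_len(as.double(range_lo), length(name)),
    range_hi = rep_len(as.double(range_hi), length(name))
  )
  schema$categories <- purrr::map(schema$categories, function(x) {
    if (is.null(x) || length(x) == 0) character() else trimws(as.character(x))
  })
  class(schema) <- c("cohort_schema", class(schema))
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  required <- c("name", "level", "categories")
  missing_cols <- setdiff(required, names(schema))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("schema is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(schema$name)) {
    dup <- unique(schema$name[duplicated(schema$name)])
    rlang::abort(paste0("duplicate variable name(s) in schema: ",
                        paste(dup, collapse = ", ")))
  }
  bad_level <- setdiff(unique(schema$level), c("nominal", "ordinal", "numeric"))
  if (length(bad_level) > 0) {
    rlang::abort(paste0("unknown measurement level(s): ",
                        paste(bad_level, collapse = ", ")))
  }
  for (i in seq_len(nrow(schema))) {
    lev <- schema$level[i]; cats <- schema$categories[[i]]
    if (lev == "numeric" && length(cats) > 0) {
      rlang::abort(paste0("numeric variable '", schema$name[i],
                          "' must not declare categories"))
    }
    if (lev == "ordinal" && length(cats) < 2) {
      rlang::abort(paste0("ordinal variable '", schema$name[i],
                          "' needs at least 2 categories in a declared order"))
    }
    if (lev == "nominal" && length(cats) < 1) {
      rlang::abort(paste0("nominal variable '", schema$name[i],
                          "' needs at least 1 category"))
    }
    if (anyDuplicated(cats)) {
      rlang::abort(paste0("duplicate categories for variable '",
                          schema$name[i], "'"))
    }
  }
  invisible(schema)
}

#' Read or write a cohort schema file
#'
#' Schemas are stored as YAML or JSON: a list of entries with fields `name`,
#' `level`, and optionally `categories`, `units`, `range_lo`, `range_hi`.
#' The file extension (`.yml`/`.yaml` vs `.json`) selects the format.
#'
#' @param path Path to the schema file.
#' @return `read_schema()` returns a [cohort_schema()] tibble;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("schema file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0) rlang::abort("schema file contains no variables")
  cohort_schema(
    name = purrr::map_chr(raw, "name"),
    level = purrr::map_chr(raw, "level"),
    categories = purrr::map(raw, function(e) {
      unlist(e$categories) %||% character()
    }),
    units = purrr::map_chr(raw, function(e) e$units %||% NA_character_),
    range_lo = purrr::map_dbl(raw, function(e) e$range_lo %||% NA_real_),
    range_hi = purrr::map_dbl(raw, function(e) e$range_hi %||% NA_real_)
  )
}

#' @rdname read_schema
#' @param schema A [cohort_schema()] tibble.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  entries <- purrr::pmap(schema, function(name, level, categories, units,
                                          range_lo, range_hi) {
    e <- list(name = name, level = level)
    if (length(categories) > 0) e$categories <- as.list(categories)
    if (!is.na(units)) e$units <- units
    if (!is.na(range_lo)) e$range_lo <- range_lo
    if (!is.na(range_hi)) e$range_hi <- range_hi
    e
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(entries, path)
  }
  invisible(path)
}

#' Default plausibility bounds for self-reported clinical fields
#'
#' Bounds used to screen out unrealistic self-entered biochemistry, blood
#' pressure and anthropometrics. They are deliberately generous: the aim is to
#' catch unit mistakes and typos, not clinically extreme but possible values.
#'
#' @return A tibble with columns `name`, `range_lo`, `range_hi`, `units`.
#' @export
default_plausible_ranges <- function() {
  tibble::tribble(
    ~name,          ~range_lo, ~range_hi, ~units,
    "glucose",             40,       500, "mg/dL",
    "sbp",                 70,       250, "mmHg",
    "dbp",                 40,       150, "mmHg",
    "height",             120,       220, "cm",
    "weight",              35,       250, "kg",
    "waist",               40,       200, "cm",
    "total_chol",          50,       500, "mg/dL",
    "hdl",                 10,       150, "mg/dL",
    "triglycerides",       20,      1000, "mg/dL"
  )
}
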