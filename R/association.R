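#' Within-typology and total percentage profiles
#'
#' For a categorical variable cross-classified with subject typologies,
#' computes the percentage distribution of the variable within each typology
#' and over the whole set of respondents. The total percentage of a category
#' equals the size-weighted mean of its within-typology percentages, so
#' comparing the two reveals whether a characteristic concentrates in
#' specific typologies.
#'
#' @param data A data frame.
#' @param typology Column (unquoted) holding the typology/cluster label.
#' @param variable Column (unquoted) holding the categorical variable.
#' @return A tibble with columns `typology`, `category`, `n`, `within_pct`,
#'   `total_pct`. Typologies with no members are flagged with `NA`
#'   percentages.
#' @examples
#' df <- data.frame(grp = rep(1, 683),
#'                  sex = rep(c("male", "female"), c(495, 188)))
#' percent_profile(df, grp, sex)  # male 72.5%
#' @export
percent_profile <- function(data, typology, variable) {
  typ <- factor(dplyr::pull(data, {{ typology }}))
  cat <- factor(dplyr::pull(data, {{ variable }}))
  counts <- as.data.frame(table(typology = typ, category = cat),
                          responseName = "n")
  counts <- tibble::as_tibble(counts)
  total_by_cat <- table(cat)
  n_total <- length(cat)
  counts |>
    dplyr::group_by(.data$typology) |>
    dplyr::mutate(within_pct = if (sum(.data$n) > 0) {
      100 * .data$n / sum(.data$n)
    } else {
      NA_real_
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      total_pct = 100 * as.vector(total_by_cat[as.character(.data$category)]) /
        n_total
    )
}

#' Chi-square test of independence for a typology-by-variable table
#'
#' Pearson chi-square test with no continuity correction: statistic
#' `sum((O - E)^2 / E)` with expected counts `E = row * col / n` and
#' `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param observed An r x c matrix or table of counts, or a data frame of two
#'   categorical columns (cross-tabulated internally).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_independence <- function(observed) {
  tab <- ht_as_count_table(observed)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 n = sum(tab))
}

ht_as_count_table <- function(observed) {
  if (is.data.frame(observed) && !all(purrr::map_lgl(observed, is.numeric))) {
    if (ncol(observed) != 2) {
      rlang::abort("data frame input must have exactly two categorical columns")
    }
    observed <- table(observed[[1]], observed[[2]])
  }
  tab <- as.matrix(observed)
  if (any(tab < 0)) rlang::abort("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    rlang::abort("contingency table must be at least 2 x 2")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("zero row or column margin")
  }
  tab
}

#' Adjusted Pearson residuals of a contingency table
#'
#' For each cell, the difference between the observed and the expected (under
#' independence) count divided by its standard error:
#' `APR = (O - E) / sqrt(E * (1 - row/n) * (1 - col/n))`. APRs are
#' asymptotically standard normal under independence, so each cell carries a
#' two-tailed p-value and can be read as an over- (+) or under- (-)
#' representation signal.
#'
#' @inheritParams chi_square_independence
#' @param thresholds Ascending positive cutoffs used by
#'   [flag_associations()]; conventionally `c(2, 3, 3.5)`, corresponding to
#'   two-tailed P = .046, .003 and < .001.
#' @return A tibble of class `apr_matrix`, one row per cell: `typology`,
#'   `category`, `observed`, `expected`, `residual`, `p_value`,
#'   `low_expected` (expected count below 1); the residual matrix is attached
#'   as attribute `"residuals"`.
#' @export
adjusted_pearson_residuals <- function(observed, thresholds = c(2, 3, 3.5)) {
  tab <- ht_as_count_table(observed)
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  E <- outer(rs, cs) / n
  APR <- (tab - E) / sqrt(E * outer(1 - rs / n, 1 - cs / n))
  if (any(E < 1)) {
    rlang::warn(paste0(sum(E < 1), " cell(s) have expected count < 1; ",
                       "their residuals may be unstable"))
  }
  rn <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  cn <- colnames(tab) %||% as.character(seq_len(ncol(tab)))
  out <- tibble::tibble(
    typology = rep(rn, times = ncol(tab)),
    category = rep(cn, each = nrow(tab)),
    observed = as.vector(tab),
    expected = as.vector(E),
    residual = as.vector(APR),
    p_value = apr_tail_p(as.vector(APR)),
    low_expected = as.vector(E) < 1
  )
  attr(out, "residuals") <- APR
  attr(out, "thresholds") <- sort(thresholds)
  class(out) <- c("apr_matrix", class(out))
  out
}

#' Two-tailed standard-normal tail probability of an adjusted residual
#'
#' @param z Numeric vector of residuals.
#' @return `2 * pnorm(-|z|)`; e.g. .046 at |z| = 2, .003 at |z| = 3, below
#'   .001 at |z| = 3.5.
#' @export
apr_tail_p <- function(z) 2 * pnorm(-abs(z))

#' Flag significant over/under-representation from adjusted residuals
#'
#' Assigns to each cell the highest threshold its |APR| reaches and the sign
#' of the deviation: `"+"` marks over-representation of a category inside a
#' typology, `"-"` under-representation, matching the boxed symbols used in
#' association maps. No multiplicity correction is applied across cells; the
#' top threshold (3.5 by default, P < .001) plays that conservative role. A
#' Bonferroni option over the table's cells is available.
#'
#' @param apr An `apr_matrix` from [adjusted_pearson_residuals()].
#' @param thresholds Ascending positive cutoffs; defaults to those stored in
#'   `apr`.
#' @param bonferroni If `TRUE`, additionally reports `p_adjusted`
#'   (Bonferroni across cells).
#' @return The `apr` tibble with added columns `flag_level` (0 if below all
#'   thresholds) and `direction` (`"+"`, `"-"` or `""`).
#' @export
flag_associations <- function(apr, thresholds = NULL, bonferroni = FALSE) {
  if (is.null(thresholds)) thresholds <- attr(apr, "thresholds") %||% c(2, 3, 3.5)
  thresholds <- sort(thresholds)
  if (any(thresholds <= 0)) rlang::abort("thresholds must be positive")
  lev <- purrr::map_dbl(abs(apr$residual), function(a) {
    hit <- thresholds[thresholds <= a]
    if (length(hit) == 0) 0 else max(hit)
  })
  out <- dplyr::mutate(
    apr,
    flag_level = lev,
    direction = dplyr::case_when(lev == 0 ~ "",
                                 .data$residual > 0 ~ "+",
                                 TRUE ~ "-")
  )
  if (bonferroni) out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out
}

#' Plot an adjusted-residual association map
#'
#' Tile map of adjusted Pearson residuals with +/- marks at the flagged
#' cells.
#'
#' @param object An `apr_matrix`.
#' @param ... Passed to [flag_associations()].
#' @return A ggplot object.
#' @export
autoplot.apr_matrix <- function(object, ...) {
  df <- flag_associations(object, ...)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$typology,
                                   fill = .data$residual)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$direction)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "APR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
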