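#' @export
print.princals_fit <- function(x, ...) {
  cat("Nonlinear PCA with optimal scaling\n")
  cat(sprintf("  %d respondents, %d variables, %d dimension(s)\n",
              x$n, nrow(x$loadings), x$ndim))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              x$converged, x$n_iter))
  cat(sprintf("  VAF per dimension: %s  (total %.1f%%)\n",
              paste(sprintf("%.1f%%", x$vaf_per_dim), collapse = ", "),
              x$vaf_total))
  cat(sprintf("  total Cronbach alpha: %.3f\n", x$alpha_total))
  cat("\nComponent loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy a nonlinear PCA fit
#'
#' `tidy()` returns one row per (variable, dimension) with the component
#' loading and its essential/negligible classification; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `princals_fit`.
#' @param threshold Absolute loading cutoff for the `essential` flag.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.princals_fit <- function(x, threshold = 0.4, ...) {
  classify_loadings(x$loadings, threshold = threshold)
}

#' @rdname tidy.princals_fit
#' @export
glance.princals_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_vars = nrow(x$loadings),
    ndim = x$ndim,
    vaf_total = x$vaf_total,
    alpha_total = x$alpha_total,
    converged = x$converged,
    n_iter = x$n_iter,
    loss = x$loss_trace[length(x$loss_trace)]
  )
}

#' Plot component loadings of a nonlinear PCA fit
#'
#' Dot plot of loadings by dimension, with the essential-loading threshold
#' marked; the standard way of reading which variables give each extracted
#' indicator its meaning.
#'
#' @param object A `princals_fit`.
#' @param threshold Absolute loading cutoff shown as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.princals_fit <- function(object, threshold = 0.4, ...) {
  df <- classify_loadings(object$loadings, threshold = threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$variable,
                                   colour = .data$essential)) +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dimension)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "component loading (correlation with dimension)",
                  y = NULL, colour = paste0("|loading| >= ", threshold)) +
    ggplot2::theme_minimal()
}
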