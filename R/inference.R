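#' Dual parametric/nonparametric two-group tests
#'
#' Runs, per variable, a one-way ANOVA (equality of group means), a
#' Mann-Whitney test and a two-sample Kolmogorov-Smirnov test (equality of
#' group distributions) across a two-level grouping factor. A variable is
#' marked "revealing" only when both procedures agree: the parametric test is
#' significant AND at least one nonparametric test is significant at `alpha`
#' (with `rule = "all"`, both nonparametric tests must be significant).
#' Relying on agreement between the two families guards against both
#' normality failures (which bias the parametric test) and the lower power
#' of the nonparametric tests.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric columns to test.
#' @param group Column name of a two-level grouping factor.
#' @param alpha Significance level (default 0.05).
#' @param rule `"either"` (default) or `"all"`: how many nonparametric tests
#'   must agree with the ANOVA.
#' @param exact_max Total sample size up to which the Mann-Whitney p-value is
#'   computed by exact enumeration; above it the normal approximation with
#'   tie correction is used (default 20).
#' @return A tibble, one row per variable: `variable`, `anova_p`,
#'   `mann_whitney_p`, `ks_p`, `anova_unreliable` (both groups with zero
#'   variance), `revealing`.
#' @export
dual_rule_tests <- function(data, vars, group, alpha = 0.05,
                            rule = c("either", "all"), exact_max = 20) {
  rule <- match.arg(rule)
  g <- factor(data[[group]])
  if (nlevels(g) != 2) rlang::abort("group must have exactly 2 levels")
  if (any(table(g) < 2)) rlang::abort("each group needs at least 2 observations")
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
    unreliable <- var(x1) == 0 && var(x2) == 0
    a_p <- if (unreliable) NA_real_ else {
      anova(aov(x ~ g))[["Pr(>F)"]][1]
    }
    exact <- length(x) <= exact_max && !any(duplicated(x))
    mw_p <- suppressWarnings(wilcox.test(x1, x2, exact = exact)$p.value)
    ks_p <- suppressWarnings(ks.test(x1, x2)$p.value)
    nonpar_sig <- c(mw_p < alpha, ks_p < alpha)
    nonpar_ok <- if (rule == "either") any(nonpar_sig) else all(nonpar_sig)
    tibble::tibble(
      variable = v,
      anova_p = a_p,
      mann_whitney_p = mw_p,
      ks_p = ks_p,
      anova_unreliable = unreliable,
      revealing = !unreliable && a_p < alpha && nonpar_ok
    )
  })
}

#' Validation battery for a cluster partition
#'
#' The inferential checks applied to a final typology: per-variable one-way
#' ANOVA (equal cluster means) and Kruskal-Wallis (equal cluster medians);
#' overall MANOVA with Wilks' lambda and the Hotelling-Lawley trace (equal
#' cluster centroids), using the standard F approximations; and, for every
#' pair of clusters, the squared Mahalanobis distance between centroids with
#' its two-sample F test based on the pooled within-cluster covariance.
#'
#' @param data A data frame of (standardized) classification variables.
#' @param vars Character vector of variable names; default all numeric
#'   columns except `row_id`.
#' @param cluster Column name (or a vector) of cluster labels.
#' @param bonferroni If `TRUE`, pairwise Mahalanobis p-values are Bonferroni
#'   adjusted over the `k(k-1)/2` comparisons (off by default).
#' @return An object of class `test_battery`: list with tibbles
#'   `per_variable` (`variable`, `anova_p`, `kruskal_p`), `manova`
#'   (`statistic`, `value`, `f`, `p_value`), `pairwise` (`cluster_a`,
#'   `cluster_b`, `d2`, `f`, `df1`, `df2`, `p_value`).
#' @export
cluster_validation <- function(data, vars = NULL, cluster,
                               bonferroni = FALSE) {
  if (length(cluster) == 1 && is.character(cluster)) {
    cl <- data[[cluster]]
    if (is.null(vars)) {
      vars <- setdiff(names(data)[purrr::map_lgl(data, is.numeric)],
                      c("row_id", cluster))
    }
  } else {
    cl <- cluster
    if (is.null(vars)) {
      vars <- setdiff(names(data)[purrr::map_lgl(data, is.numeric)], "row_id")
    }
  }
  g <- factor(cl)
  k <- nlevels(g)
  if (k < 2) rlang::abort("need at least 2 clusters")
  if (any(table(g) < 2)) rlang::abort("every cluster needs at least 2 members")
  Z <- as.matrix(data[vars])
  n <- nrow(Z); m <- ncol(Z)

  per_variable <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    tibble::tibble(
      variable = v,
      anova_p = anova(aov(x ~ g))[["Pr(>F)"]][1],
      kruskal_p = kruskal.test(x, g)$p.value
    )
  })

  # pooled within-cluster covariance and pairwise squared Mahalanobis tests
  sizes <- table(g)
  centroids <- rowsum(Z, g) / as.vector(sizes)
  W <- crossprod(Z - centroids[as.integer(g), , drop = FALSE])
  S <- W / (n - k)
  Sinv <- tryCatch(solve(S), error = function(e) {
    rlang::abort(paste0("pooled within-cluster covariance is singular; ",
                        "consider removing collinear variables"))
  })
  if (kappa(S) > 1e10) {
    rlang::abort(paste0("pooled within-cluster covariance is singular; ",
                        "consider removing collinear variables"))
  }

  man <- if (m >= 2) {
    fit <- manova(Z ~ g)
    purrr::map_dfr(c("Wilks", "Hotelling-Lawley"), function(tst) {
      s <- summary(fit, test = tst)$stats
      tibble::tibble(statistic = tst, value = s[1, 2], f = s[1, 3],
                     df1 = s[1, 4], df2 = s[1, 5], p_value = s[1, 6])
    })
  } else {
    tibble::tibble(statistic = character(), value = numeric(),
                   f = numeric(), df1 = numeric(), df2 = numeric(),
                   p_value = numeric())
  }
  pairs <- utils::combn(levels(g), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dvec <- centroids[a, ] - centroids[b, ]
    d2 <- as.numeric(dvec %*% Sinv %*% dvec)
    na <- sizes[[a]]; nb <- sizes[[b]]
    df2 <- n - k - m + 1
    fstat <- (na * nb * df2) / ((na + nb) * (n - k) * m) * d2
    p <- stats::pf(fstat, m, df2, lower.tail = FALSE)
    tibble::tibble(cluster_a = a, cluster_b = b, d2 = d2, f = fstat,
                   df1 = m, df2 = df2, p_value = p)
  })
  if (bonferroni) {
    pairwise$p_adjusted <- pmin(1, pairwise$p_value * nrow(pairwise))
  }
  structure(list(per_variable = per_variable, manova = man,
                 pairwise = pairwise, k = k, n = n, vars = vars),
            class = "test_battery")
}

#' @export
print.test_battery <- function(x, ...) {
  cat(sprintf("Cluster validation battery (k = %d, N = %d, %d variable(s))\n",
              x$k, x$n, length(x$vars)))
  cat("\nMANOVA:\n"); print(x$manova)
  cat("\nPer-variable tests:\n"); print(x$per_variable)
  cat(sprintf("\nPairwise squared Mahalanobis tests (%d comparisons): min p = %.3g, max p = %.3g\n",
              nrow(x$pairwise), min(x$pairwise$p_value),
              max(x$pairwise$p_value)))
  invisible(x)
}

#' @export
tidy.test_battery <- function(x, ...) x$per_variable

#' @export
glance.test_battery <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, n_vars = length(x$vars),
    wilks_p = c(x$manova$p_value[x$manova$statistic == "Wilks"], NA)[1],
    hotelling_lawley_p = c(x$manova$p_value[x$manova$statistic ==
                                              "Hotelling-Lawley"], NA)[1],
    n_pairwise = nrow(x$pairwise),
    max_pairwise_p = max(x$pairwise$p_value)
  )
}
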