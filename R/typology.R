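#' Scan the number of clusters with the Calinski-Harabasz statistic
#'
#' Runs best-of-restarts k-means for every k in `k_range` and records the CH
#' value of each solution. The selected k maximizes CH; when two or more k
#' values lie within `tie_tol` (relative) of the maximum, the tie is resolved
#' by `prefer_larger_k`.
#'
#' @inheritParams kmeans_random_starts
#' @param k_range Integer vector of cluster counts to scan (default `2:15`).
#' @param tie_tol Relative CH difference treated as a tie (default 0.005).
#' @param prefer_larger_k On a tie, pick the larger k (default `TRUE`).
#' @param df CH degrees-of-freedom convention, see [calinski_harabasz()].
#' @return A tibble of class `ch_profile` with columns `k`, `ch`, `within`,
#'   `between`; attributes `argmax_k` (selected k), `tied_k` (all k within
#'   tolerance of the maximum) and `solutions` (list of `km_solution`s).
#' @export
ch_scan <- function(x, k_range = 2:15, n_starts = 1000, seed = NULL,
                    tie_tol = 0.005, prefer_larger_k = TRUE, df = "k") {
  X <- as.matrix(x)
  n <- nrow(X)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    rlang::abort("k_range must lie within [2, N - 1]")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, length(k_range))
  sols <- purrr::map2(k_range, sub_seeds, function(k, s) {
    kmeans_random_starts(X, k, n_starts = n_starts, seed = s)
  })
  prof <- tibble::tibble(
    k = as.integer(k_range),
    ch = purrr::map_dbl(sols, function(s) {
      calinski_harabasz(X, s$assignments, df = df)
    }),
    within = purrr::map_dbl(sols, "within_deviance"),
    between = purrr::map_dbl(sols, "between_deviance")
  )
  ch_max <- max(prof$ch)
  tied <- prof$k[prof$ch >= ch_max * (1 - tie_tol)]
  argmax <- if (prefer_larger_k) max(tied) else min(tied)
  attr(prof, "argmax_k") <- argmax
  attr(prof, "tied_k") <- tied
  attr(prof, "solutions") <- setNames(sols, paste0("k", k_range))
  class(prof) <- c("ch_profile", class(prof))
  prof
}

#' @export
print.ch_profile <- function(x, ...) {
  cat("Calinski-Harabasz profile\n")
  NextMethod()
  cat("selected k:", attr(x, "argmax_k"),
      " (tied within tolerance:", paste(attr(x, "tied_k"), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Plot a Calinski-Harabasz profile
#' @param object A `ch_profile` from [ch_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ch_profile <- function(object, ...) {
  argmax <- attr(object, "argmax_k")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = object[object$k == argmax, ],
                        colour = "#b2182b", size = 3) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "Calinski-Harabasz statistic") +
    ggplot2::theme_minimal()
}

#' Detect outliers as stable small clusters
#'
#' Runs k-means over an increasing number of groups and flags small clusters
#' (size at most `max_cluster_size`) that persist over at least
#' `min_stability` consecutive k values. Such groups of isolated
#' respondents, stably separated from the bulk of the data as k grows, are
#' treated as outlying units to be removed before the final classification.
#'
#' Two stability readings are available. With `membership = "exact"`
#' (default) a group counts as stable only when its exact membership recurs
#' unchanged across consecutive k. With `membership = "rows"` stability is
#' assessed per respondent -- a row is flagged when it sits in *some* small
#' cluster for `min_stability` consecutive k values -- which is robust to
#' two isolated respondents alternating between a joint pair cluster and
#' separate singletons as k grows.
#'
#' @inheritParams ch_scan
#' @param max_cluster_size Largest cluster size still considered an outlier
#'   group; default `max(1, round(0.01 * N))`.
#' @param min_stability Minimum number of consecutive k values over which the
#'   group must persist (default 3).
#' @param membership `"exact"` (default) or `"rows"`, see Details.
#' @return A tibble of class `outlier_report`, one row per stable group:
#'   `group`, `size`, `k_onset`, `stability_span`, `row_ids` (list-column);
#'   attribute `outlier_rows` holds the union of flagged row indices.
#' @export
detect_outliers <- function(x, k_range = 2:15, n_starts = 1000, seed = NULL,
                            max_cluster_size = NULL, min_stability = 3,
                            membership = c("exact", "rows")) {
  membership <- match.arg(membership)
  X <- as.matrix(x)
  n <- nrow(X)
  if (is.null(max_cluster_size)) max_cluster_size <- max(1, round(0.01 * n))
  if (max_cluster_size < 1) rlang::abort("max_cluster_size must be >= 1")
  if (min_stability < 2) rlang::abort("min_stability must be >= 2")
  k_range <- sort(unique(as.integer(k_range)))
  empty <- tibble::tibble(group = integer(), size = integer(),
                          k_onset = integer(), stability_span = integer(),
                          row_ids = list())
  if (min_stability > length(k_range)) {
    return(ht_as_outlier_report(empty, integer()))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, length(k_range))
  # row memberships of all small clusters, per k
  small_by_k <- purrr::map2(k_range, sub_seeds, function(k, s) {
    sol <- kmeans_random_starts(X, k, n_starts = n_starts, seed = s)
    sizes <- tabulate(sol$assignments, k)
    small <- which(sizes <= max_cluster_size)
    purrr::map(small, function(cl) sort(which(sol$assignments == cl)))
  })
  if (membership == "rows") {
    return(ht_row_stability_report(small_by_k, k_range, min_stability, n,
                                   empty))
  }
  keys_by_k <- purrr::map(small_by_k, function(groups) {
    purrr::map_chr(groups, paste, collapse = ",")
  })
  all_keys <- unique(unlist(keys_by_k))
  groups <- purrr::map(all_keys, function(key) {
    present <- purrr::map_lgl(keys_by_k, function(ks) key %in% ks)
    # longest run of consecutive k values containing this exact membership
    r <- rle(present)
    runs <- which(r$values & r$lengths >= min_stability)
    if (length(runs) == 0) return(NULL)
    best <- runs[which.max(r$lengths[runs])]
    onset_idx <- sum(r$lengths[seq_len(best - 1)]) + 1
    rows <- as.integer(strsplit(key, ",")[[1]])
    tibble::tibble(size = length(rows),
                   k_onset = k_range[onset_idx],
                   stability_span = r$lengths[best],
                   row_ids = list(rows))
  })
  groups <- purrr::compact(groups)
  if (length(groups) == 0) return(ht_as_outlier_report(empty, integer()))
  report <- dplyr::bind_rows(groups)
  report <- dplyr::arrange(report, .data$k_onset, dplyr::desc(.data$size))
  report <- dplyr::mutate(report, group = dplyr::row_number(), .before = 1)
  ht_as_outlier_report(report, sort(unique(unlist(report$row_ids))))
}

# row-level stability: a row is outlying if it lies in some small cluster
# for >= min_stability consecutive k; flagged rows sharing a small cluster
# anywhere are reported as one group
ht_row_stability_report <- function(small_by_k, k_range, min_stability, n,
                                    empty) {
  nk <- length(k_range)
  present <- matrix(FALSE, n, nk)
  for (ki in seq_len(nk)) {
    for (rows in small_by_k[[ki]]) present[rows, ki] <- TRUE
  }
  run_info <- purrr::map(seq_len(n), function(i) {
    r <- rle(present[i, ])
    runs <- which(r$values & r$lengths >= min_stability)
    if (length(runs) == 0) return(NULL)
    best <- runs[which.max(r$lengths[runs])]
    onset_idx <- sum(r$lengths[seq_len(best - 1)]) + 1
    c(onset = k_range[onset_idx], span = r$lengths[best])
  })
  flagged <- which(!purrr::map_lgl(run_info, is.null))
  if (length(flagged) == 0) return(ht_as_outlier_report(empty, integer()))
  # union-find over flagged rows through shared small clusters
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ki in seq_len(nk)) {
    for (rows in small_by_k[[ki]]) {
      rows <- intersect(rows, flagged)
      if (length(rows) > 1) {
        for (r2 in rows[-1]) parent[find(r2)] <- find(rows[1])
      }
    }
  }
  roots <- purrr::map_int(flagged, find)
  groups <- split(flagged, roots)
  report <- purrr::map_dfr(groups, function(rows) {
    info <- do.call(rbind, run_info[rows])
    tibble::tibble(size = length(rows),
                   k_onset = min(info[, "onset"]),
                   stability_span = as.integer(max(info[, "span"])),
                   row_ids = list(as.integer(rows)))
  })
  report <- dplyr::arrange(report, .data$k_onset, dplyr::desc(.data$size))
  report <- dplyr::mutate(report, group = dplyr::row_number(), .before = 1)
  ht_as_outlier_report(report, sort(unique(unlist(report$row_ids))))
}

ht_as_outlier_report <- function(report, rows) {
  attr(report, "outlier_rows") <- rows
  class(report) <- c("outlier_report", class(report))
  report
}

#' @export
print.outlier_report <- function(x, ...) {
  rows <- attr(x, "outlier_rows")
  cat(sprintf("Outlier report: %d outlying row(s) in %d stable small group(s)\n",
              length(rows), nrow(x)))
  if (nrow(x) > 0) NextMethod()
  invisible(x)
}

#' Two-phase typology construction
#'
#' The full classification stage: (1) z-score the classification variables;
#' (2) detect outliers as stable small k-means clusters and remove them;
#' (3) restandardize the remaining rows; (4) scan k with the
#' Calinski-Harabasz statistic; (5) fit the final best-of-restarts k-means
#' partition at the selected k and summarize each cluster as a subject
#' typology.
#'
#' @param data A data frame containing the classification variables (e.g.
#'   stress, control, activity, smoking and alcohol indicators plus reported
#'   absenteeism).
#' @param vars Character vector of classification variable names; default all
#'   numeric columns except `row_id`.
#' @param k_range Cluster counts to scan (default `2:15`).
#' @param n_starts Random starts per k (default 1000).
#' @param seed Integer seed controlling all restart sampling.
#' @param max_cluster_size,min_stability,membership Outlier rule, see
#'   [detect_outliers()].
#' @param tie_tol,prefer_larger_k CH tie handling, see [ch_scan()].
#' @param df CH degrees-of-freedom convention.
#' @return An object of class `typology_result`: list with `outliers`
#'   (outlier report), `ch_profile`, `solution` (final `km_solution`),
#'   `assignments` (tibble `row_id`, `cluster`), `typology` (per-cluster
#'   size, share and label placeholder), `variable_summary` (per cluster and
#'   variable quartile summary of the standardized values), `z` (tibble of
#'   restandardized classification variables of retained rows), `vars`.
#' @export
run_typology_pipeline <- function(data, vars = NULL, k_range = 2:15,
                                  n_starts = 1000, seed = NULL,
                                  max_cluster_size = NULL, min_stability = 3,
                                  membership = "exact",
                                  tie_tol = 0.005, prefer_larger_k = TRUE,
                                  df = "k") {
  if (is.null(vars)) {
    vars <- setdiff(names(data)[purrr::map_lgl(data, is.numeric)], "row_id")
  }
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v) > 0) {
    rlang::abort(paste0("column(s) not found: ", paste(missing_v, collapse = ", ")))
  }
  row_id <- if ("row_id" %in% names(data)) data$row_id else seq_len(nrow(data))
  if (!is.null(seed)) withr::local_seed(seed)
  phase_seeds <- sample.int(.Machine$integer.max - 1, 3)

  # phase 1: standardize and screen for stable small clusters
  z1 <- zscore_columns(data, vars)
  outliers <- detect_outliers(z1, k_range = k_range, n_starts = n_starts,
                              seed = phase_seeds[1],
                              max_cluster_size = max_cluster_size,
                              min_stability = min_stability,
                              membership = membership)
  out_rows <- attr(outliers, "outlier_rows")
  keep <- setdiff(seq_len(nrow(data)), out_rows)

  # phase 2: restandardize retained rows, rescan k, fit final partition
  z2 <- zscore_columns(data[keep, , drop = FALSE], vars)
  k_range2 <- k_range[k_range <= length(keep) - 1]
  profile <- ch_scan(z2, k_range = k_range2, n_starts = n_starts,
                     seed = phase_seeds[2], tie_tol = tie_tol,
                     prefer_larger_k = prefer_larger_k, df = df)
  k_final <- attr(profile, "argmax_k")
  solution <- kmeans_random_starts(z2, k_final, n_starts = n_starts,
                                   seed = phase_seeds[3])

  assignments <- tibble::tibble(row_id = row_id[keep],
                                cluster = solution$assignments)
  sizes <- tabulate(solution$assignments, k_final)
  typology <- tibble::tibble(
    cluster = seq_len(k_final),
    n = sizes,
    share_pct = 100 * sizes / length(keep)
  )
  zsol <- dplyr::bind_cols(assignments["cluster"], z2)
  variable_summary <- zsol |>
    tidyr::pivot_longer(-"cluster", names_to = "variable") |>
    dplyr::group_by(.data$cluster, .data$variable) |>
    dplyr::summarise(
      min = min(.data$value), q1 = quantile(.data$value, 0.25),
      median = median(.data$value), q3 = quantile(.data$value, 0.75),
      max = max(.data$value), .groups = "drop"
    )

  structure(list(
    outliers = outliers,
    outlier_row_ids = row_id[out_rows],
    ch_profile = profile,
    solution = solution,
    assignments = assignments,
    typology = typology,
    variable_summary = variable_summary,
    z = dplyr::bind_cols(tibble::tibble(row_id = row_id[keep]), z2),
    vars = vars,
    seed = seed
  ), class = "typology_result")
}

#' @export
print.typology_result <- function(x, ...) {
  cat("Subject typologies\n")
  cat(sprintf("  %d respondent(s) retained, %d outlier(s) removed\n",
              nrow(x$assignments), length(x$outlier_row_ids)))
  cat(sprintf("  selected k = %d (CH = %.2f)\n", x$solution$k,
              x$ch_profile$ch[x$ch_profile$k == x$solution$k]))
  print(x$typology)
  invisible(x)
}

#' Tidy methods for typology results
#'
#' `tidy()` returns the per-respondent cluster assignments; `glance()` a
#' one-row summary of the final partition.
#'
#' @param x A `typology_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.typology_result <- function(x, ...) x$assignments

#' @rdname tidy.typology_result
#' @export
glance.typology_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$assignments),
    n_outliers = length(x$outlier_row_ids),
    k = x$solution$k,
    ch = x$ch_profile$ch[x$ch_profile$k == x$solution$k],
    within_deviance = x$solution$within_deviance,
    between_deviance = x$solution$between_deviance
  )
}

#' Boxplots of classification variables within typologies
#'
#' The standard reading aid for labeling clusters: within-cluster
#' distributions of the standardized classification variables.
#'
#' @param object A `typology_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.typology_result <- function(object, ...) {
  df <- dplyr::bind_cols(object$assignments["cluster"],
                         object$z[object$vars]) |>
    tidyr::pivot_longer(-"cluster", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable)) +
    ggplot2::labs(x = "cluster", y = "standardized value") +
    ggplot2::theme_minimal()
}
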