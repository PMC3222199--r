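#' Best-of-restarts k-means clustering
#'
#' Lloyd-type k-means with random starts: each run seeds the k initial
#' centroids with k distinct respondents drawn at random without replacement,
#' iterates assignment/centroid updates to a fixed point, and the partition
#' with minimum within-cluster deviance over all runs is returned. The large
#' number of restarts defeats the order dependence of single-start k-means.
#' If a cluster empties during iteration it is re-seeded with the point
#' farthest from the centroid of the largest cluster.
#'
#' @param x Numeric matrix or data frame of classification variables
#'   (typically z-scored).
#' @param k Number of clusters, `2 <= k <= N`.
#' @param n_starts Number of random starts (default 1000).
#' @param seed Optional integer seed making the run reproducible.
#' @param max_iter Iteration cap per start (default 300).
#' @param greedy_start Also run one deterministic farthest-point (Gonzalez)
#'   start alongside the random starts (default `TRUE`). With very many
#'   random starts this is redundant; at small `n_starts` it recovers the
#'   deep minima -- isolated extreme points captured as their own clusters --
#'   that a large random-restart budget would find. It can only lower the
#'   selected within-deviance.
#' @return An object of class `km_solution`: list with `assignments`
#'   (integer vector), `centroids` (k x p matrix), `within_deviance`,
#'   `between_deviance`, `total_deviance`, `k`, `n_starts`, `seed`.
#' @export
kmeans_random_starts <- function(x, k, n_starts = 1000, seed = NULL,
                                 max_iter = 300, greedy_start = TRUE) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1 || k > n) rlang::abort("k must be between 1 and N")
  if (n_starts < 1) rlang::abort("n_starts must be at least 1")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) {
    rlang::abort(paste0("k = ", k, " exceeds the number of distinct rows (",
                        n_distinct, ")"))
  }
  if (!is.null(seed)) withr::local_seed(seed)

  seed_idx <- matrix(0L, n_starts, k)
  for (s in seq_len(n_starts)) seed_idx[s, ] <- sample.int(n, k)
  if (greedy_start) seed_idx <- rbind(seed_idx, ht_gonzalez_seeds(X, k))
  best <- ht_kmeans_best(X, seed_idx, as.integer(max_iter))
  cl <- best$assignments + 1L
  centers <- rowsum(X, cl) / tabulate(cl, k)
  grand <- colMeans(X)
  total <- sum(sweep(X, 2, grand)^2)
  structure(list(
    assignments = cl,
    centroids = centers,
    within_deviance = best$within,
    between_deviance = total - best$within,
    total_deviance = total,
    k = k,
    n = n,
    n_starts = n_starts,
    seed = seed
  ), class = "km_solution")
}

# farthest-point (Gonzalez) seeding: start from the point farthest from the
# grand centroid, then repeatedly add the point maximizing the minimum
# distance to the seeds already chosen
ht_gonzalez_seeds <- function(X, k) {
  n <- nrow(X)
  seeds <- integer(k)
  d0 <- rowSums(sweep(X, 2, colMeans(X))^2)
  seeds[1] <- which.max(d0)
  dmin <- rep(Inf, n)
  for (j in seq_len(k - 1)) {
    dj <- rowSums(sweep(X, 2, X[seeds[j], ])^2)
    dmin <- pmin(dmin, dj)
    dmin[seeds[seq_len(j)]] <- -1
    seeds[j + 1] <- which.max(dmin)
  }
  seeds
}

#' @export
print.km_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, N = %d, best of %d random start(s)\n",
              x$k, x$n, x$n_starts))
  cat(sprintf("  within-cluster deviance: %.4f  (between: %.4f)\n",
              x$within_deviance, x$between_deviance))
  cat("  cluster sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

#' Calinski-Harabasz statistic
#'
#' Ratio of between-cluster to within-cluster variance used to compare
#' partitions with different numbers of groups. The default degrees of
#' freedom divide the between deviance by `k` and the within deviance by
#' `N - k`; the textbook convention (`k - 1`, `N - k`) is available via
#' `df = "classic"`. Larger values indicate greater separation between
#' groups.
#'
#' @param x Numeric matrix or data frame.
#' @param assignments Integer/factor cluster labels, one per row of `x`.
#' @param df Degrees-of-freedom convention, `"k"` (default) or `"classic"`.
#' @return The CH value (`Inf` with a warning when the within deviance is 0).
#' @export
calinski_harabasz <- function(x, assignments, df = c("k", "classic")) {
  df <- match.arg(df)
  X <- as.matrix(x)
  cl <- as.integer(factor(assignments))
  n <- nrow(X)
  k <- max(cl)
  if (k < 2) rlang::abort("need at least 2 clusters")
  sizes <- tabulate(cl, k)
  if (any(sizes == 0)) rlang::abort("all clusters must be nonempty")
  centers <- rowsum(X, cl) / sizes
  W <- sum((X - centers[cl, , drop = FALSE])^2)
  grand <- colMeans(X)
  B <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  if (W == 0) {
    rlang::warn("within-cluster deviance is 0; CH is infinite")
    return(Inf)
  }
  df_b <- if (df == "k") k else k - 1
  (B / df_b) / (W / (n - k))
}
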