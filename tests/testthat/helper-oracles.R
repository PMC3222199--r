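# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Weighted least-squares monotone fit by exhaustive search over all
# level-set partitions (consecutive blocks with nondecreasing block means).
oracle_monotone <- function(targets, weights) {
  n <- length(targets)
  best_sse <- Inf
  best_fit <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    means <- numeric(length(bounds) - 1)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- sum(weights[idx] * targets[idx]) / sum(weights[idx])
      fit[idx] <- means[b]
    }
    if (any(diff(means) < -1e-12)) next
    sse <- sum(weights * (fit - targets)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_fit <- fit
    }
  }
  best_fit
}

# Globally optimal k-means within-deviance by enumerating every assignment
# of n points (n small) to k nonempty clusters, vectorized over all k^n
# assignments at once: W = sum(||x||^2) - sum_c ||sum_c x||^2 / n_c.
oracle_kmeans_within <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  sumxx <- sum(X^2)
  reduction <- 0
  valid <- rep(TRUE, nrow(A))
  for (cl in seq_len(k)) {
    mask <- (A == cl) * 1
    counts <- rowSums(mask)
    valid <- valid & counts > 0
    S <- mask %*% X
    contrib <- rowSums(S^2) / pmax(counts, 1)
    contrib[counts == 0] <- 0
    reduction <- reduction + contrib
  }
  min(sumxx - reduction[valid])
}

# Double-loop Pearson chi-square statistic.
oracle_chisq <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Double-loop adjusted Pearson residuals.
oracle_apr <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  out <- matrix(0, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      se <- sqrt(e * (1 - rs[i] / n) * (1 - cs[j] / n))
      out[i, j] <- (tab[i, j] - e) / se
    }
  }
  out
}

# Small mixed-type fixture used across the schema/cleaning tests.
make_test_schema <- function() {
  cohort_schema(
    name = c("sex", "smoking", "glucose", "days"),
    level = c("nominal", "ordinal", "numeric", "numeric"),
    categories = list(c("male", "female"),
                      c("never", "former", "current"),
                      character(), character()),
    range_lo = c(NA, NA, 40, 0),
    range_hi = c(NA, NA, 500, 366)
  )
}

make_test_cohort <- function() {
  as_cohort(tibble::tibble(
    sex = c("male", "female", "male"),
    smoking = c("never", "current", "former"),
    glucose = c(90, 110, 85),
    days = c(0, 3, 12)
  ), make_test_schema())
}
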