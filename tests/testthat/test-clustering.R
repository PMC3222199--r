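test_that("best-of-restarts matches the exhaustive-partition optimum", {
  # two tight triads
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(5, 5), c(5.1, 5), c(5, 5.1))
  sol <- kmeans_random_starts(X, 2, n_starts = 20, seed = 1)
  expect_equal(sol$within_deviance, oracle_kmeans_within(X, 2),
               tolerance = 1e-10)
  expect_equal(sort(tabulate(sol$assignments, 2)), c(3, 3))
  # degenerate: k = N
  solN <- kmeans_random_starts(X, 6, n_starts = 5, seed = 2)
  expect_equal(solN$within_deviance, 0)
  expect_equal(sort(sol$assignments[1:3]), rep(sol$assignments[1], 3))
  expect_error(kmeans_random_starts(rbind(c(1, 1), c(1, 1)), 2), "distinct")
})

test_that("deviance decomposition holds and restarts defeat row order", {
  withr::with_seed(4, X <- matrix(rnorm(60 * 3), 60, 3))
  sol <- kmeans_random_starts(X, 3, n_starts = 50, seed = 7)
  expect_equal(sol$within_deviance + sol$between_deviance,
               sol$total_deviance, tolerance = 1e-8)
  # recompute within deviance independently
  ctr <- rowsum(X, sol$assignments) / tabulate(sol$assignments, 3)
  expect_equal(sol$within_deviance,
               sum((X - ctr[sol$assignments, ])^2), tolerance = 1e-10)
  # permuting rows returns the same partition up to relabeling
  perm <- withr::with_seed(9, sample(60))
  sol_p <- kmeans_random_starts(X[perm, ], 3, n_starts = 50, seed = 8)
  expect_equal(sol_p$within_deviance, sol$within_deviance, tolerance = 1e-8)
  expect_equal(mclust::adjustedRandIndex(sol$assignments[perm],
                                         sol_p$assignments), 1)
})

test_that("best-of-restarts deviance is nonincreasing in the restart count", {
  withr::with_seed(10, X <- matrix(rnorm(80 * 4), 80, 4))
  w <- sapply(c(1, 5, 25, 100), function(ns) {
    kmeans_random_starts(X, 5, n_starts = ns, seed = 3)$within_deviance
  })
  expect_true(all(diff(w) <= 1e-10))
})

test_that("Calinski-Harabasz follows the stated degrees of freedom", {
  # constructed 1-d fixture: B = 40, W = 10, k = 2, N = 6
  a <- sqrt(20 / 3); c_ <- sqrt(2.5)
  X <- matrix(c(-a - c_, -a, -a + c_, a - c_, a, a + c_), ncol = 1)
  cl <- rep(1:2, each = 3)
  expect_equal(calinski_harabasz(X, cl), (40 / 2) / (10 / 4), tolerance = 1e-10)
  expect_equal(calinski_harabasz(X, cl, df = "classic"),
               (40 / 1) / (10 / 4), tolerance = 1e-10)
  # duplicating every point doubles both deviances; only the df terms move
  X2 <- rbind(X, X); cl2 <- c(cl, cl)
  expect_equal(calinski_harabasz(X2, cl2), (80 / 2) / (20 / 10),
               tolerance = 1e-10)
  # rotation invariance
  withr::with_seed(2, {
    Y <- matrix(rnorm(40 * 3), 40, 3)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    clr <- sample(1:3, 40, replace = TRUE)
  })
  expect_equal(calinski_harabasz(Y, clr),
               calinski_harabasz(Y %*% Q, clr), tolerance = 1e-8)
  expect_error(calinski_harabasz(Y, rep(1, 40)), "2 clusters")
  expect_warning(calinski_harabasz(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                                   c(1, 1, 2, 2)), "infinite")
})

test_that("CH agrees with an independent deviance-based computation", {
  withr::with_seed(14, {
    X <- matrix(rnorm(50 * 2), 50, 2)
    cl <- sample(1:4, 50, replace = TRUE)
  })
  k <- 4; n <- 50
  grand <- colMeans(X)
  w <- 0; b <- 0
  for (g in 1:k) {
    pts <- X[cl == g, , drop = FALSE]
    ctr <- colMeans(pts)
    w <- w + sum(sweep(pts, 2, ctr)^2)
    b <- b + nrow(pts) * sum((ctr - grand)^2)
  }
  expect_equal(calinski_harabasz(X, cl), (b / k) / (w / (n - k)),
               tolerance = 1e-10)
})

test_that("CH scan bookkeeping, selection and tie handling", {
  withr::with_seed(6, {
    X <- rbind(matrix(rnorm(60 * 2), 60, 2),
               matrix(rnorm(60 * 2, mean = 8), 60, 2))
  })
  prof <- ch_scan(X, k_range = 2:6, n_starts = 20, seed = 5)
  expect_equal(nrow(prof), 5)
  expect_equal(attr(prof, "argmax_k"), 2)
  expect_gt(prof$ch[prof$k == 2], prof$ch[prof$k == 6])
  # tie handling: equal CH within tolerance resolved by prefer_larger_k
  prof2 <- prof
  prof2$ch <- c(100, 100.1, 50, 40, 30)
  ch_max <- max(prof2$ch)
  tied <- prof2$k[prof2$ch >= ch_max * (1 - 0.005)]
  expect_equal(tied, c(2L, 3L))
  expect_error(ch_scan(X, k_range = 1:4), "k_range")
})

test_that("stable small clusters are reported as outliers", {
  # bulk Gaussian plus a planted quintet and a far singleton
  withr::with_seed(31, Z <- matrix(rnorm(200 * 3), 200, 3))
  Z[196:200, 1] <- 9 + rnorm(5, 0, 0.1)   # tight small group
  Z[195, 2] <- 15                          # isolated point
  rep_ <- detect_outliers(Z, k_range = 2:8, n_starts = 50, seed = 3,
                          max_cluster_size = 6, min_stability = 3)
  rows <- attr(rep_, "outlier_rows")
  expect_true(all(195:200 %in% rows))
  expect_gte(nrow(rep_), 2)
  expect_true(all(rep_$stability_span >= 3))

  # unsatisfiable stability window gives an empty report
  rep0 <- detect_outliers(Z, k_range = 2:3, n_starts = 10, seed = 3,
                          min_stability = 5)
  expect_equal(nrow(rep0), 0)
  expect_equal(attr(rep0, "outlier_rows"), integer())

  # homogeneous data: nothing stable to flag
  withr::with_seed(32, H <- matrix(rnorm(150 * 3), 150, 3))
  repH <- detect_outliers(H, k_range = 2:8, n_starts = 25, seed = 4,
                          max_cluster_size = 2, min_stability = 4)
  expect_lte(length(attr(repH, "outlier_rows")), 2)
})

test_that("the two-phase pipeline is deterministic and self-consistent", {
  g <- generate_cohort(cohort_config(n = 300, seed = 55,
                                     typology_spec = default_typology_spec()))
  ct <- classification_truth(g)
  dat <- dplyr::bind_cols(ct[setdiff(names(ct), "absenteeism")],
                          lost = g$table$lost_days)
  run1 <- run_typology_pipeline(dat, vars = setdiff(names(dat), "row_id"),
                                k_range = 2:9, n_starts = 40, seed = 99)
  run2 <- run_typology_pipeline(dat, vars = setdiff(names(dat), "row_id"),
                                k_range = 2:9, n_starts = 40, seed = 99)
  expect_identical(run1$assignments, run2$assignments)
  expect_identical(run1$ch_profile$ch, run2$ch_profile$ch)

  # shares sum to 100 and sizes to the retained count
  expect_equal(sum(run1$typology$share_pct), 100, tolerance = 0.1)
  expect_equal(sum(run1$typology$n), nrow(run1$assignments))
  # restandardization leaves per-column rank structure unchanged
  kept <- run1$assignments$row_id
  for (v in setdiff(names(dat), "row_id")) {
    expect_equal(rank(dat[[v]][match(kept, dat$row_id)]),
                 rank(run1$z[[v]]))
  }
  gl <- glance(run1)
  expect_equal(gl$k, run1$solution$k)
  expect_s3_class(autoplot(run1), "ggplot")
  expect_s3_class(autoplot(run1$ch_profile), "ggplot")
})

test_that("cluster shares reproduce printed-style percentages", {
  # a 194-member cluster among 677 respondents is a 28.7% share
  assignments <- rep(1:7, c(90, 98, 88, 57, 194, 130, 20))
  share <- 100 * tabulate(assignments, 7) / length(assignments)
  expect_equal(round(share[5], 1), 28.7)
  expect_equal(length(assignments), 677)
})
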