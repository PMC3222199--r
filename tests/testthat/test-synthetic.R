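test_that("generation is deterministic given the seed", {
  g1 <- generate_cohort(cohort_config(n = 120, seed = 77))
  g2 <- generate_cohort(cohort_config(n = 120, seed = 77))
  expect_identical(g1$table, g2$table)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_cohort(cohort_config(n = 120, seed = 78))
  expect_false(identical(g1$table, g3$table))
})

test_that("the generated table passes its own schema and cleaning", {
  g <- generate_cohort(cohort_config(n = 200, seed = 5))
  expect_s3_class(g$table, "tbl_df")
  expect_equal(nrow(g$table), 200)
  expect_equal(nrow(g$truth), 200)
  # revalidation round-trip raises no errors
  revalidated <- as_cohort(g$table, g$schema)
  expect_equal(nrow(revalidated), 200)
  cleaned <- apply_exclusions(g$table)
  expect_equal(cleaning_report(cleaned)$n_retained, 200)
  # ordinal items respect their declared category sets
  for (v in c("four_sq", "smoking_habit", "wine_beer")) {
    cats <- g$schema$categories[[match(v, g$schema$name)]]
    expect_true(all(as.character(g$table[[v]]) %in% cats))
    expect_true(is.ordered(g$table[[v]]))
  }
})

test_that("per-sex clinical fields track their target moments", {
  g <- generate_cohort(cohort_config(n = 683, seed = 31, outlier_spec = NULL))
  params <- default_biochem_params()
  tab <- g$table
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    for (sx in c("male", "female")) {
      x <- tab[[v]][tab$sex == sx]
      mu <- if (sx == "male") params$male_mean[i] else params$female_mean[i]
      sdv <- if (sx == "male") params$male_sd[i] else params$female_sd[i]
      se <- sdv / sqrt(length(x))
      expect_lt(abs(mean(x) - mu), 3.5 * se + 0.05 * sdv)
    }
  }
})

test_that("the injected 300-day absentee is an extreme z-score", {
  g <- generate_cohort(cohort_config(seed = 13))
  z <- zscore_columns(g$table["lost_days"])$lost_days
  idx <- which(g$truth$outlier_group == "absentee")
  expect_equal(g$table$lost_days[idx], 300)
  expect_gt(z[idx], 12)
  expect_lt(z[idx], 25)
  expect_equal(max(z), z[idx])
})

test_that("injected outliers are the most extreme rows on their variables", {
  hits <- sapply(1:10, function(s) {
    g <- generate_cohort(cohort_config(seed = s))
    ls_rows <- which(g$truth$outlier_group == "lifestyle")
    top_alc <- order(g$truth$alcohol, decreasing = TRUE)[1:5]
    ab_row <- which(g$truth$outlier_group == "absentee")
    all(sort(top_alc) == sort(ls_rows)) &&
      which.max(g$table$lost_days) == ab_row
  })
  expect_gte(sum(hits), 9)
})

test_that("items co-loading on a latent grow more correlated with loadings", {
  withr::with_seed(61, {
    cors <- sapply(c(0.3, 0.6, 0.9), function(l) {
      items <- default_perception_items()
      items$loading[items$item %in% c("four_sq", "stress_scale")] <- l
      g <- generate_cohort(cohort_config(n = 600, perception_items = items,
                                         outlier_spec = NULL, seed = 601))
      cor(as.integer(g$table$four_sq), as.integer(g$table$stress_scale),
          method = "spearman")
    })
  })
  expect_true(all(diff(cors) > 0))
})

test_that("absenteeism is right-skewed, zero-inflated and stress-linked", {
  g <- generate_cohort(cohort_config(n = 683, seed = 41, outlier_spec = NULL))
  d <- g$table$lost_days
  expect_gte(mean(d == 0), 0.2)
  expect_gt(mean(d), median(d))  # right skew
  r <- cor(g$truth$stress, d)
  expect_gt(r, 0.08)
  expect_lt(r, 0.35)
})

test_that("planted typologies produce the declared mixture", {
  spec <- default_typology_spec()
  g <- generate_cohort(cohort_config(n = 677, typology_spec = spec,
                                     outlier_spec = NULL, seed = 8))
  expect_equal(sort(unique(g$truth$typology)), 1:7)
  shares <- tabulate(g$truth$typology, 7) / 677
  expect_lt(max(abs(shares - spec$weights)), 0.08)
  # latent centroids sit near the planted ones
  ctr <- rowsum(as.matrix(g$truth[, colnames(spec$centroids)]),
                g$truth$typology) / tabulate(g$truth$typology, 7)
  expect_lt(max(abs(ctr - spec$centroids)), 0.6)
})

test_that("recovery harness reports matched correlations, ARI and recall", {
  g <- generate_cohort(cohort_config(n = 300, typology_spec = default_typology_spec(),
                                     seed = 19))
  ct <- classification_truth(g)
  # perfect recovery: feed the truth back in
  rh <- recovery_harness(
    g,
    indicators = ct[c("row_id", "stress", "control", "activity", "smoking",
                      "alcohol")],
    assignments = tibble::tibble(row_id = ct$row_id,
                                 cluster = g$truth$typology),
    outlier_row_ids = g$truth$row_id[g$truth$outlier]
  )
  expect_equal(rh$value[rh$metric == "indicator_cor"], rep(1, 5),
               tolerance = 1e-12)
  expect_equal(rh$value[rh$metric == "ari"], 1)
  expect_equal(rh$value[rh$metric == "outlier_recall"], 1)
  expect_equal(rh$value[rh$metric == "outlier_precision"], 1)

  # no planted structure: ARI against arbitrary labels is about zero
  g0 <- generate_cohort(cohort_config(n = 400, seed = 23,
                                      typology_spec = default_typology_spec()))
  rand_cl <- withr::with_seed(3, sample(1:7, 400, replace = TRUE))
  rh0 <- recovery_harness(g0, assignments = tibble::tibble(
    row_id = g0$truth$row_id, cluster = rand_cl))
  expect_lt(abs(rh0$value[rh0$metric == "ari"]), 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n = 0), "positive")
  expect_error(cohort_config(male_fraction = 1.5), "male_fraction")
  expect_error(cohort_config(typology_spec = list(
    centroids = matrix(0, 3, 6), weights = c(0.5, 0.2, 0.2))), "sum to 1")
  expect_error(cohort_config(typology_spec = list(
    centroids = matrix(0, 3, 5), weights = c(0.6, 0.2, 0.2))), "6 columns")
  bad_items <- default_perception_items()
  bad_items$loading[1] <- 1.4
  expect_error(cohort_config(perception_items = bad_items), "loadings")
})
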