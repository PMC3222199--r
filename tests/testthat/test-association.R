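test_that("percentage profiles match hand-computed shares", {
  df <- data.frame(grp = rep(1, 683),
                   sex = rep(c("male", "female"), c(495, 188)))
  pp <- percent_profile(df, grp, sex)
  expect_equal(round(pp$within_pct[pp$category == "male"], 1), 72.5)
  # single typology: within equals total exactly
  expect_equal(pp$within_pct, pp$total_pct)

  # 60/40 typology split with category rates 50% vs 25% -> total 40%
  df2 <- data.frame(
    grp = rep(c("A", "B"), c(60, 40)),
    hit = c(rep(c("yes", "no"), c(30, 30)), rep(c("yes", "no"), c(10, 30)))
  )
  pp2 <- percent_profile(df2, grp, hit)
  expect_equal(pp2$within_pct[pp2$typology == "A" & pp2$category == "yes"], 50)
  expect_equal(pp2$within_pct[pp2$typology == "B" & pp2$category == "yes"], 25)
  expect_equal(pp2$total_pct[pp2$category == "yes"][1], 40)
})

test_that("total percentages are the size-weighted mean of within percentages", {
  withr::with_seed(17, {
    df <- data.frame(grp = sample(1:5, 400, replace = TRUE),
                     cat = sample(letters[1:4], 400, replace = TRUE))
  })
  pp <- percent_profile(df, grp, cat)
  for (cc in letters[1:4]) {
    sub <- pp[pp$category == cc, ]
    sizes <- as.vector(table(df$grp))
    expect_equal(sum(sub$within_pct * sizes) / sum(sizes),
                 sub$total_pct[1], tolerance = 1e-10)
  }
  # within each typology the percentages over categories sum to 100
  sums <- tapply(pp$within_pct, pp$typology, sum)
  expect_equal(as.numeric(sums), rep(100, 5), tolerance = 0.1)
})

test_that("chi-square independence test matches closed forms and the oracle", {
  even <- matrix(10, 2, 2)
  res <- chi_square_independence(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1)

  skew <- matrix(c(20, 10, 10, 20), 2, 2)
  res2 <- chi_square_independence(skew)
  expect_equal(round(res2$statistic, 3), 6.667)
  expect_equal(res2$statistic, oracle_chisq(skew), tolerance = 1e-10)

  withr::with_seed(23, {
    for (i in 1:10) {
      tab <- matrix(rpois(12, 20) + 1, 3, 4)
      expect_equal(chi_square_independence(tab)$statistic,
                   oracle_chisq(tab), tolerance = 1e-10)
    }
  })
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("adjusted residuals match the formula, the oracle and chisq stdres", {
  checker <- matrix(c(30, 10, 10, 30), 2, 2)
  apr <- adjusted_pearson_residuals(checker)
  expect_equal(round(abs(apr$residual), 3), rep(4.472, 4))
  expect_equal(sign(apr$residual), c(1, -1, -1, 1))

  # independent table: all residuals zero
  ind <- outer(c(20, 30), c(10, 40)) / 50
  apr0 <- adjusted_pearson_residuals(ind)
  expect_equal(apr0$residual, rep(0, 4), tolerance = 1e-10)

  withr::with_seed(29, {
    for (i in 1:10) {
      tab <- matrix(rpois(12, 15) + 1, 3, 4)
      apr_i <- attr(adjusted_pearson_residuals(tab), "residuals")
      expect_equal(apr_i, oracle_apr(tab), tolerance = 1e-10,
                   ignore_attr = TRUE)
      # cross-check against the reference implementation in stats
      std <- suppressWarnings(chisq.test(tab, correct = FALSE))$stdres
      expect_equal(apr_i, std, tolerance = 1e-10, ignore_attr = TRUE)
      # row sums of O - E vanish
      expect_equal(rowSums(tab - outer(rowSums(tab), colSums(tab)) / sum(tab)),
                   rep(0, 3), tolerance = 1e-10, ignore_attr = TRUE)
      # chi-square equals the sum of squared unadjusted residuals
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(chi_square_independence(tab)$statistic,
                   sum((tab - E)^2 / E), tolerance = 1e-10)
    }
  })
})

test_that("residual thresholds translate to the conventional tail p-values", {
  expect_equal(round(apr_tail_p(2), 3), 0.046)
  expect_equal(round(apr_tail_p(3), 3), 0.003)
  expect_lt(apr_tail_p(3.5), 0.001)
})

test_that("association flags bracket residuals by threshold and sign", {
  tab <- matrix(c(30, 10, 10, 30), 2, 2)
  apr <- adjusted_pearson_residuals(tab)
  fl <- flag_associations(apr)
  expect_equal(fl$flag_level[1], 3.5)   # |APR| = 4.47
  expect_equal(fl$direction[1], "+")
  expect_equal(fl$direction[2], "-")

  fake <- apr
  fake$residual <- c(-2.5, 1.9, 3.1, -0.5)
  fl2 <- flag_associations(fake)
  expect_equal(fl2$flag_level, c(2, 0, 3, 0))
  expect_equal(fl2$direction, c("-", "", "+", ""))
  # flag monotonicity: a 3.5-level cell is also beyond 3 and 2
  expect_true(all(fl$flag_level[abs(fl$residual) >= 3.5] == 3.5))
  fl3 <- flag_associations(apr, bonferroni = TRUE)
  expect_true(all(fl3$p_adjusted >= fl3$p_value))
  expect_s3_class(autoplot(apr), "ggplot")
})
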