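test_that("t tests match their degenerate and symmetric contracts", {
  x <- c(1, 2, 3)
  # identical data: statistic 0, p = 1, both paired and unpaired
  expect_identical(t_test(x, x, paired = TRUE)$p_value, 1)
  expect_identical(t_test(x, x, paired = TRUE)$statistic, 0)
  expect_identical(t_test(x, x)$statistic, 0)
  expect_identical(t_test(x, x)$p_value, 1)
  # zero variance everywhere, different means
  expect_identical(t_test(c(1, 1), c(2, 2))$p_value, 0)
  # symmetry: swapping groups flips the sign, p unchanged
  y <- c(2.5, 3.1, 4.0, 2.2)
  a <- t_test(x, y); b <- t_test(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  # agreement with the reference implementation on regular data
  expect_equal(a$p_value, stats::t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(t_test(x, y, welch = TRUE)$p_value,
               stats::t.test(x, y)$p.value)
  expect_error(t_test(1, c(1, 2)), "at least 2")
  expect_error(t_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal-length")
})

test_that("significance stars follow the legend convention", {
  expect_identical(significance_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("ANOVA + Tukey flags degenerate input and finds shifted groups", {
  expect_error(anova_tukey(rnorm(4), rep(c("a", "b"), 2)), "3 groups")
  # all groups identical constants: error flag, not a crash
  res <- anova_tukey(rep(5, 9), rep(letters[1:3], each = 3))
  expect_false(res$valid)
  # one group shifted by 5 SD
  withr::with_seed(43, {
    v <- c(rnorm(10), rnorm(10), rnorm(10, mean = 5))
    g <- rep(c("a", "b", "c"), each = 10)
    res2 <- anova_tukey(v, g)
  })
  expect_true(res2$valid)
  pw <- res2$pairwise
  expect_lt(pw$p_adj[pw$comparison == "c-a"], 0.001)
  expect_lt(pw$p_adj[pw$comparison == "c-b"], 0.001)
  expect_gt(pw$p_adj[pw$comparison == "b-a"], 0.05)
})

test_that("Tukey-adjusted p is never below the unadjusted pooled-error p", {
  # the comparable unadjusted test shares Tukey's pooled error term and
  # residual df (Fisher's LSD); the multiplicity adjustment can only
  # raise its p-value
  withr::with_seed(47, {
    for (i in 1:20) {
      v <- rnorm(24, mean = rep(runif(4, 0, 1), each = 6))
      g <- rep(letters[1:4], each = 6)
      res <- anova_tukey(v, g)
      fit <- stats::aov(v ~ g)
      mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
      df_res <- summary(fit)[[1]]["Residuals", "Df"]
      for (j in seq_len(nrow(res$pairwise))) {
        pair <- strsplit(res$pairwise$comparison[j], "-")[[1]]
        diff <- mean(v[g == pair[1]]) - mean(v[g == pair[2]])
        se <- sqrt(mse * (1 / 6 + 1 / 6))
        p_lsd <- 2 * stats::pt(abs(diff) / se, df_res, lower.tail = FALSE)
        expect_gte(res$pairwise$p_adj[j] + 1e-12, p_lsd)
      }
    }
  })
})

test_that("replicate-first aggregation summarizes and tests correctly", {
  df <- data.frame(
    value = c(rnorm(50, 0.9, 0.01), rnorm(50, 0.88, 0.01),
              rnorm(50, 0.7, 0.01), rnorm(50, 0.72, 0.01)),
    condition = rep(c("wt", "mut"), each = 100),
    replicate = rep(rep(1:2, each = 50), 2))
  agg <- aggregate_replicates(df)
  expect_identical(nrow(agg$replicate), 4L)
  expect_identical(agg$condition$n_replicates, c(2L, 2L))
  expect_s3_class(agg$test, "test_result")
  # invariance to within-replicate row order
  agg2 <- aggregate_replicates(df[sample(nrow(df)), ])
  expect_equal(agg$replicate$value, agg2$replicate$value)
  # single replicate, single value: SD missing, no test
  one <- aggregate_replicates(data.frame(value = 1, condition = "wt",
                                         replicate = 1))
  expect_true(is.na(one$condition$sd))
  expect_null(one$test)
  # three identical replicates: SD 0
  same <- aggregate_replicates(data.frame(value = rep(c(1, 2), 3),
                                          condition = "wt",
                                          replicate = rep(1:3, each = 2)))
  expect_identical(same$condition$sd, 0)
  # custom statistic: percentage of positives
  pct <- aggregate_replicates(
    data.frame(value = c(1, 0, 0, 0), condition = "wt", replicate = 1),
    statistic = function(v) 100 * mean(v >= 1))
  expect_identical(pct$replicate$value, 25)
})
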