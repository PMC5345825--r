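test_that("describe_features: means, degenerate SDs, empty groups", {
  df <- data.frame(x = c(1, 1, 1, 5, 6, 7), y = c(2, 2, 2, 2, 2, 2),
                   g = rep(c("a", "b"), each = 3))
  d <- describe_features(df, "g")
  expect_equal(d$sd[d$group == "a" & d$feature == "x"], 0)
  expect_equal(d$mean[d$group == "b" & d$feature == "x"], 6)
  expect_equal(d$min[d$group == "b" & d$feature == "x"], 5)
  one <- describe_features(data.frame(x = 3, g = "a"), "g")
  expect_equal(one$mean[one$feature == "x"], 3)
  expect_true(is.na(one$sd[one$feature == "x"]))
  expect_error(describe_features(df[0, ], "g"), "empty")
})

test_that("generator round-trip: published means recovered by describe", {
  tab <- sample_feature_table("normal", 10000, seed = 42)
  tab$g <- "normal"
  d <- describe_features(tab, "g", features = "Area")
  expect_lt(abs(d$mean - 117.1), 3 * 94.1 / sqrt(10000))
})

test_that("two_group_test: trivial, extreme and permutation-checked cases", {
  df <- data.frame(x = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r <- two_group_test(df, "x", "g")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(1)
  df2 <- data.frame(x = c(rnorm(100), rnorm(100, 5)),
                    g = rep(c("a", "b"), each = 100))
  expect_lt(two_group_test(df2, "x", "g")$p_value, 1e-15)

  # missing values dropped, n reported
  df3 <- df2; df3$x[c(1, 150)] <- NA
  expect_equal(two_group_test(df3, "x", "g")$n, c(99L, 99L))

  # agreement with a permutation oracle on a moderate-effect case
  set.seed(33)
  x <- c(rnorm(25, 0, 1), rnorm(25, 0.55, 1))
  g <- rep(c("a", "b"), each = 25)
  p_w <- two_group_test(data.frame(x = x, g = g), "x", "g",
                        var_equal = TRUE)$p_value
  obs <- abs(mean(x[g == "a"]) - mean(x[g == "b"]))
  perm <- replicate(5000, {
    sh <- sample(g)
    abs(mean(x[sh == "a"]) - mean(x[sh == "b"]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_w - p_perm), 0.01)
})

test_that("ks_compare: identical, disjoint and analytic uniform shift", {
  a <- rnorm(50)
  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(1:3, 4:6)$D, 1)
  set.seed(2)
  r <- ks_compare(runif(1000), runif(1000, 0.5, 1.5))
  expect_lt(abs(r$D - 0.5), 0.05)
})

test_that("multi_group_comparison: F = t^2 for two groups, power, errors", {
  set.seed(3)
  df <- data.frame(x = rnorm(40), g = rep(c("a", "b"), each = 20))
  Fres <- multi_group_comparison(df, "g")
  tres <- two_group_test(df, "x", "g", var_equal = TRUE)
  expect_equal(Fres$F, tres$statistic^2, tolerance = 1e-10)
  expect_equal(Fres$p_value, tres$p_value, tolerance = 1e-10)

  df2 <- data.frame(x = c(rnorm(30), rnorm(30), rnorm(30, 5)),
                    g = rep(c("a", "b", "c"), each = 30))
  expect_lt(multi_group_comparison(df2, "g")$p_value, 1e-6)
  expect_error(multi_group_comparison(data.frame(x = 1:5,
                                                 g = rep("a", 5)), "g"),
               "two groups")
})

test_that("stepwise_lda separates, selects and reports row percentages", {
  set.seed(4)
  df <- data.frame(x = c(rnorm(60), rnorm(60, 10)),
                   y = rnorm(120),
                   cls = rep(c("a", "b"), each = 60))
  fit <- stepwise_lda(df, "cls")
  expect_equal(fit$correct_rate, 100)
  expect_true("x" %in% fit$selected)
  expect_equal(unname(rowSums(fit$confusion)), c(100, 100),
               tolerance = 1e-9)

  # informative + 10 noise features: informative kept, few noise enter
  hits <- 0L; lean <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- as.data.frame(matrix(rnorm(100 * 11), 100))
    X$V1 <- X$V1 + rep(c(0, 2), each = 50)
    X$cls <- rep(c("a", "b"), each = 50)
    f <- stepwise_lda(X, "cls")
    hits <- hits + ("V1" %in% f$selected)
    lean <- lean + (length(setdiff(f$selected, "V1")) <= 2L)
  }
  expect_gte(hits, 19L)
  expect_gte(lean, 18L)
})

test_that("features reported non-significant separate least in simulation", {
  # at the published means/SDs, Compactness/ModRatio/Sphericity (the three
  # non-flagged features) should rank among the weakest separators
  nt <- sample_feature_table("normal", 4000, seed = 11)
  xt <- sample_feature_table("neoplastic", 4000, seed = 12)
  both <- rbind(nt, xt)
  res <- multi_group_comparison(both, "group")
  ord <- res$feature[order(res$p_value, decreasing = TRUE)]
  expect_true(all(c("Compactness", "ModRatio", "Sphericity") %in% ord[1:5]))
})

test_that("cohort_summary computes shares and totals", {
  s <- cohort_summary(c(affected = 15, healthy = 585))
  expect_equal(unname(s$share_pct["affected"]), 2.5)
  expect_equal(s$total, 600)
  expect_equal(unname(cohort_summary(c(a = 0, b = 10))$share_pct["a"]), 0)
  expect_equal(cohort_summary(c(normal = 28141, neoplastic = 92083))$total,
               120224)
  expect_error(cohort_summary(c(0, 0)), "zero total")
  expect_error(cohort_summary(c(-1, 5)), "nonnegative")
})
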