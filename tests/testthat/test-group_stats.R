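# hand decomposition oracle for one-way ANOVA
anova_oracle <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, 1L)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the hand decomposition", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- one_way_anova(groups)
  expect_equal(res$f_stat, 3.0)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 6L)
  oracle <- anova_oracle(groups)
  expect_equal(res$f_stat, oracle$f, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  # random fixture
  set.seed(1)
  g2 <- list(rnorm(5), rnorm(6, 1), rnorm(4, 2), rnorm(7))
  expect_equal(one_way_anova(g2)$f_stat, anova_oracle(g2)$f,
               tolerance = 1e-10)
})

test_that("ANOVA degenerate and identity cases", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$f_stat, 0)
  expect_error(one_way_anova(list(c(1, 2), c(3))), "at least 2")
  # two groups: F equals the square of the pooled t statistic
  set.seed(2)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  f <- one_way_anova(list(a, b))$f_stat
  t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("Tukey HSD matches a Monte-Carlo studentized-range oracle", {
  set.seed(33)
  n <- 6
  groups <- list(rnorm(n, 0), rnorm(n, 1.1), rnorm(n, 0.3))
  res <- tukey_hsd(groups)
  expect_equal(nrow(res), 3)
  # observed studentized-range statistics
  k <- 3
  means <- vapply(groups, mean, numeric(1))
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / (k * (n - 1))
  se <- sqrt(msw / n)
  pairs_idx <- list(c(2, 1), c(3, 1), c(3, 2))
  q_obs <- vapply(pairs_idx, function(ij) {
    abs(means[ij[1]] - means[ij[2]]) / se
  }, numeric(1))
  # Monte-Carlo null distribution of the max studentized range
  B <- 50000
  set.seed(34)
  null_means <- matrix(rnorm(B * k, 0, 1 / sqrt(n)), B, k)
  null_s2 <- rchisq(B, k * (n - 1)) / (k * (n - 1))
  q_null <- (apply(null_means, 1, max) - apply(null_means, 1, min)) /
    sqrt(null_s2 / n)
  p_mc <- vapply(q_obs, function(q) mean(q_null >= q), numeric(1))
  expect_equal(unname(res$p_adj), p_mc, tolerance = 0.01)
})

test_that("Tukey HSD boundary behaviour", {
  same <- list(c(1, 2, 3, 2), c(2, 1, 3, 2), c(2, 3, 1, 2))
  expect_false(any(tukey_hsd(same)$significant))
  far <- list(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01))
  expect_true(all(tukey_hsd(far)$significant))
})

test_that("Pearson correlation matches brute-force formulas", {
  expect_equal(pearson_with_ci(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_ci(c(1, 2, 3), c(6, 4, 2))$r, -1)
  set.seed(9)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12, 0, 0.8)
  res <- pearson_with_ci(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_brute, tolerance = 1e-12)
  # Fisher-z CI oracle
  z <- atanh(r_brute)
  zse <- 1 / sqrt(length(x) - 3)
  expect_equal(res$ci95,
               tanh(c(z - qnorm(0.975) * zse, z + qnorm(0.975) * zse)),
               tolerance = 1e-10)
  # two-tailed t-test oracle on n - 2 df
  tstat <- r_brute * sqrt((length(x) - 2) / (1 - r_brute^2))
  expect_equal(res$p_two_tailed, 2 * pt(-abs(tstat), length(x) - 2),
               tolerance = 1e-10)
  expect_error(pearson_with_ci(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_with_ci(1:2, 1:2), "at least 3")
})

test_that("correlation strength classes follow the magnitude rule", {
  expect_identical(classify_r(0.7), "strong")
  expect_identical(classify_r(-0.69), "moderate")
  expect_identical(classify_r(0.29), "negligible")
  expect_identical(classify_r(0.5), "moderate")
  expect_identical(classify_r(0.3), "fair")
  expect_identical(classify_r(-1), "strong")
  expect_identical(classify_r(c(0.75, -0.4)), c("strong", "fair"))
  expect_error(classify_r(1.2), "not a correlation")
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  # hand step-up oracle on random vectors; order invariance
  set.seed(4)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(adj, 1)[order(o)]
  }
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlation matrix is symmetric, BH-adjusted and starred", {
  set.seed(12)
  n <- 40
  x <- rnorm(n)
  df <- data.frame(animal_id = paste0("a", 1:n),
                   f1 = x, f2 = x + rnorm(n, 0, 0.1),
                   f3 = rnorm(n), f4 = rnorm(n))
  res <- correlation_matrix(df)
  expect_identical(res$features, c("f1", "f2", "f3", "f4"))
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_identical(res$stars["f1", "f2"], "***")
  # BH pools all off-diagonal tests jointly
  up <- upper.tri(res$p_raw)
  expect_equal(res$p_adj[up], bh_adjust(res$p_raw[up]))
  # zero-variance feature excluded with a warning
  df$flat <- 1
  expect_warning(res2 <- correlation_matrix(df), "flat")
  expect_false("flat" %in% res2$features)
})

test_that("null features yield few BH discoveries", {
  set.seed(99)
  df <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  res <- correlation_matrix(df)
  frac <- mean(res$p_adj[upper.tri(res$p_adj)] < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 45))
})
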