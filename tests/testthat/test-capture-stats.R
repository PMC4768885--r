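test_that("the count transform is ln(x + 1)", {
  expect_equal(log1_transform(0), 0)
  expect_equal(log1_transform(exp(1) - 1), 1)
  expect_error(log1_transform(c(3, -1)), "non-negative")
})

test_that("summaries use the n-1 denominator at one-decimal report precision", {
  tab <- table2()
  s <- summarize_captures(tab)
  row <- s[s$column == "tml_trapped", ]
  expect_equal(round(row$mean, 1), 324.1)
  expect_equal(round(row$sd, 1), 134.7)
  const <- summarize_captures(data.frame(x = c(5, 5, 5)))
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)
  two <- summarize_captures(data.frame(x = c(4, 69)))
  expect_equal(two$mean, 36.5)
  expect_equal(round(two$sd, 2), 45.96)
  expect_error(summarize_captures(data.frame(x = 1)), "2 rows")
})

test_that("one-way F equals the squared pooled t and known closed forms", {
  a <- one_way_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(a$statistic[1], 13.5, tolerance = 1e-12)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(a$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p.value[1], tt$p.value, tolerance = 1e-10)
  # identity holds on arbitrary data
  set.seed(401)
  for (k in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), mean = runif(1))
    aov1 <- one_way_anova(x, y)
    t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)^2
    expect_equal(aov1$statistic[1], t2, tolerance = 1e-10)
  }
})

test_that("degenerate one-way inputs are flagged, never an exception", {
  same <- one_way_anova(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$statistic[1], 0)
  nores <- one_way_anova(c(1, 1, 1), c(5, 5, 5))
  expect_true(is.infinite(nores$statistic[1]))
  expect_true(attr(nores, "degenerate"))
})

test_that("two-way ANOVA has the factorial df structure and conserves SS", {
  set.seed(402)
  d <- expand.grid(bait = c("Control", "TML", "TML-DDVP"),
                   surface = paste("S", 1:5), rep = 1:7)
  d$response <- rnorm(nrow(d), mean = as.integer(factor(d$bait)))
  a <- two_way_anova(d)
  expect_equal(a$df, c(2, 4, 8, 90))
  total_ss <- sum((d$response - mean(d$response))^2)
  expect_equal(sum(a$sumsq), total_ss, tolerance = 1e-8 * total_ss)
  expect_equal(a$meansq, a$sumsq / a$df)
  # balanced data: marginal (Type II) SS coincide with sequential
  b <- two_way_anova(d, ss_type = "marginal")
  expect_equal(b$sumsq, a$sumsq, tolerance = 1e-8)
})

test_that("F statistics do not depend on the base of the logarithm", {
  tab <- table2()
  for (col in c("in_tub", "trapped", "total")) {
    x <- tab[[paste0("tml_", col)]]; y <- tab[[paste0("tml_ddvp_", col)]]
    f_ln <- one_way_anova(log(x + 1), log(y + 1))$statistic[1]
    f_10 <- one_way_anova(log10(x + 1), log10(y + 1))$statistic[1]
    expect_equal(f_ln, f_10, tolerance = 1e-10)
  }
})

test_that("two-way degenerate and single-level inputs behave as specified", {
  d <- expand.grid(bait = c("A", "B"), surface = c("x", "y"), rep = 1:3)
  d$response <- 1
  a <- two_way_anova(d)
  expect_true(attr(a, "degenerate"))
  expect_true(all(is.nan(a$statistic[1:3]) | a$statistic[1:3] == 0))
  d2 <- d; d2$bait <- "A"; d2$response <- rnorm(nrow(d2))
  expect_error(two_way_anova(d2), "2 levels")
})

test_that("null interaction F has mean near one with uniform p-values", {
  set.seed(403)
  nsim <- 400
  d0 <- expand.grid(bait = c("A", "B", "C"), surface = paste("S", 1:5),
                    rep = 1:3)
  bait_eff <- c(A = 0, B = 1, C = 2)
  fs <- numeric(nsim); ps <- numeric(nsim)
  for (i in seq_len(nsim)) {
    d0$response <- bait_eff[d0$bait] + rnorm(nrow(d0))
    a <- two_way_anova(d0)
    fs[i] <- a$statistic[3]; ps[i] <- a$p.value[3]
  }
  # mean of F(8, 30) is 30/28
  expect_lt(abs(mean(fs) - 30 / 28), 3 * sd(fs) / sqrt(nsim))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Fisher LSD reduces to the unadjusted t-test for two groups", {
  set.seed(404)
  for (k in 1:10) {
    x <- rnorm(7, 0); y <- rnorm(7, runif(1, 0, 2))
    a <- one_way_anova(x, y)
    lsd <- fisher_lsd(c(a = mean(x), b = mean(y)), n_per_cell = 7,
                      residual_ms = a$meansq[2], residual_df = a$df[2])
    tt <- t.test(x, y, var.equal = TRUE)
    expect_identical(lsd$significant, tt$p.value < 0.05)
  }
  zero <- fisher_lsd(c(a = 1, b = 1), 5, residual_ms = 0.5,
                     residual_df = 8)
  expect_false(zero$significant)
})

test_that("LSD decisions match a quadrature t-tail at the ANOVA residual", {
  lsd <- fisher_lsd(c(a = 0, b = 1), n_per_cell = 7, residual_ms = 0.6,
                    residual_df = 88, alpha = 0.05)
  tstat <- 1 / sqrt(2 * 0.6 / 7)
  p_brute <- t_tail_quadrature(tstat, 88)
  expect_identical(lsd$significant, p_brute < 0.05)
  expect_error(fisher_lsd(c(1, 2), 7, 0.6, 88, alpha = 1.5), "alpha")
  expect_error(fisher_lsd(c(1, 2), 7, 0, 88), "residual_ms")
})

test_that("KS D statistic matches the analytic stepwise supremum", {
  n <- 25
  x <- qnorm((seq_len(n) - 0.5) / n, mean = 3, sd = 2)
  k <- ks_normality(x, mean = 3, sd = 2)
  expect_equal(k$statistic, 0.5 / n, tolerance = 1e-12)
  expect_error(ks_normality(c(1, 2)), "3 values")
  expect_error(ks_normality(c(2, 2, 2)), "variance")
})

test_that("KS is consistent under the null", {
  set.seed(405)
  x <- rnorm(2000, 10, 2)
  k <- ks_normality(x)
  expect_lt(k$statistic, 0.05)
  expect_gt(k$p.value, 0.2)
})

test_that("capture ANOVA power rises with the treatment effect", {
  set.seed(406)
  rates <- vapply(c(1, 2, 4), function(mult) {
    mean(replicate(150, {
      x <- rnbinom(7, mu = 35, size = 3)
      y <- rnbinom(7, mu = 35 * mult, size = 3)
      a <- one_way_anova(log1_transform(x), log1_transform(y))
      a$p.value[1] < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[3], 0.8)
})
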