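test_that("OLS matches the normal-equations oracle on random instances", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(10:30, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-8)
    expect_equal(fit$df, n - p - 1)
    # classical SEs from the oracle covariance
    s2 <- sum((y - Xi %*% beta)^2) / (n - p - 1)
    expect_equal(unname(fit$se), sqrt(diag(s2 * solve(t(Xi) %*% Xi))),
                 tolerance = 1e-8)
  }
})

test_that("exact linear data give zero residuals; degenerate designs error", {
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  y <- 3 + 2 * X[, 1] - X[, 2]
  fit <- fit_ols(y, X)
  expect_true(all(abs(fit$residuals) < 1e-10))
  expect_equal(unname(fit$coefficients), c(3, 2, -1), tolerance = 1e-10)
  yc <- rep(4, 20)
  expect_equal(unname(fit_ols(yc, X)$coefficients), c(4, 0, 0),
               tolerance = 1e-10)
  expect_error(fit_ols(y, cbind(X, X[, 1])), "singular")
  expect_error(fit_ols(y[1:3], X[1:3, ]), "n > p")
})

test_that("LOOCV fast path equals an explicit refit loop", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(8:25, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    e_loop <- vapply(seq_len(n), function(i) {
      fit <- lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
      y[i] - sum(c(1, X[i, ]) * fit$coefficients)
    }, 0)
    expect_equal(loocv_rmse(y, X),
                 sqrt(mean(e_loop^2) - mean(e_loop)^2), tolerance = 1e-8)
    expect_equal(loocv_rmse(y, X, bias_corrected = FALSE),
                 sqrt(mean(e_loop^2)), tolerance = 1e-8)
  }
})

test_that("LOOCV RMSE vanishes on exactly linear data", {
  set.seed(23)
  X <- matrix(rnorm(30), 15, 2)
  y <- 1 + X %*% c(2, -0.5)
  expect_lt(loocv_rmse(y, X), 1e-8)
})

test_that("a pure-noise predictor inflates LOOCV RMSE in expectation", {
  set.seed(24)
  diffs <- replicate(200, {
    X <- matrix(rnorm(100), 50, 2)
    y <- 2 * X[, 1] + rnorm(50)
    loocv_rmse(y, X) - loocv_rmse(y, X[, 1, drop = FALSE])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.5)
})

test_that("subset selection enumerates 2^p - 1 models with documented ties", {
  set.seed(25)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  d$y <- 1 + d$x1 + rnorm(40, sd = 0.3)
  m <- loocv_select(y ~ x1 + x2 + x3, d)
  expect_equal(nrow(m$comparison), 7L)
  expect_equal(m$criterion, min(m$comparison$loocv_rmse_bc))
  # selection invariant to candidate order
  m2 <- loocv_select(y ~ x3 + x2 + x1, d)
  expect_setequal(m2$selected, m$selected)
  # single candidate trivially selected
  m1 <- loocv_select(y ~ x1, d)
  expect_equal(m1$selected, "x1")
  expect_equal(nrow(m1$comparison), 1L)
})

test_that("loocv_select methods behave like a model object", {
  set.seed(26)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  d$y <- 2 * d$x1 + rnorm(60)
  m <- loocv_select(y ~ x1 + x2, d)
  expect_s3_class(m, "loocv_select")
  expect_named(coef(m), c("(Intercept)", m$selected))
  expect_equal(length(residuals(m)), 60)
  expect_equal(predict(m), m$fit$fitted)
  nd <- data.frame(x1 = c(0, 1), x2 = c(0, 0))
  pr <- predict(m, nd)
  expect_equal(pr[2] - pr[1], unname(coef(m)["x1"]))
  expect_output(print(m), "Selected")
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$estimate, -1)
  set.seed(27)
  x <- c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9)
  y <- c(2, 1, 4, 4, 6, 5, 9, 8, 8, 10)
  res <- spearman_cor(x, y)
  # brute-force mid-rank oracle
  r_oracle <- cor(rank(x), rank(y))
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  tt <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(abs(tt), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$estimate,
               unname(cor.test(x, y, method = "spearman",
                               exact = FALSE)$estimate))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("partial correlation matches the closed form and handles degeneracy", {
  set.seed(28)
  for (rep in 1:20) {
    n <- 30
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    pc <- partial_cor(x, y, z)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    expect_equal(pc$estimate,
                 (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
                 tolerance = 1e-10)
  }
  # an exactly orthogonal covariate leaves the Pearson correlation intact
  x <- rnorm(25); y <- rnorm(25)
  z <- residualize(rnorm(25), cbind(x, y))
  expect_equal(partial_cor(x, y, z)$estimate, cor(x, y), tolerance = 1e-10)
  # y identical to the covariate: zero residual variance
  expect_error(partial_cor(x, z, z), "constant")
})

test_that("residualisation returns mean-zero residuals orthogonal to covariates", {
  set.seed(29)
  Z <- matrix(rnorm(60), 30, 2)
  y <- Z %*% c(1, -2) + rnorm(30)
  r <- residualize(y, Z)
  expect_lt(abs(mean(r)), 1e-10)
  expect_true(all(abs(crossprod(Z, r)) < 1e-8))
  age <- rnorm(30, 60, 5)
  expect_true(all(abs(residualize(3 * age, age)) < 1e-10))
})

test_that("median split cuts at the mid-rank median with ties going low", {
  s <- median_split(c(0, 0, 1, 1, 2, 3))
  expect_equal(s$cut, 1)
  expect_equal(as.character(s$group),
               c("low", "low", "low", "low", "high", "high"))
  s2 <- median_split(c(0, 5))
  expect_equal(s2$n_low, 1); expect_equal(s2$n_high, 1)
  expect_error(median_split(rep(2, 10)), "degenerate")
  # a combined-risk-like integer vector with median 1 splits <=1 vs >1
  scores <- rep(c(0, 1, 2, 3), c(46, 56, 33, 7))
  s3 <- median_split(scores)
  expect_equal(s3$cut, 1)
  expect_equal(s3$n_low, 102); expect_equal(s3$n_high, 40)
})

test_that("pooled t-test matches the hand formula and is antisymmetric", {
  a <- c(1.1, 2.3, 0.7); b <- c(2.0, 2.9, 3.4)
  res <- two_sample_t(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  same <- c(1, 2, 3)
  expect_equal(two_sample_t(same, same)$t, 0)
  expect_equal(two_sample_t(same, same)$p, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("pooled t-test holds its nominal size under the null", {
  set.seed(30)
  rej <- replicate(5000, two_sample_t(rnorm(20), rnorm(20))$p < 0.05)
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Holm adjustment reproduces the step-down worked example", {
  adj <- holm_adjust(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(adj$p_holm, c(0.03, 0.06, 0.06))
  expect_identical(adj$reject, c(TRUE, FALSE, FALSE))
  one <- holm_adjust(0.02)
  expect_equal(one$p_holm, 0.02)
  allzero <- holm_adjust(rep(0, 4))
  expect_true(all(allzero$reject))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(0.5, alpha = 1.5), "alpha")
})

test_that("Holm rejections sit between Bonferroni and unadjusted", {
  set.seed(31)
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- holm_adjust(p, alpha = 0.05)
    ord <- order(p)
    expect_true(all(diff(adj$p_holm[ord]) >= -1e-15))
    expect_true(all(adj$p_holm >= p))
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(adj$reject[bonf]))       # superset of Bonferroni
    expect_true(all(p[adj$reject] <= 0.05))  # subset of unadjusted
  }
})
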