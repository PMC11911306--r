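test_that("pearson matches the covariance formula and handles degeneracy", {
  expect_equal(pearson(1:10, 1:10)$r, 1)
  expect_equal(pearson(1:10, -2 * (1:10) + 3)$r, -1)
  set.seed(71)
  for (rep in 1:5) {
    x <- rnorm(25); y <- rnorm(25)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson(x, y)$r, r_oracle, tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("partial correlation residualises on the controls", {
  set.seed(72)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partial_correlation(x, y, NULL)$r, pearson(x, y)$r)
  # y identical to a control: nothing left to correlate
  z <- rnorm(40)
  expect_lt(abs(partial_correlation(x, z, z)$r), 1e-10)
  # inverse-correlation-matrix oracle
  for (rep in 1:5) {
    Z <- matrix(rnorm(40 * 2), 40)
    x <- rnorm(40) + Z[, 1]; y <- rnorm(40) + 0.5 * Z[, 2]
    P <- solve(cor(cbind(x, y, Z)))
    r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    got <- partial_correlation(x, y, Z)
    expect_equal(got$r, r_oracle, tolerance = 1e-10)
    expect_equal(got$df, 40 - 2 - 2)
  }
  expect_error(partial_correlation(x, y, cbind(Z, Z[, 1])), "collinear")
})

test_that("the dependent-correlation test behaves like a t-statistic", {
  same <- compare_dependent_correlations(0.5, 0.5, 0.3, 50)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 47)
  a <- compare_dependent_correlations(0.6, 0.3, 0.4, 40)
  b <- compare_dependent_correlations(0.3, 0.6, 0.4, 40)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p, b$p)
  expect_error(compare_dependent_correlations(0.99, -0.99, 0.99, 30),
               "degenerate")
})

test_that("the dependent-correlation test holds its nominal level", {
  # trivariate normals with equal true correlations of both variables
  # with the criterion (common-factor construction)
  set.seed(73)
  n <- 60
  reject <- vapply(seq_len(2000), function(i) {
    f <- rnorm(n)
    x1 <- 0.6 * f + rnorm(n)
    x2 <- 0.6 * f + rnorm(n)
    x3 <- 0.6 * f + rnorm(n)
    r13 <- cor(x1, x3); r23 <- cor(x2, x3); r12 <- cor(x1, x2)
    compare_dependent_correlations(r13, r23, r12, n)$p <= 0.05
  }, TRUE)
  expect_lt(abs(mean(reject) - 0.05), 0.01)
})

test_that("Bland-Altman agreement has its closed forms", {
  a <- c(9.1, 9.8, 10.4, 8.7, 10.9)
  same <- bland_altman(a, a)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$loa_low, same$loa_high)

  shift <- bland_altman(a, a - 0.5)
  expect_equal(shift$bias, 0.5)
  expect_equal(shift$sd_diff, 0)

  set.seed(74)
  x <- rnorm(30, 10); y <- x + rnorm(30, 0.2, 0.3)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  expect_equal(ba$proportional_slope,
               unname(coef(lm(d ~ I((x + y) / 2)))[2]))
})

test_that("regression with RMSE recovers exact coefficients", {
  x <- seq(8, 12, length.out = 20)
  fit <- linreg_rmse(x, 3 * x - 5)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(-5, 3), tolerance = 1e-10)

  # two-predictor form: noise-free coefficients come back exactly
  set.seed(75)
  A1 <- rnorm(30, 2); A2 <- rnorm(30, 1)
  age <- 68.8 - 22.5 * A1 + 44.1 * A2
  fit2 <- linreg_rmse(cbind(A1, A2), age)
  expect_equal(unname(fit2$coefficients), c(68.8, -22.5, 44.1),
               tolerance = 1e-8)
  expect_equal(fit2$r, 1, tolerance = 1e-10)

  # normal-equations oracle, and the divisor convention
  X <- cbind(rnorm(25), rnorm(25)); y <- rnorm(25)
  fit3 <- linreg_rmse(X, y)
  beta_oracle <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(fit3$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-10)
  res <- y - cbind(1, X) %*% beta_oracle
  expect_equal(fit3$rmse, sqrt(mean(res^2)))
  expect_equal(linreg_rmse(X, y, divisor = "residual_df")$rmse,
               sqrt(sum(res^2) / (25 - 3)))
  expect_error(linreg_rmse(cbind(X, X[, 1]), y), "singular")
})

test_that("paired t-test handles degenerate differences explicitly", {
  a <- c(9.5, 10.1, 9.8, 10.4)
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(a, a)$p, 1)
  shifted <- paired_t(a + 1, a)
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p, 0)
  set.seed(76)
  x <- rnorm(20); y <- rnorm(20)
  got <- paired_t(x, y)
  d <- x - y
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  expect_equal(got$df, 19)
})

test_that("paired t-test holds its nominal level", {
  set.seed(77)
  reject <- vapply(seq_len(2000), function(i) {
    x <- rnorm(20); y <- rnorm(20)
    paired_t(x, y)$p <= 0.05
  }, TRUE)
  expect_lt(abs(mean(reject) - 0.05), 0.01)
})

test_that("MINQUE(1) equals ANOVA estimators on balanced grids", {
  set.seed(78)
  for (rep in 1:3) {
    P <- 12; C <- 6
    a <- rnorm(P, sd = 2); b <- rnorm(C, sd = 1)
    Y <- outer(a, rep(1, C)) + outer(rep(1, P), b) +
      matrix(rnorm(P * C, sd = 1.5), P)
    got <- minque_components(Y)
    # expected-mean-squares oracle for the two-way crossed model without
    # replication
    msa <- C * var(rowMeans(Y))
    msb <- P * var(colMeans(Y))
    mse <- sum((Y - outer(rowMeans(Y), rep(1, C)) -
                  outer(rep(1, P), colMeans(Y)) + mean(Y))^2) /
      ((P - 1) * (C - 1))
    oracle <- c((msa - mse) / C, (msb - mse) / P, mse)
    expect_equal(unname(got$raw), oracle, tolerance = 1e-8)
    expect_equal(sum(got$proportions), 1, tolerance = 1e-12)
  }
})

test_that("MINQUE attributes pure participant shifts to the between term", {
  Y <- outer(c(1, 5, 9, 13), rep(1, 5))
  got <- minque_components(Y)
  expect_equal(unname(got$proportions["between_subject"]), 1,
               tolerance = 1e-8)
})

test_that("MINQUE recovers known components on average and allows missing", {
  set.seed(79)
  est <- t(vapply(1:40, function(i) {
    P <- 20; C <- 10
    Y <- outer(rnorm(P, sd = 2), rep(1, C)) +
      outer(rep(1, P), rnorm(C, sd = 1)) +
      matrix(rnorm(P * C, sd = sqrt(2)), P)
    Y[sample(length(Y), 8)] <- NA
    unname(minque_components(Y)$raw)
  }, numeric(3)))
  means <- colMeans(est)
  ses <- apply(est, 2, sd) / sqrt(40)
  expect_lt(abs(means[1] - 4), 4 * ses[1])
  expect_lt(abs(means[2] - 1), 4 * ses[2])
  expect_lt(abs(means[3] - 2), 4 * ses[3])
  expect_error(minque_components(matrix(1, 1, 5)), "at least 2")
})

test_that("JZS Bayes factors penalise complexity and match an MC oracle", {
  set.seed(80)
  n <- 100
  x1 <- rnorm(n)
  y <- 0.7 * x1 + rnorm(n)
  same <- jzs_regression_bf01(y, x1, x1)
  expect_equal(same$bf01, 1)

  # Occam penalty: an added pure-noise covariate is disfavoured
  pref_null <- vapply(1:30, function(i) {
    x <- rnorm(60); yy <- 0.6 * x + rnorm(60)
    jzs_regression_bf01(yy, x, cbind(x, rnorm(60)))$bf01 > 1
  }, TRUE)
  expect_gte(mean(pref_null), 0.9)

  # quadrature against a Monte-Carlo importance-sampling oracle of the
  # same g-integral (inverse-gamma prior draws)
  r_scale <- 0.354
  X <- cbind(x1, rnorm(n))
  r2 <- summary(lm(y ~ X))$r.squared
  p <- ncol(X)
  g <- 1 / stats::rgamma(4e5, shape = 0.5, rate = n * r_scale^2 / 2)
  mc <- mean(exp((n - 1 - p) / 2 * log1p(g) -
                   (n - 1) / 2 * log1p(g * (1 - r2))))
  quad <- jzs_regression_bf01(y, NULL, X)$bf10_alt
  expect_lt(abs(quad - mc) / mc, 0.02)

  expect_error(jzs_regression_bf01(y, cbind(rnorm(n)), X), "nest")
})
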