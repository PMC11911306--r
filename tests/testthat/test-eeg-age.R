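test_that("PLS1 fits exactly representable responses and degenerate ones", {
  set.seed(51)
  # two predictors, noise-free linear response: two factors span the
  # predictor space, so the fit is exact
  X <- matrix(rnorm(40 * 2), 40)
  y <- 2 * X[, 1] - 3 * X[, 2] + 7
  fit <- fit_pls(X, y, 2)
  expect_lt(sqrt(mean((fit$fitted - y)^2)), 1e-8)
  expect_equal(cor(fit$fitted, y), 1)
  expect_equal(fit$beta, c(2, -3), tolerance = 1e-10)

  # constant response: zero coefficients, mean prediction
  X6 <- matrix(rnorm(40 * 6), 40)
  fitc <- fit_pls(X6, rep(5, 40), 3)
  expect_equal(fitc$beta, rep(0, 6))
  expect_equal(fitc$fitted, rep(5, 40))

  expect_error(fit_pls(X6, y, 10), "rank")
})

test_that("PLS predictions match the explicit score-regression oracle", {
  set.seed(52)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 12), 30)
    y <- rnorm(30)
    A <- 3
    fit <- fit_pls(X, y, A)
    # oracle: recompute scores by explicit NIPALS deflation, then regress
    # y on them by ordinary least squares
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    Xd <- Xc; yd <- yc
    Tm <- matrix(0, 30, A)
    for (a in 1:A) {
      w <- crossprod(Xd, yd); w <- w / sqrt(sum(w^2))
      t <- Xd %*% w
      p <- crossprod(Xd, t) / sum(t^2)
      Tm[, a] <- t
      yd <- yd - as.numeric(crossprod(t, yd) / sum(t^2)) * t
      Xd <- Xd - t %*% t(p)
    }
    pred_oracle <- mean(y) + Tm %*% lm.fit(Tm, yc)$coefficients
    expect_equal(fit$fitted, as.numeric(pred_oracle), tolerance = 1e-8)
    # explained variance is nondecreasing in information: proportions sum
    # below 1 and are each nonnegative
    expect_true(all(fit$explained_y_variance >= 0))
    expect_lte(sum(fit$explained_y_variance), 1 + 1e-12)
  }
})

test_that("predict_age is centring-consistent and validates the grid", {
  set.seed(53)
  X <- matrix(rnorm(30 * 8), 30)
  y <- X[, 1] + rnorm(30, sd = 0.1) + 50
  fit <- fit_pls(X, y, 2)
  expect_equal(predict_age(fit, X), fit$fitted)
  fit2 <- fit_pls(X, y + 7, 2)
  expect_equal(predict_age(fit2, X), predict_age(fit, X) + 7,
               tolerance = 1e-10)
  expect_error(predict_age(fit, X[, 1:5]), "grid")
})

test_that("permutation factor selection is calibrated and powerful", {
  set.seed(54)
  # type I: pure-noise response keeps zero factors almost always
  n_null <- 60
  hits <- vapply(seq_len(n_null), function(i) {
    X <- matrix(rnorm(20 * 10), 20)
    sel <- select_factors_by_permutation(X, rnorm(20), max_factors = 2,
                                         n_perm = 199, seed = i)
    sel$n_significant
  }, 0L)
  expect_gte(mean(hits == 0), 0.9)

  # power: a planted two-factor structure (a second, weaker X-direction
  # carrying a large share of the response) is found
  found <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    n <- 40
    s1 <- rnorm(n); s2 <- rnorm(n)
    p1 <- rnorm(25); p2 <- rnorm(25)
    X <- s1 %*% t(p1) + 0.3 * s2 %*% t(p2) +
      matrix(rnorm(n * 25, sd = 0.05), n)
    y <- s1 + 3 * s2 + rnorm(n, sd = 0.05)
    select_factors_by_permutation(X, y, max_factors = 4, n_perm = 199,
                                  seed = i)$n_significant
  }, 0L)
  expect_gte(mean(found >= 2), 0.9)

  # determinism under a fixed seed
  X <- matrix(rnorm(20 * 10), 20); y <- rnorm(20)
  a <- select_factors_by_permutation(X, y, max_factors = 3, n_perm = 199,
                                     seed = 9)
  b <- select_factors_by_permutation(X, y, max_factors = 3, n_perm = 199,
                                     seed = 9)
  expect_identical(a, b)
})

test_that("VIP scores obey their closed form and identity", {
  set.seed(55)
  # one informative predictor concentrates the VIP mass
  n <- 50
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 7, sd = 1), n))
  y <- 3 * X[, 1]
  fit <- fit_pls(X, y, 1)
  v <- vip_scores(fit)
  expect_equal(unname(v[1]), sqrt(8) * abs(fit$W[1, 1]), tolerance = 1e-12)
  expect_gt(v[1], 2.5)

  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 15), 30)
    y <- rnorm(30)
    fit <- fit_pls(X, y, 3)
    v <- vip_scores(fit)
    expect_equal(mean(v^2), 1, tolerance = 1e-12)
    # brute-force summation oracle
    p <- ncol(X)
    ssy <- fit$explained_y_variance
    oracle <- vapply(seq_len(p), function(j) {
      num <- sum(vapply(1:3, function(a)
        ssy[a] * (fit$W[j, a] / sqrt(sum(fit$W[, a]^2)))^2, 0))
      sqrt(p * num / sum(ssy))
    }, 0)
    expect_equal(unname(v), oracle, tolerance = 1e-12)
  }
})

test_that("leave-one-out cross-validation matches a hand-rolled loop", {
  set.seed(66)
  X <- matrix(rnorm(25 * 4), 25)
  y <- X[, 1] - 2 * X[, 3] + rnorm(25, sd = 0.1)
  cv <- pls_loocv(X, y, 2)
  i <- 7
  fit_i <- fit_pls(X[-i, ], y[-i], 2)
  expect_equal(cv$predictions[i], predict_age(fit_i, X[i, , drop = FALSE]))
  expect_equal(cv$rmse, sqrt(mean((cv$predictions - y)^2)))
  # strong signal survives held-out prediction
  expect_gt(cv$r, 0.9)
  # out-of-sample error is no smaller than the in-sample error
  fit_all <- fit_pls(X, y, 2)
  expect_gte(cv$rmse, sqrt(mean((fit_all$fitted - y)^2)) - 1e-12)
})

test_that("recursive weighted PLS isolates planted frequency support", {
  set.seed(56)
  n <- 50; p <- 40
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- sprintf("f%0.1f", seq_len(p) / 2)
  y <- 3 * X[, 10] - 2 * X[, 25] + rnorm(n, sd = 0.05)
  res <- rpls_select(X, y, n_factors = 2)
  expect_true(all(c(10, 25) %in% res$selected))
  expect_lte(length(res$selected), 6)
  expect_lte(res$iterations, 50)
  expect_gt(cor(res$final_model$fitted, y), 0.95)

  # pure noise terminates without assertions on the surviving set
  resn <- rpls_select(X, rnorm(n), n_factors = 2)
  expect_lte(resn$iterations, 50)

  # a duplicated informative column: at least one twin survives
  X2 <- X; X2[, 11] <- X2[, 10]
  res2 <- rpls_select(X2, y, n_factors = 2)
  expect_true(any(c(10, 11) %in% res2$selected))
})

test_that("PARAFAC recovers exact low-rank structure and flags overfactoring", {
  set.seed(57)
  a <- rnorm(12); b <- rnorm(8); cc <- rnorm(20)
  t1 <- outer(a, outer(b, cc))
  fit1 <- fit_parafac(t1, 1, n_replications = 4, seed = 1)
  expect_lt(fit1$sse / sum(t1^2), 1e-10)
  expect_equal(fit1$corcondia, 100, tolerance = 1e-4)
  # unit-norm loading convention
  expect_equal(sum(fit1$B[, 1]^2), 1, tolerance = 1e-10)
  expect_equal(sum(fit1$C[, 1]^2), 1, tolerance = 1e-10)

  t2 <- t1 + outer(rnorm(12), outer(rnorm(8), rnorm(20)))
  fit3 <- fit_parafac(t2, 3, n_replications = 6, max_iter = 500, seed = 2)
  expect_lt(fit3$corcondia, 80)

  fit1b <- fit_parafac(t1, 1, n_replications = 4, seed = 1)
  expect_identical(fit1$replicates, fit1b$replicates)
  expect_equal(fit1$A, fit1b$A)
})

test_that("PARAFAC rank scan reports nonincreasing error", {
  set.seed(58)
  tens <- outer(rnorm(10), outer(rnorm(6), rnorm(15))) +
    outer(rnorm(10), outer(rnorm(6), rnorm(15))) +
    array(rnorm(10 * 6 * 15, sd = 0.05), c(10, 6, 15))
  scan <- parafac_rank_scan(tens, factors = 1:3, n_replications = 3,
                            max_iter = 300, seed = 3)
  expect_equal(scan$n_factors, 1:3)
  expect_true(all(diff(scan$sse) <= 1e-8))
  expect_true(all(scan$corcondia <= 100 + 1e-6))
})

test_that("trilinear PLS recovers a planted trilinear age signal", {
  set.seed(59)
  n <- 30
  ages <- runif(n, 20, 80)
  chan_prof <- abs(rnorm(6)); chan_prof <- chan_prof / sqrt(sum(chan_prof^2))
  freq_prof <- exp(-0.5 * ((seq_len(40) - 20) / 5)^2)
  freq_prof <- freq_prof / sqrt(sum(freq_prof^2))
  tens <- (ages - mean(ages)) %o% (chan_prof %o% freq_prof)
  fit <- fit_tripls(tens, ages, 1)
  expect_gt(abs(fit$factor_cor[1]), 0.99)
  expect_equal(fit$fitted, ages, tolerance = 1e-8)
  expect_equal(sum(fit$channel_weights[, 1]^2), 1, tolerance = 1e-10)
  expect_equal(sum(fit$frequency_weights[, 1]^2), 1, tolerance = 1e-10)

  # constant response: flat regression, mean prediction
  fitc <- fit_tripls(tens, rep(42, n), 2)
  expect_equal(fitc$fitted, rep(42, n), tolerance = 1e-10)

  expect_error(fit_tripls(tens, ages[-1], 1), "first mode")
})

test_that("spectral age models recover a planted cohort age signal", {
  # spectra synthesized directly from the generative model (no time
  # series), a fast stand-in for the full pipeline
  grid <- frequency_grid()
  coh <- generate_cohort(cohort_spec(n_participants = 40, seed = 61,
                                     montage = tiny_montage()))
  ages <- cohort_table(coh)$age
  chans <- tiny_montage()$label
  spectra <- lapply(seq_along(coh$participants), function(i) {
    p <- coh$participants[[i]]
    vapply(chans, function(ch)
      synthesize_spectrum(p, ch, grid, noise_sd = 0.1,
                          seed = 700 + 10 * i + match(ch, chans))$values[, 1],
      numeric(length(grid)))
  })
  X <- t(vapply(spectra, function(m)
    svd_first_component(t(m))$component_spectrum, numeric(length(grid))))
  # the generator plants only the alpha-centre trend, against sizeable
  # participant-specific amplitude/offset variation; six latent factors
  # span enough of that nuisance space to expose the age signal
  pls6 <- fit_pls(X, ages, 6)
  expect_gt(cor(pls6$fitted, ages), 0.6)
  # in-sample mean prediction equals the mean age (OLS-on-scores)
  expect_equal(mean(pls6$fitted), mean(ages), tolerance = 1e-8)

  # cross-method consistency at a matched factor count
  pls3 <- fit_pls(X, ages, 3)
  tens <- aperm(simplify2array(spectra), c(3, 2, 1))
  tri <- fit_tripls(tens, ages, 3)
  expect_lt(abs(cor(tri$fitted, ages) - cor(pls3$fitted, ages)),
            0.1 + 1e-9)
})
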