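grid <- frequency_grid()

test_that("alpha peak finding matches a brute-force neighbour scan", {
  set.seed(41)
  f <- seq(5, 15, by = 0.1)
  for (rep in 1:300) {
    v <- as.numeric(stats::filter(rnorm(length(f)), rep(1 / 3, 3),
                                  sides = 2))
    v[is.na(v)] <- rnorm(sum(is.na(v)))
    got <- find_alpha_peaks(v, f)
    want <- which(vapply(2:(length(v) - 1), function(i)
      v[i] > v[i - 1] && v[i] > v[i + 1], TRUE)) + 1L
    want <- want[f[want] >= 7 & f[want] <= 13]
    expect_equal(got$frequency, f[want])
    expect_equal(got$amplitude, v[want])
  }
  # strictly monotone spectrum has no peaks; endpoints never count
  expect_equal(nrow(find_alpha_peaks(seq_along(f), f)), 0)
})

test_that("N-PAF averages per-channel best peaks with a low-frequency tie-break", {
  f <- seq(6, 14, by = 0.1)
  gauss <- function(mu, a = 1) a * exp(-0.5 * ((f - mu) / 0.5)^2)
  m <- cbind(ch1 = gauss(10), ch2 = gauss(10))
  expect_equal(naive_paf(m, f)$value, 10)
  m2 <- cbind(ch1 = gauss(9), ch2 = gauss(11))
  est <- naive_paf(m2, f)
  expect_equal(est$value, 10)
  expect_equal(unname(est$per_channel), c(9, 11))
  expect_equal(est$n_channels_used, 2L)
  # two exactly equal peaks in one channel: lower frequency wins
  m3 <- cbind(ch1 = gauss(8.5) + gauss(11.5))
  expect_equal(naive_paf(m3, f)$value, 8.5)
  # peakless channels are missing, not fabricated
  m4 <- cbind(ch1 = gauss(10), ch2 = f)
  est4 <- naive_paf(m4, f)
  expect_equal(est4$n_channels_used, 1L)
  expect_equal(est4$value, 10)
  expect_true(is.na(naive_paf(cbind(ch1 = f), f)$value))
})

test_that("D-PAF reads the SVD component peak and degrades to missing", {
  s <- 2 * exp(-0.5 * ((grid - 10.3) / 1)^2) + 4 * (0.1 * grid)^-0.25
  sv <- svd_first_component(outer(c(0.8, 1, 1.2), s))
  expect_equal(direct_paf(sv, grid)$value, 10.3)
  aper <- 4 * (0.1 * grid)^-0.25
  expect_true(is.na(direct_paf(svd_first_component(outer(c(1, 1.1), aper)),
                               grid)$value))
  # dominant-alpha model spectrum: D-PAF within a grid step of the dense
  # numeric argmax of the model itself
  p <- make_participant(mu = c(4, 9.4, 16, 25, 35))
  v <- synthesize_spectrum(p, "O1", grid)$values[, 1]
  dense_f <- seq(7, 13, by = 0.001)
  dense_v <- eval_spectral_model(p$true_params, dense_f, alpha_gain = 1.2)
  f_oracle <- dense_f[which.max(dense_v)]
  est <- direct_paf(v, grid)
  expect_lt(abs(est$value - f_oracle), 0.1 + 1e-9)
})

test_that("the spectral model fit recovers generating parameters", {
  set.seed(17)
  coh <- generate_cohort(cohort_spec(n_participants = 6, seed = 19))
  for (p in coh$participants) {
    truth <- p$true_params
    v <- synthesize_spectrum(p, "Pz", grid)$values[, 1]
    fit <- fit_spectral_model(v, grid, n_starts = 10, seed = 1)
    expect_lt(max(abs(fit$bands$mu - truth$bands$mu)), 0.05)
    amp_true <- truth$bands$amp
    amp_true[2] <- amp_true[2] * p$channel_gains[["Pz"]]
    expect_lt(max(abs(fit$bands$amp - amp_true)), 0.05)
    expect_lt(abs(fit$m - truth$m), 0.05)
    expect_gt(fit$adj_r2, 0.999)
  }
})

test_that("the fit does not hallucinate an absent alpha peak", {
  p <- make_participant(amp = c(0.3, 0, 0.3, 0.2, 0.1))
  v <- synthesize_spectrum(p, "Cz", grid)$values[, 1]
  fit <- fit_spectral_model(v, grid, n_starts = 10, seed = 2)
  expect_lt(fit$bands$amp[2], 0.1)
})

test_that("noisy fits stay above the adjusted-R2 quality floor", {
  coh <- generate_cohort(cohort_spec(n_participants = 20, seed = 29))
  r2 <- vapply(seq_along(coh$participants), function(i) {
    p <- coh$participants[[i]]
    v <- synthesize_spectrum(p, "Pz", grid, noise_sd = 0.1,
                             seed = 100 + i)$values[, 1]
    fit_spectral_model(v, grid, n_starts = 5, seed = i)$adj_r2
  }, 0)
  expect_gte(mean(r2 >= 0.96), 0.95)
})

test_that("M-PAF is the alpha-Gaussian centre", {
  par <- spectral_model_params(4, -0.25, -2, amp = c(0, 1, 0, 0, 0),
                               mu = c(4, 9.63, 16, 25, 35),
                               sigma = c(1, 1, 3, 3, 4))
  expect_equal(modeled_paf(par)$value, 9.63)
  par$bands$mu[2] <- 7.85
  expect_equal(modeled_paf(par)$value, 7.85)
  expect_equal(modeled_paf(par)$method, "M")
})

test_that("C-PAF admits channels by the 1-SD-above-background rule", {
  f <- seq(0.5, 45, by = 0.25)
  bg <- 10 * f^-1
  peak <- function(a, mu = 10) a * exp(-0.5 * ((f - mu) / 1)^2)
  strong <- lapply(1:4, function(i) list(freq = f, power = bg + peak(5)))
  est <- corcoran_paf(strong)
  expect_equal(est$value, 10, tolerance = 1e-6)
  w <- est$channel_weights[!is.na(est$channel_weights)]
  expect_equal(unname(w / sum(w)), rep(0.25, 4))

  # half the channels peakless: excluded, value from the rest
  mixed <- c(strong[1:2],
             lapply(1:2, function(i) list(freq = f, power = bg)))
  est2 <- corcoran_paf(mixed, min_channels = 2)
  expect_equal(est2$n_channels_used, 2L)
  expect_equal(est2$value, 10, tolerance = 1e-6)
  # admissibility oracle, channel by channel: log peak power must exceed
  # the background regression prediction by one residual SD
  for (ci in seq_along(mixed)) {
    p <- mixed[[ci]]$power
    pk <- find_alpha_peaks(p, f)
    admitted <- FALSE
    if (nrow(pk)) {
      pk <- pk[which.max(pk$amplitude), ]
      idx <- f >= 1 & f <= 40 & !(f >= 7 & f <= 13)
      bgfit <- lm(log(p[idx]) ~ log(f[idx]))
      pred <- coef(bgfit)[1] + coef(bgfit)[2] * log(pk$frequency)
      admitted <- unname(log(pk$amplitude) > pred + sd(residuals(bgfit)))
    }
    expect_equal(unname(!is.na(est2$per_channel[ci])), admitted)
  }

  # too few admissible channels: explicit missing state
  est3 <- corcoran_paf(mixed, min_channels = 3)
  expect_true(is.na(est3$value))
  expect_equal(est3$n_channels_used, 2L)
})

test_that("K-PAF computes the centre of gravity over individual alpha bands", {
  f <- seq(0.5, 45, by = 0.25)
  # symmetric peak on a flat background: CoG at the mode
  sym <- 1 + exp(-0.5 * ((f - 10) / 1)^2) +
    0.5 * exp(-0.5 * ((f - 4) / 1)^2) + 0.5 * exp(-0.5 * ((f - 16) / 1)^2)
  est <- klimesch_paf(list(list(freq = f, power = sym)))
  expect_equal(est$value, 10, tolerance = 0.01)

  # right-skewed hump: CoG above the mode (numeric oracle on the band)
  skew <- 1 + exp(-0.5 * ((f - 9.5) / 0.8)^2) +
    0.8 * exp(-0.5 * ((f - 11) / 1.6)^2) +
    0.5 * exp(-0.5 * ((f - 4) / 1)^2) + 0.5 * exp(-0.5 * ((f - 16) / 1)^2)
  estk <- klimesch_paf(list(list(freq = f, power = skew)))
  mode_f <- f[which.max(skew * (f > 7 & f < 13))]
  expect_gt(estk$value, mode_f)

  # peakless channels give a missing estimate
  expect_true(is.na(klimesch_paf(list(list(freq = f, power = 10 * f^-1),
                                      list(freq = f, power = f)))$value))
})

test_that("all five estimators agree on a high-SNR single-peak spectrum", {
  # a gentle aperiodic slope keeps clear troughs on both sides of the
  # dominant alpha peak, so every estimator (including the individually
  # bounded centre of gravity) sees a well-defined peak
  p <- make_participant(mu = c(4, 10.2, 16, 25, 35),
                        amp = c(0.3, 2.5, 0.3, 0.2, 0.1), m = -0.05,
                        gains = c(F3 = 0.9, Cz = 1, Pz = 1.1, O1 = 1.2))
  chans <- names(p$channel_gains)
  m <- vapply(chans, function(ch)
    synthesize_spectrum(p, ch, grid)$values[, 1], numeric(length(grid)))
  n <- naive_paf(m, grid)$value
  sv <- svd_first_component(t(m))
  d <- direct_paf(sv, grid)$value
  mm <- modeled_paf(fit_spectral_model(sv$component_spectrum, grid,
                                       seed = 1))$value
  # C/K run on power spectra, as from the smoothed-Welch branch
  welch_like <- lapply(chans, function(ch) {
    f <- seq(0.25, 45, by = 0.25)
    v <- eval_spectral_model(p$true_params, f,
                             alpha_gain = p$channel_gains[[ch]])
    normalize_and_smooth((2^v)^2, f)
  })
  cc <- corcoran_paf(welch_like)$value
  k <- klimesch_paf(welch_like)$value
  five <- c(N = n, D = d, M = mm, C = cc, K = k)
  expect_lt(max(five) - min(five), 0.3)
  # and the direct/model pair agrees tightly on dominant-alpha spectra
  expect_lt(abs(d - mm), 0.2)
})
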