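# Method-agreement and inference layer: Pearson and partial correlations,
# the Hotelling-Williams test for dependent correlations, Bland-Altman
# agreement, regression with RMSE, paired t-tests, MINQUE variance
# components for the participant x channel PAF grid, and JZS Bayes
# factors for nested regressions.

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `r`, `p`, `t`, `df`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       t = unname(ct$statistic), df = unname(ct$parameter), n = length(x))
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the OLS residuals of `x` and `y` on the control
#' variables, with the degrees of freedom reduced by the number of
#' controls: `t = r sqrt((n - 2 - k) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors.
#' @param controls Matrix/data frame of control variables (may be empty).
#' @return List with `r`, `p`, `t`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0 || length(controls) == 0)
    return(pearson(x, y))
  Z <- as.matrix(controls)
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n <= k + 3) stop("need n > #controls + 3", call. = FALSE)
  D <- cbind(1, Z)
  if (qr(D)$rank < ncol(D)) stop("collinear controls", call. = FALSE)
  rx <- lm.fit(D, x)$residuals
  ry <- lm.fit(D, y)$residuals
  # a variable fully explained by the controls leaves only numerical dust
  if (sd(rx) < 1e-10 * max(sd(x), 1) || sd(ry) < 1e-10 * max(sd(y), 1)) {
    k <- ncol(Z)
    return(list(r = 0, p = 1, t = 0, df = n - 2 - k, n = n))
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tval), df), t = tval, df = df, n = n)
}

#' Compare two dependent correlations (Hotelling-Williams)
#'
#' Tests whether variable 1 and variable 2 correlate equally strongly
#' with variable 3, given that all three were measured on the same `n`
#' cases:
#' `t = (r13 - r23) sqrt(((n-1)(1+r12)) / (2((n-1)/(n-3))|R| + rbar^2 (1-r12)^3))`
#' with `|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23`,
#' `rbar = (r13 + r23)/2`, and `df = n - 3`.
#'
#' @param r13,r23 Correlations being compared.
#' @param r12 Correlation between the two compared variables.
#' @param n Sample size (>= 4).
#' @return Object of class `correlation_comparison` with `t_stat`, `df`,
#'   `p` and the inputs.
#' @export
compare_dependent_correlations <- function(r13, r23, r12, n) {
  stopifnot(n >= 4, abs(r13) <= 1, abs(r23) <= 1, abs(r12) <= 1)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) stop("degenerate correlation matrix (|R| <= 0)",
                      call. = FALSE)
  rbar <- (r13 + r23) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3
  tval <- (r13 - r23) * sqrt((n - 1) * (1 + r12) / denom)
  structure(list(r13 = r13, r23 = r23, r12 = r12, n = n,
                 t_stat = tval, df = n - 3,
                 p = 2 * pt(-abs(tval), n - 3)),
            class = "correlation_comparison")
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`. Reports the bias (mean difference), the SD of
#' the differences, the 95% limits of agreement `bias -/+ 1.96 SD`, and
#' the proportional-error slope from the OLS regression of the
#' differences on the pair means.
#'
#' @param a,b Paired measurements of the same quantity.
#' @return Object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `proportional_slope`, `n`.
#' @export
bland_altman <- function(a, b) {
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  s <- sd(d)
  slope <- if (sd(m) > 0) unname(coef(lm(d ~ m))[2]) else NA_real_
  structure(list(bias = mean(d), sd_diff = s,
                 loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s,
                 proportional_slope = slope, n = length(d)),
            class = "bland_altman")
}

#' OLS regression with root-mean-square error
#'
#' RMSE uses divisor `n` by default (the in-sample "error of estimation"
#' convention that pairs with an in-sample regression line); the residual
#' degrees-of-freedom divisor is available as an option. `r` is the
#' multiple correlation between fitted and observed values.
#'
#' @param X Predictor vector/matrix.
#' @param y Response.
#' @param divisor `"n"` (default) or `"residual_df"`.
#' @return Object of class `regression_fit` with `coefficients`
#'   (intercept first), `r`, `rmse`, `r_squared`, `n`.
#' @export
linreg_rmse <- function(X, y, divisor = c("n", "residual_df")) {
  divisor <- match.arg(divisor)
  X <- as.matrix(X)
  ok <- complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n <= ncol(X) + 1) stop("need n > #predictors + 1", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X)
  if (qr(D)$rank < ncol(D)) stop("singular design matrix", call. = FALSE)
  fit <- lm.fit(D, y)
  res <- fit$residuals
  den <- if (divisor == "n") n else n - ncol(D)
  fitted <- y - res
  r <- if (sd(fitted) > 0) cor(fitted, y) else 0
  structure(list(coefficients = fit$coefficients, r = r,
                 rmse = sqrt(sum(res^2) / den),
                 r_squared = r^2, n = n, fitted = fitted),
            class = "regression_fit")
}

#' Paired t-test (one-sample t on the differences)
#'
#' Zero-variance differences are handled explicitly: `t = 0, p = 1` for a
#' zero mean difference and `t = +-Inf, p = 0` for a nonzero constant
#' shift.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  ok <- complete.cases(a, b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1,
                                  mean_diff = 0, n = n))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), n = n))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), n = n)
}

#' MINQUE variance components for a participant-by-channel grid
#'
#' Two-way crossed random-effects model
#' `y_pc = mu + a_p + b_c + e_pc` with between-subject (participants),
#' within-subject (channels) and error components, estimated by the
#' Minimum Norm Quadratic Unbiased Estimator with all prior weights equal
#' to one (scheme 1). Missing cells are allowed. Negative raw estimates
#' are truncated to zero for the reported proportions; raw values are
#' preserved.
#'
#' @param values Participants-by-channels numeric matrix, `NA` for
#'   missing cells.
#' @return Object of class `variance_components` with `raw` and
#'   `proportions` (between_subject, within_subject, error).
#' @export
minque_components <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 participants and 2 channels", call. = FALSE)
  idx <- which(!is.na(values), arr.ind = TRUE)
  n <- nrow(idx)
  if (n < nrow(values) + ncol(values) + 2)
    stop("too few non-missing cells", call. = FALSE)
  y <- values[idx]
  U1 <- outer(idx[, 1], seq_len(nrow(values)), `==`) * 1
  U2 <- outer(idx[, 2], seq_len(ncol(values)), `==`) * 1
  V <- list(between_subject = tcrossprod(U1),
            within_subject = tcrossprod(U2),
            error = diag(n))
  V0 <- V[[1]] + V[[2]] + V[[3]]
  V0inv <- solve(V0)
  v1 <- V0inv %*% rep(1, n)
  R <- V0inv - v1 %*% t(v1) / sum(v1)
  M <- lapply(V, function(Vi) R %*% Vi)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    S[i, j] <- S[j, i] <- sum(M[[i]] * t(M[[j]]))
  }
  ry <- R %*% y
  q <- vapply(V, function(Vi) as.numeric(t(ry) %*% Vi %*% ry), 0)
  theta <- solve(S, q)
  names(theta) <- names(V)
  trunc <- pmax(theta, 0)
  props <- if (sum(trunc) > 0) trunc / sum(trunc) else rep(NA_real_, 3)
  structure(list(raw = theta, proportions = props, n_cells = n),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("MINQUE(1) variance components:\n")
  print(round(rbind(estimate = x$raw, proportion = x$proportions), 4))
  invisible(x)
}

#' JZS Bayes factor for nested regressions
#'
#' For each model the Bayes factor against the intercept-only model uses
#' the Jeffreys-Zellner-Siow mixture-of-g prior,
#' `BF10 = integral (1+g)^((n-1-p)/2) (1+g(1-R^2))^(-(n-1)/2) pi(g) dg`
#' with `pi(g)` inverse-gamma(1/2, n r^2 / 2), evaluated by adaptive
#' quadrature. `bf01` is the evidence ratio favouring the null (simpler)
#' model over the alternative; the null's covariates must be a subset of
#' the alternative's.
#'
#' @param y Response.
#' @param covariates_null Matrix/data frame (or `NULL` for the
#'   intercept-only null).
#' @param covariates_alt Matrix/data frame of the richer model.
#' @param r_scale JZS prior scale (default 0.354).
#' @return Object of class `bayes_factor_result` with `bf01`,
#'   `bf10_null`, `bf10_alt`, `r_scale`.
#' @export
jzs_regression_bf01 <- function(y, covariates_null, covariates_alt,
                                r_scale = 0.354) {
  Xa <- if (is.null(covariates_alt)) NULL else as.matrix(covariates_alt)
  Xn <- if (is.null(covariates_null) || NCOL(covariates_null) == 0) NULL
        else as.matrix(covariates_null)
  n <- length(y)
  if (!is.null(Xn)) {
    if (is.null(Xa)) stop("null covariates must nest in the alternative",
                          call. = FALSE)
    aug <- cbind(Xn, Xa)
    if (qr(aug)$rank > qr(Xa)$rank)
      stop("null covariates must nest in the alternative", call. = FALSE)
  }
  if (!is.null(Xa) && n <= ncol(Xa) + 2)
    stop("need n > #alt covariates + 2", call. = FALSE)
  bf_n <- .jzs_bf10(y, Xn, r_scale)
  bf_a <- .jzs_bf10(y, Xa, r_scale)
  structure(list(bf01 = bf_n / bf_a, bf10_null = bf_n, bf10_alt = bf_a,
                 r_scale = r_scale, method = "adaptive quadrature"),
            class = "bayes_factor_result")
}

.jzs_bf10 <- function(y, X, r_scale) {
  if (is.null(X) || NCOL(X) == 0) return(1)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  r2 <- summary(lm(y ~ X))$r.squared
  a <- n * r_scale^2 / 2
  log_f <- function(g)
    (n - 1 - p) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
      0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g
  # integrate on the log scale with a stabilising shift
  peak <- stats::optimize(log_f, c(1e-6, 1e7), maximum = TRUE)$objective
  val <- integrate(function(g) exp(log_f(g) - peak), 0, Inf,
                   rel.tol = 1e-9, subdivisions = 500L)$value
  exp(peak) * val
}
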