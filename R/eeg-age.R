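# Age prediction from the broad 0.1-45 Hz spectrum: univariate-response
# (PLS1) partial least squares via NIPALS, permutation-based factor
# selection, VIP scores, recursive weighted PLS for frequency selection,
# PARAFAC alternating least squares with the core consistency diagnostic,
# and trilinear PLS1 on the participant x channel x frequency tensor.

#' Fit a PLS1 regression (NIPALS)
#'
#' Predictors and response are centred internally. Factor weights
#' maximise covariance with the (deflated) response; the regression
#' vector `beta` maps centred predictors to the response.
#'
#' @param X Participants-by-predictors matrix (e.g. SVD summary spectra).
#' @param y Numeric response (chronological age).
#' @param n_factors Number of latent factors.
#' @return Object of class `pls_model`: weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, `beta`, `intercept`, per-factor
#'   `explained_y_variance` (proportions of the response sum of squares),
#'   in-sample `fitted`, and centring constants.
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows(X) must match length(y)", call. = FALSE)
  if (n < n_factors + 2)
    stop("need at least n_factors + 2 observations", call. = FALSE)
  if (n_factors > min(n - 1, p) || n_factors > qr(X)$rank)
    stop("n_factors exceeds the rank of X", call. = FALSE)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  ssy <- sum(yc^2)
  W <- P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- tt <- numeric(n_factors)
  Xd <- Xc; yd <- yc
  a_done <- 0L
  for (a in seq_len(n_factors)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # nothing left to model (e.g. constant y)
    w <- w / nw
    t <- Xd %*% w
    tt[a] <- sum(t^2)
    pv <- crossprod(Xd, t)[, 1] / tt[a]
    q[a] <- sum(t * yd) / tt[a]
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t
    Xd <- Xd - t %*% t(pv)
    yd <- yd - q[a] * t
    a_done <- a
  }
  if (a_done == 0L) {
    beta <- numeric(p)
    expl <- numeric(0)
  } else {
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    Tm <- Tm[, seq_len(a_done), drop = FALSE]
    q <- q[seq_len(a_done)]; tt <- tt[seq_len(a_done)]
    beta <- W %*% solve(crossprod(P, W), q)
    expl <- if (ssy > 0) q^2 * tt / ssy else rep(0, a_done)
  }
  intercept <- y_center - sum(x_center * beta)
  fitted <- as.numeric(X %*% beta + intercept)
  structure(list(n_factors = a_done, W = W, P = P, q = q, scores = Tm,
                 score_ss = tt, beta = as.numeric(beta),
                 intercept = intercept,
                 explained_y_variance = as.numeric(expl),
                 fitted = fitted, x_center = x_center, y_center = y_center,
                 predictor_names = colnames(X)),
            class = "pls_model")
}

#' Predict from a fitted PLS model (EEG-age)
#'
#' @param model A [fit_pls()] model.
#' @param X_new New predictor matrix on the same grid.
#' @return Predicted response values.
#' @export
predict_age <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_center))
    stop("predictor grid mismatch", call. = FALSE)
  as.numeric(X_new %*% model$beta + model$intercept)
}

#' Leave-one-out cross-validation of a PLS age model
#'
#' Refits the model with each participant held out in turn and predicts
#' the held-out response. In-sample correlations flatter any
#' high-dimensional regression; this is the honest companion number.
#'
#' @inheritParams fit_pls
#' @return List with out-of-sample `predictions`, their correlation `r`
#'   with the observed response, and `rmse` (divisor n).
#' @export
pls_loocv <- function(X, y, n_factors) {
  X <- as.matrix(X)
  n <- nrow(X)
  pred <- vapply(seq_len(n), function(i) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_factors)
    predict_age(fit, X[i, , drop = FALSE])
  }, 0)
  list(predictions = pred,
       r = if (sd(pred) > 0) cor(pred, y) else NA_real_,
       rmse = sqrt(mean((pred - y)^2)))
}

#' Select the number of PLS factors by permutation
#'
#' Factor k is retained when its incremental explained response variance
#' is significantly larger than under permuted responses: the permutation
#' p-value `(1 + #{perm >= observed}) / (n_perm + 1)` must be at most
#' `level`. Permuted responses are refitted through the full sequential
#' NIPALS, and selection stops at the first non-significant factor.
#'
#' @inheritParams fit_pls
#' @param max_factors Largest factor count examined.
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param level One-sided significance level.
#' @param seed RNG seed for the permutations.
#' @return List with `n_significant`, per-factor `p_values` and the
#'   observed incremental variances.
#' @export
select_factors_by_permutation <- function(X, y, max_factors = 10,
                                          n_perm = 1000, level = 0.05,
                                          seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  X <- as.matrix(X)
  max_factors <- min(max_factors, qr(X)$rank, nrow(X) - 2)
  obs <- .incr_variance(X, y, max_factors)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      .incr_variance(X, sample(y), max_factors), numeric(max_factors))
  })
  perm <- matrix(perm, nrow = max_factors)
  pvals <- vapply(seq_len(max_factors), function(k)
    (1 + sum(perm[k, ] >= obs[k])) / (n_perm + 1), 0)
  n_sig <- 0L
  for (k in seq_len(max_factors)) {
    if (pvals[k] <= level) n_sig <- k else break
  }
  list(n_significant = n_sig, p_values = pvals, observed_increment = obs)
}

# incremental explained-y-variance of each factor (padded with zeros when
# the fit exhausts early)
.incr_variance <- function(X, y, max_factors) {
  m <- fit_pls(X, y, max_factors)
  out <- numeric(max_factors)
  if (m$n_factors > 0)
    out[seq_len(m$n_factors)] <- m$explained_y_variance
  out
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` with
#' `p` predictors and `SSY_a` the response variance explained by factor
#' `a`; the mean of the squared scores over predictors is 1.
#'
#' @param model A [fit_pls()] model.
#' @return Per-predictor VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  ssy <- model$explained_y_variance
  if (length(ssy) == 0 || sum(ssy) == 0) return(rep(NA_real_, p))
  Wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), `/`)
  v <- sqrt(p * as.numeric(Wn^2 %*% ssy) / sum(ssy))
  setNames(v, model$predictor_names)
}

#' Recursive weighted PLS frequency selection (R-PLS)
#'
#' Iteratively refits PLS on column-reweighted predictors: after each
#' fit every column's cumulative weight is multiplied by
#' `|beta| / max|beta|`, and columns whose cumulative weight falls below
#' `tol` times the maximum are dropped from the support. Iteration stops
#' when the support stabilises (or `max_iter`); the final model is a PLS
#' fit on the surviving columns of the unweighted predictors.
#'
#' @inheritParams fit_pls
#' @param n_factors Factors per fit (default 2).
#' @param max_iter Iteration cap (default 50).
#' @param tol Survival tolerance relative to the maximum cumulative
#'   weight (default 1e-3).
#' @return Object of class `rpls_result`: `selected` (column indices),
#'   `selected_frequencies` (names when available), `iterations`,
#'   `final_model`, `weight_history`.
#' @export
rpls_select <- function(X, y, n_factors = 2, max_iter = 50, tol = 1e-3) {
  X <- as.matrix(X)
  p <- ncol(X)
  w_cum <- rep(1, p)
  support <- seq_len(p)
  history <- list()
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    Xw <- sweep(X, 2, w_cum, `*`)
    nf <- min(n_factors, length(support), qr(Xw)$rank)
    if (nf < 1) break
    fit <- fit_pls(Xw, y, nf)
    b <- abs(fit$beta)
    if (max(b) == 0) break
    w_cum <- w_cum * b / max(b)
    history[[it]] <- w_cum
    new_support <- which(w_cum > tol * max(w_cum))
    if (identical(new_support, support)) break
    support <- new_support
  }
  final <- fit_pls(X[, support, drop = FALSE], y,
                   max(1, min(n_factors, length(support), nrow(X) - 2,
                              qr(X[, support, drop = FALSE])$rank)))
  structure(list(selected = support,
                 selected_frequencies = colnames(X)[support],
                 iterations = iterations, final_model = final,
                 weight_history = history),
            class = "rpls_result")
}

# ---- PARAFAC --------------------------------------------------------------

.unfold <- function(A, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(A, perm), nrow = d[mode])
}

.khatri_rao <- function(B, C) {
  # columnwise Kronecker product, F columns
  out <- matrix(0, nrow(B) * nrow(C), ncol(B))
  for (f in seq_len(ncol(B))) out[, f] <- kronecker(B[, f], C[, f])
  out
}

# multiply t(M) into `arr` along `mode`
.ttm <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- c(mode, setdiff(1:3, mode))
  mat <- matrix(aperm(arr, perm), nrow = d[mode])
  res <- crossprod(M, mat)
  aperm(array(res, c(ncol(M), d[setdiff(1:3, mode)])), order(perm))
}

#' PARAFAC decomposition by alternating least squares
#'
#' Trilinear decomposition of a three-mode array from random starts;
#' the replicate with the lowest sum of squared errors is kept. Mode-2
#' and mode-3 loadings are normalised to unit length with magnitudes
#' absorbed into mode 1. The core consistency diagnostic (CORCONDIA) is
#' `100 * (1 - sum((g - t)^2) / sum(t^2))` where `g` is the least-squares
#' Tucker core given the PARAFAC loadings and `t` the superdiagonal
#' identity core; values near 100 indicate an appropriate factor count.
#'
#' @param tensor Three-dimensional numeric array
#'   (participants x channels x frequencies).
#' @param n_factors Number of factors.
#' @param n_replications Random restarts (default 25).
#' @param max_iter,tol ALS stopping rule: relative SSE change below `tol`
#'   (default 1e-8) or `max_iter` (default 2500) iterations.
#' @param seed RNG seed for the restarts.
#' @return Object of class `parafac_fit`: loadings `A`, `B`, `C`, `sse`,
#'   `corcondia`, `iterations` (of the best replicate),
#'   `best_replicate_id`, and a `replicates` diagnostic table.
#' @export
fit_parafac <- function(tensor, n_factors, n_replications = 25,
                        max_iter = 2500, tol = 1e-8, seed = NULL) {
  stopifnot(length(dim(tensor)) == 3, all(is.finite(tensor)))
  d <- dim(tensor)
  X1 <- .unfold(tensor, 1); X2 <- .unfold(tensor, 2); X3 <- .unfold(tensor, 3)
  ssx <- sum(tensor^2)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replications), function(rep_i) {
      B <- matrix(rnorm(d[2] * n_factors), d[2])
      C <- matrix(rnorm(d[3] * n_factors), d[3])
      A <- NULL
      sse_prev <- Inf; sse <- ssx; iter <- 0L
      for (iter in seq_len(max_iter)) {
        A <- X1 %*% .khatri_rao(C, B) %*%
          solve(crossprod(C) * crossprod(B) + diag(1e-12, n_factors))
        B <- X2 %*% .khatri_rao(C, A) %*%
          solve(crossprod(C) * crossprod(A) + diag(1e-12, n_factors))
        C <- X3 %*% .khatri_rao(B, A) %*%
          solve(crossprod(B) * crossprod(A) + diag(1e-12, n_factors))
        rec <- A %*% t(.khatri_rao(C, B))
        sse <- sum((X1 - rec)^2)
        if (is.finite(sse_prev) &&
            abs(sse_prev - sse) < tol * max(sse_prev, 1e-300)) break
        sse_prev <- sse
      }
      list(A = A, B = B, C = C, sse = sse, iterations = iter)
    })
  })
  sses <- vapply(reps, `[[`, 0, "sse")
  best_id <- which.min(sses)
  best <- reps[[best_id]]
  # unit-norm B and C, magnitudes into A; fix signs via max-abs elements
  A <- best$A; B <- best$B; C <- best$C
  for (f in seq_len(n_factors)) {
    nb <- sqrt(sum(B[, f]^2)); nc <- sqrt(sum(C[, f]^2))
    if (nb > 0) { A[, f] <- A[, f] * nb; B[, f] <- B[, f] / nb }
    if (nc > 0) { A[, f] <- A[, f] * nc; C[, f] <- C[, f] / nc }
    sb <- sign(B[which.max(abs(B[, f])), f])
    sc <- sign(C[which.max(abs(C[, f])), f])
    B[, f] <- B[, f] * sb; C[, f] <- C[, f] * sc
    A[, f] <- A[, f] * sb * sc
  }
  structure(list(A = A, B = B, C = C, sse = best$sse,
                 corcondia = .corcondia(tensor, A, B, C),
                 iterations = best$iterations,
                 best_replicate_id = best_id,
                 replicates = data.frame(
                   replicate = seq_len(n_replications), sse = sses,
                   iterations = vapply(reps, `[[`, 0L, "iterations"))),
            class = "parafac_fit")
}

.corcondia <- function(tensor, A, B, C) {
  F <- ncol(A)
  # least-squares Tucker core given the loadings, via the normal equations
  # (C'C ox B'B ox A'A) vec(G) = vec(tensor x1 A' x2 B' x3 C')
  G <- tryCatch({
    rhs <- .ttm(.ttm(.ttm(tensor, A, 1), B, 2), C, 3)
    K <- kronecker(crossprod(C), kronecker(crossprod(B), crossprod(A)))
    array(solve(K + diag(1e-10 * max(diag(K)), F^3), as.vector(rhs)),
          dim = c(F, F, F))
  }, error = function(e) NULL)
  if (is.null(G)) return(NA_real_)
  Tcore <- array(0, dim = c(F, F, F))
  for (f in seq_len(F)) Tcore[f, f, f] <- 1
  100 * (1 - sum((G - Tcore)^2) / sum(Tcore^2))
}

#' Scan PARAFAC factor counts
#'
#' Convenience wrapper running [fit_parafac()] for a range of factor
#' counts and collecting the rank-selection diagnostics (SSE, CORCONDIA,
#' iterations of the best replicate).
#'
#' @inheritParams fit_parafac
#' @param factors Factor counts to examine (default 1:10).
#' @return Data frame with one row per factor count.
#' @export
parafac_rank_scan <- function(tensor, factors = 1:10, n_replications = 25,
                              max_iter = 2500, tol = 1e-8, seed = NULL) {
  rows <- lapply(seq_along(factors), function(i) {
    fit <- fit_parafac(tensor, factors[i], n_replications = n_replications,
                       max_iter = max_iter, tol = tol,
                       seed = derive_seed(seed, i))
    data.frame(n_factors = factors[i], sse = fit$sse,
               corcondia = fit$corcondia, iterations = fit$iterations,
               n_replications = n_replications,
               best_replicate_id = fit$best_replicate_id)
  })
  do.call(rbind, rows)
}

#' Trilinear PLS1 (tensor regression of a scalar response)
#'
#' For each factor the channel/frequency weight pair is the dominant
#' singular pair of the response-covariance matrix
#' `Z_jk = sum_i y_i X_ijk` (on centred data); scores are
#' `t_i = sum_jk X_ijk w_j w_k`. The predictor tensor and response are
#' deflated between factors and the response is finally regressed on all
#' scores jointly.
#'
#' @param tensor Participants x channels x frequencies array.
#' @param y Response (ages), length matching the first mode.
#' @param n_factors Number of factors.
#' @return Object of class `tripls_model` with unit-norm `channel_weights`
#'   and `frequency_weights` (one column per factor), `scores`,
#'   regression coefficients `b`, in-sample `fitted`, and per-factor
#'   score-response correlations `factor_cor`.
#' @export
fit_tripls <- function(tensor, y, n_factors) {
  stopifnot(length(dim(tensor)) == 3)
  d <- dim(tensor)
  y <- as.numeric(y)
  if (d[1] != length(y)) stop("first mode must match length(y)",
                              call. = FALSE)
  if (n_factors > min(d)) stop("n_factors exceeds the smallest mode",
                               call. = FALSE)
  X1 <- .unfold(tensor, 1)
  x_center <- colMeans(X1)
  Xd <- sweep(X1, 2, x_center)
  y_center <- mean(y)
  yd <- y - y_center
  Wj <- matrix(0, d[2], n_factors)
  Wk <- matrix(0, d[3], n_factors)
  Tm <- matrix(0, d[1], n_factors)
  b <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    z <- crossprod(Xd, yd)[, 1]
    Z <- matrix(z, nrow = d[2], ncol = d[3])
    sv <- svd(Z, nu = 1, nv = 1)
    wj <- sv$u[, 1]; wk <- sv$v[, 1]
    sgn <- sign(wj[which.max(abs(wj))]); if (sgn == 0) sgn <- 1
    wj <- wj * sgn; wk <- wk * sgn
    w <- as.vector(outer(wj, wk))  # column-major: mode-2 index fastest
    t <- Xd %*% w
    Wj[, a] <- wj; Wk[, a] <- wk; Tm[, a] <- t
    ba <- lm.fit(Tm[, seq_len(a), drop = FALSE], yd)$coefficients
    yd_hat <- Tm[, seq_len(a), drop = FALSE] %*% ba
    yd_res <- (y - y_center) - yd_hat
    Xd <- Xd - t %*% t(w)
    yd <- as.numeric(yd_res)
  }
  bfin <- lm.fit(Tm, y - y_center)$coefficients
  bfin[is.na(bfin)] <- 0
  fitted <- as.numeric(Tm %*% bfin + y_center)
  sdy <- sd(y)
  factor_cor <- apply(Tm, 2, function(t)
    if (sd(t) > 0 && sdy > 0) cor(t, y) else NA_real_)
  structure(list(n_factors = n_factors, channel_weights = Wj,
                 frequency_weights = Wk, scores = Tm, b = as.numeric(bfin),
                 fitted = fitted, factor_cor = factor_cor,
                 y_center = y_center, x_center = x_center),
            class = "tripls_model")
}
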