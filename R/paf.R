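# The five peak-alpha-frequency estimators:
#   N-PAF  per-channel highest-amplitude alpha peak, averaged
#   D-PAF  highest-amplitude alpha peak of the SVD summary spectrum
#   M-PAF  alpha-Gaussian centre of the parametric spectral-model fit
#   C-PAF  SNR-weighted mean of admissible channel peaks (Welch smoothed)
#   K-PAF  centre of gravity over individually bounded alpha bands
# Estimators return an explicit missing state rather than fabricating a
# value when no admissible peak exists.

#' Method-tagged PAF estimate
#'
#' @param method One of `"N"`, `"D"`, `"M"`, `"C"`, `"K"`.
#' @param value Summary PAF in Hz, or `NA` when unavailable.
#' @param per_channel Optional named per-channel values (Hz).
#' @param channel_weights Optional per-channel weights (C-PAF SNR weights).
#' @param n_channels_used Number of channels contributing.
#' @return Object of class `paf_estimate`.
#' @export
paf_estimate <- function(method, value, per_channel = NULL,
                         channel_weights = NULL, n_channels_used = NA_integer_) {
  stopifnot(method %in% c("N", "D", "M", "C", "K"))
  structure(list(method = method, value = value, per_channel = per_channel,
                 channel_weights = channel_weights,
                 n_channels_used = n_channels_used),
            class = "paf_estimate")
}

#' @export
print.paf_estimate <- function(x, ...) {
  cat(sprintf("%s-PAF: %s Hz (%s channels)\n", x$method,
              if (is.na(x$value)) "missing" else sprintf("%.2f", x$value),
              x$n_channels_used))
  invisible(x)
}

#' Find local alpha-band peaks of a spectrum
#'
#' A peak is a grid point where the first difference of the amplitude
#' changes sign from positive to negative (flat tops are attributed to
#' their first sample); band endpoints are not peaks.
#'
#' @param values Per-frequency amplitude values.
#' @param freq Matching frequency grid.
#' @param band Search band in Hz, default `c(7, 13)`.
#' @return Data frame with `frequency` and `amplitude`, possibly empty.
#' @export
find_alpha_peaks <- function(values, freq, band = c(7, 13)) {
  stopifnot(length(values) == length(freq))
  n <- length(values)
  if (n < 3) return(data.frame(frequency = numeric(0), amplitude = numeric(0)))
  d <- diff(values)
  s <- sign(d)
  # carry the previous non-zero sign through flat runs
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  idx <- idx[freq[idx] >= band[1] & freq[idx] <= band[2]]
  idx <- idx[idx > 1 & idx < n]
  data.frame(frequency = freq[idx], amplitude = values[idx])
}

# Highest-amplitude peak; ties broken toward the lowest frequency.
.best_peak <- function(values, freq, band) {
  pk <- find_alpha_peaks(values, freq, band)
  if (nrow(pk) == 0) return(NULL)
  pk[order(-pk$amplitude, pk$frequency), ][1, ]
}

#' Naive per-channel PAF (N-PAF)
#'
#' Per channel the highest-amplitude alpha peak of the AR log2-amplitude
#' spectrum; channels without an identifiable peak are recorded as
#' missing. The summary is the unweighted mean over non-missing channels.
#'
#' @param spectra An [amplitude_spectrum()] (frequency-by-channel) or a
#'   matrix with frequencies in rows.
#' @param freq Frequency grid (taken from the object when omitted).
#' @param band Alpha band, Hz.
#' @return A [paf_estimate()] with method `"N"` and per-channel detail.
#' @export
naive_paf <- function(spectra, freq = NULL, band = c(7, 13)) {
  v <- if (inherits(spectra, "amplitude_spectrum")) spectra$values else
    as.matrix(spectra)
  freq <- freq %||% spectra$freq
  per <- apply(v, 2, function(col) {
    bp <- .best_peak(col, freq, band)
    if (is.null(bp)) NA_real_ else bp$frequency
  })
  used <- sum(!is.na(per))
  paf_estimate("N", value = if (used) mean(per, na.rm = TRUE) else NA_real_,
               per_channel = per, n_channels_used = used)
}

#' Direct SVD-summary PAF (D-PAF)
#'
#' Highest-amplitude alpha peak of the first SVD component spectrum.
#'
#' @param svd An [svd_first_component()] result (or a plain spectrum
#'   vector).
#' @param freq Frequency grid.
#' @param band Alpha band, Hz.
#' @return A [paf_estimate()] with method `"D"`.
#' @export
direct_paf <- function(svd, freq = frequency_grid(), band = c(7, 13)) {
  spec <- if (inherits(svd, "svd_summary")) svd$component_spectrum else
    as.numeric(svd)
  bp <- .best_peak(spec, freq, band)
  paf_estimate("D", value = if (is.null(bp)) NA_real_ else bp$frequency,
               n_channels_used = NA_integer_)
}

# ---- parametric spectral-model fit (M-PAF) --------------------------------

.model_bounds <- function() {
  list(lower = c(a0 = 0, m = -8, k = -30,
                 amp = rep(0, 5), mu = .band_mu_bounds[, "lo"],
                 sigma = rep(0.05, 5)),
       upper = c(a0 = 50, m = -1e-4, k = 30,
                 amp = rep(10, 5), mu = .band_mu_bounds[, "hi"],
                 sigma = .band_sigma_max))
}

.model_eval <- function(par, freq) {
  v <- par[1] * (0.1 * freq)^par[2] + par[3]
  for (i in 1:5) {
    v <- v + par[3 + i] *
      exp(-0.5 * ((freq - par[8 + i]) / par[13 + i])^2)
  }
  v
}

.model_jacobian <- function(par, freq) {
  base <- (0.1 * freq)^par[2]
  J <- matrix(0, length(freq), 18)
  J[, 1] <- base
  J[, 2] <- par[1] * base * log(0.1 * freq)
  J[, 3] <- 1
  for (i in 1:5) {
    z <- (freq - par[8 + i]) / par[13 + i]
    E <- exp(-0.5 * z^2)
    J[, 3 + i] <- E
    J[, 8 + i] <- par[3 + i] * E * z / par[13 + i]
    J[, 13 + i] <- par[3 + i] * E * z^2 / par[13 + i]
  }
  J
}

#' Fit the aperiodic-plus-Gaussians spectral model (for M-PAF)
#'
#' Bound-constrained nonlinear least squares of the 18-parameter model
#' (aperiodic `A0 (0.1 f)^m + k` plus five Gaussian band peaks) to a
#' log2-amplitude spectrum, via Levenberg-Marquardt with an analytic
#' Jacobian. One heuristic start (aperiodic-only prefit, band amplitudes
#' from its residuals) plus `n_starts` random starts within bounds; the
#' lowest-SSE solution wins.
#'
#' @param values log2-amplitude spectrum (typically the SVD summary) on
#'   `freq`.
#' @param freq Frequency grid, default [frequency_grid()].
#' @param n_starts Number of random restarts (default 10).
#' @param seed Seed for the random starts.
#' @return A [spectral_model_params()] with `adj_r2` and `sse` filled.
#' @export
fit_spectral_model <- function(values, freq = frequency_grid(),
                               n_starts = 10, seed = NULL) {
  stopifnot(length(values) == length(freq), all(is.finite(values)))
  b <- .model_bounds()
  y <- as.numeric(values)
  resid_fn <- function(par) .model_eval(par, freq) - y
  jac_fn <- function(par) .model_jacobian(par, freq)

  hs <- .heuristic_start(y, freq)
  # variants of the guided start: width rescalings and a version with the
  # weakly-supported bands switched off, to escape peak-assignment local
  # minima in the joint fit
  hs_narrow <- hs; hs_narrow[14:18] <- pmax(hs[14:18] * 0.5, 0.3)
  hs_wide <- hs; hs_wide[14:18] <- pmin(hs[14:18] * 2, .band_sigma_max - 0.1)
  hs_sparse <- hs; hs_sparse[4:8][hs[4:8] < 0.3] <- 1e-3
  starts <- list(hs, hs_narrow, hs_wide, hs_sparse)
  if (n_starts > 0) {
    rnd <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
      c(runif(1, 0.5, 8), runif(1, -2, -0.1), runif(1, min(y), max(y)),
        runif(5, 0, 3),
        runif(5, .band_mu_bounds[, "lo"],
              pmin(.band_mu_bounds[, "hi"], 45)),
        runif(5, 0.5, 5))
    }))
    starts <- c(starts, rnd)
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, b$lower + 1e-9), b$upper - 1e-9)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                           fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, nprint = 0))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$par)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (!is.finite(sse)) next
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best))
    stop("spectral model fit failed on every start", call. = FALSE)
  run_lm <- function(st) {
    st <- pmin(pmax(st, b$lower + 1e-9), b$upper - 1e-9)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                           fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, nprint = 0))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$par)) return(NULL)
    sse <- sum(resid_fn(fit$par)^2)
    if (!is.finite(sse)) return(NULL)
    list(par = fit$par, sse = sse)
  }
  # re-detection refinement: re-initialise single bands, then adjacent
  # band pairs, from their partial residuals and refit — escapes the
  # peak-assignment local minima of the joint fit
  redetect <- function(par, bands) {
    cand <- par
    cand[3 + bands] <- 0
    r <- y - .model_eval(cand, freq)
    d <- diff(r); s <- sign(d)
    for (j in seq_along(s)) if (s[j] == 0 && j > 1) s[j] <- s[j - 1]
    pk <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
    for (i in bands) {
      in_band <- pk[freq[pk] >= .band_mu_bounds[i, "lo"] &
                      freq[pk] < .band_mu_bounds[i, "hi"] & r[pk] > 0.01]
      if (length(in_band)) {
        j <- in_band[which.max(r[in_band])]
        cand[3 + i] <- min(r[j], 10)
        cand[8 + i] <- freq[j]
        r <- r - cand[3 + i] *
          exp(-0.5 * ((freq - cand[8 + i]) / cand[13 + i])^2)
      } else {
        cand[3 + i] <- 1e-3
        cand[8 + i] <- min(mean(.band_mu_bounds[i, ]), 40)
      }
    }
    cand
  }
  # structured (smooth) residuals signal a local-minimum misfit; white
  # residuals are just measurement noise and need no rescue
  misfit <- function(sol) {
    if (sol$sse < 1e-12) return(FALSE)
    r <- resid_fn(sol$par)
    cor(r[-1], r[-length(r)]) > 0.3
  }
  for (round in 1:3) {
    improved <- FALSE
    if (!misfit(best)) break
    groups <- c(as.list(1:5), list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
    for (grp in groups) {
      trial <- run_lm(redetect(best$par, grp))
      if (!is.null(trial) && trial$sse < best$sse - 1e-12) {
        best <- trial
        improved <- TRUE
        if (best$sse < 1e-12) break
      }
    }
    if (!improved) break
  }
  # last resort for merged neighbouring peaks: coarse scan of one band's
  # centre frequency with the rest of the solution held as the start
  if (misfit(best)) {
    for (i in 5:1) {
      if (best$sse < 1e-12) break
      lo <- .band_mu_bounds[i, "lo"]
      hi <- min(.band_mu_bounds[i, "hi"], max(freq) - 1)
      for (mu_try in seq(lo + 0.5, hi, by = 1.5)) {
        cand <- best$par
        cand[3 + i] <- max(cand[3 + i], 0.1)
        cand[8 + i] <- mu_try
        cand[13 + i] <- 2
        trial <- run_lm(cand)
        if (!is.null(trial) && trial$sse < best$sse - 1e-12) best <- trial
        if (best$sse < 1e-12) break
      }
    }
  }
  p <- best$par
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - best$sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - 18 - 1)
  spectral_model_params(a0 = p[1], m = p[2], k = p[3],
                        amp = p[4:8], mu = p[9:13], sigma = p[14:18],
                        adj_r2 = adj, sse = best$sse)
}

.heuristic_start <- function(y, freq) {
  # aperiodic prefit tracking the lower envelope: profile the exponent on
  # a grid, solving (A0, k) by linear least squares at each m, and refit
  # on the points at or below the curve so band peaks do not bias it
  aper_profile <- function(yy, ff) {
    best <- NULL
    for (m in seq(-3, -0.05, by = 0.05)) {
      basis <- (0.1 * ff)^m
      cf <- lm.fit(cbind(basis, 1), yy)$coefficients
      if (cf[1] < 0) next
      sse <- sum((cf[1] * basis + cf[2] - yy)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = c(cf[1], m, cf[2]), sse = sse)
    }
    best$par %||% c(1, -0.5, mean(yy))
  }
  par0 <- aper_profile(y, freq)
  for (round in 1:3) {
    fitv <- par0[1] * (0.1 * freq)^par0[2] + par0[3]
    keep <- (y - fitv) <= max(0.05, quantile(y - fitv, 0.6))
    if (sum(keep) < 20) break
    par0 <- aper_profile(y[keep], freq[keep])
  }
  r <- y - (par0[1] * (0.1 * freq)^par0[2] + par0[3])
  # assign genuine interior local maxima of the detrended residual to
  # bands; bands without a peak of their own start near zero amplitude at
  # the band centre, so they cannot latch onto a neighbour's tail
  d <- diff(r)
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  pk <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  amp0 <- rep(0.05, 5)
  mu0 <- pmin(rowMeans(.band_mu_bounds), 40)
  sg0 <- c(1.5, 1.2, 3, 3, 4)
  for (i in 1:5) {
    in_band <- pk[freq[pk] >= .band_mu_bounds[i, "lo"] &
                    freq[pk] < .band_mu_bounds[i, "hi"]]
    in_band <- in_band[r[in_band] > 0.02]
    if (length(in_band)) {
      j <- in_band[which.max(r[in_band])]
      mu0[i] <- freq[j]
      amp0[i] <- min(r[j], 10)
      # half-width at half maximum -> sigma
      half <- r[j] / 2
      lo <- j; while (lo > 1 && r[lo] > half) lo <- lo - 1
      hi <- j; while (hi < length(r) && r[hi] > half) hi <- hi + 1
      sg0[i] <- max(0.3, min((freq[hi] - freq[lo]) / 2.355,
                             .band_sigma_max[i] - 0.1))
    }
  }
  c(par0, amp0, mu0, sg0)
}

#' Model-based PAF (M-PAF)
#'
#' The centre frequency of the fitted alpha Gaussian.
#'
#' @param params A [spectral_model_params()] (typically from
#'   [fit_spectral_model()]).
#' @return A [paf_estimate()] with method `"M"`.
#' @export
modeled_paf <- function(params) {
  stopifnot(inherits(params, "spectral_model_params"))
  paf_estimate("M", value = params$bands$mu[2])
}

#' SNR-weighted channel-average PAF (C-PAF)
#'
#' Per channel, the highest alpha peak of the smoothed Welch spectrum is
#' admitted only when its log power exceeds the background predicted by a
#' linear regression of log power on log frequency (fitted over
#' `fit_band`, alpha band excluded) by at least one residual standard
#' deviation. Admitted peak frequencies are combined with SNR weights
#' `q_j = peak - predicted background`; the estimate is missing when
#' fewer than `min_channels` channels qualify.
#'
#' @param spectra List of per-channel smoothed spectra (each a list with
#'   `freq`, `power`, as from [normalize_and_smooth()]), or a
#'   frequency-by-channel matrix with `freq` supplied.
#' @param freq Frequency grid when `spectra` is a matrix.
#' @param min_channels Minimum admissible channels (default 3).
#' @param alpha_band Alpha search band, Hz.
#' @param fit_band Background-regression band, Hz.
#' @return A [paf_estimate()] with method `"C"`, per-channel peaks and
#'   SNR weights.
#' @export
corcoran_paf <- function(spectra, freq = NULL, min_channels = 3,
                         alpha_band = c(7, 13), fit_band = c(1, 40)) {
  chan <- .as_channel_list(spectra, freq)
  peaks <- weights <- setNames(rep(NA_real_, length(chan)), names(chan))
  for (ci in seq_along(chan)) {
    f <- chan[[ci]]$freq
    p <- chan[[ci]]$power
    bp <- .best_peak(p, f, alpha_band)
    if (is.null(bp)) next
    bg_idx <- f >= fit_band[1] & f <= fit_band[2] &
      !(f >= alpha_band[1] & f <= alpha_band[2]) & p > 0
    if (sum(bg_idx) < 4) next
    fit <- lm(log(p[bg_idx]) ~ log(f[bg_idx]))
    pred <- coef(fit)[1] + coef(fit)[2] * log(bp$frequency)
    if (log(bp$amplitude) > pred + sd(residuals(fit))) {
      peaks[ci] <- bp$frequency
      weights[ci] <- bp$amplitude - exp(pred)
    }
  }
  ok <- !is.na(peaks)
  if (sum(ok) < min_channels)
    return(paf_estimate("C", NA_real_, per_channel = peaks,
                        n_channels_used = sum(ok)))
  w <- weights[ok] / sum(weights[ok])
  paf_estimate("C", value = sum(w * peaks[ok]), per_channel = peaks,
               channel_weights = weights, n_channels_used = sum(ok))
}

#' Centre-of-gravity PAF (K-PAF)
#'
#' Per channel, the alpha peak of the smoothed Welch spectrum is located
#' and the individual alpha band is bounded by the nearest local minima
#' (zero-gradient points) on each side of the peak within the search
#' window; the channel PAF is the amplitude-weighted mean frequency over
#' that band. Channels without an enclosing pair of minima are missing.
#' The summary is the unweighted mean across contributing channels.
#'
#' @inheritParams corcoran_paf
#' @param search_window Window within which the individual alpha bounds
#'   are sought, Hz (default 5-15).
#' @return A [paf_estimate()] with method `"K"`.
#' @export
klimesch_paf <- function(spectra, freq = NULL, alpha_band = c(7, 13),
                         search_window = c(5, 15)) {
  chan <- .as_channel_list(spectra, freq)
  per <- setNames(rep(NA_real_, length(chan)), names(chan))
  for (ci in seq_along(chan)) {
    f <- chan[[ci]]$freq
    p <- chan[[ci]]$power
    bp <- .best_peak(p, f, alpha_band)
    if (is.null(bp)) next
    pk_i <- which.min(abs(f - bp$frequency))
    win <- which(f >= search_window[1] & f <= search_window[2])
    d <- diff(p)
    s <- sign(d)
    for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
    minima <- which(s[-length(s)] < 0 & s[-1] > 0) + 1L
    minima <- intersect(minima, win)
    lo <- minima[minima < pk_i]
    hi <- minima[minima > pk_i]
    if (length(lo) == 0 || length(hi) == 0) next
    band_i <- max(lo):min(hi)
    per[ci] <- sum(f[band_i] * p[band_i]) / sum(p[band_i])
  }
  used <- sum(!is.na(per))
  paf_estimate("K", value = if (used) mean(per, na.rm = TRUE) else NA_real_,
               per_channel = per, n_channels_used = used)
}

.as_channel_list <- function(spectra, freq) {
  if (is.list(spectra) && !is.data.frame(spectra) &&
      !inherits(spectra, "amplitude_spectrum") && is.null(dim(spectra))) {
    stopifnot(all(vapply(spectra, function(s)
      all(c("freq", "power") %in% names(s)), TRUE)))
    if (is.null(names(spectra)))
      names(spectra) <- paste0("ch", seq_along(spectra))
    return(spectra)
  }
  v <- if (inherits(spectra, "amplitude_spectrum")) spectra$values else
    as.matrix(spectra)
  freq <- freq %||% spectra$freq
  out <- lapply(seq_len(ncol(v)), function(j)
    list(freq = freq, power = v[, j]))
  names(out) <- colnames(v) %||% paste0("ch", seq_len(ncol(v)))
  out
}
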