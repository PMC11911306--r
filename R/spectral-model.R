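# The parametric log2-amplitude spectral model shared by the generator and
# the M-PAF fitter: an aperiodic power-law background plus five Gaussian
# band peaks (theta, alpha, beta1, beta2, gamma),
#
#   log2 A(f) = A0 * (0.1 f)^m + sum_i Ai * exp(-((f - mu_i)^2) / (2 s_i^2)) + k
#
# with m < 0. The frequency inside the power law is pre-scaled by 0.1 so the
# aperiodic term equals A0 at 10 Hz regardless of the exponent.

.band_names <- c("theta", "alpha", "beta1", "beta2", "gamma")
.band_mu_bounds <- cbind(lo = c(1, 7, 13, 21, 29), hi = c(7, 13, 21, 29, 47))
.band_sigma_max <- c(15, 10, 30, 30, 30)

#' Ground-truth / fitted parameters of the spectral model
#'
#' Bundles the aperiodic parameters (`a0`, `m`, `k`) and the five Gaussian
#' band triplets (amplitude, centre frequency, width) into a validated
#' object. The centre-frequency bounds per band are 1-7, 7-13, 13-21,
#' 21-29 and 29-47 Hz and the maximum widths are 15, 10, 30, 30 and 30 Hz.
#'
#' @param a0 Aperiodic scale (log2-amplitude units).
#' @param m Aperiodic exponent; must be negative.
#' @param k Constant offset (log2-amplitude units).
#' @param amp,mu,sigma Numeric length-5 vectors with the Gaussian amplitude
#'   (log2-amplitude units, in `[0, 10]`), centre (Hz) and width (Hz) of the
#'   theta, alpha, beta1, beta2 and gamma peaks.
#' @param adj_r2,sse Optional fit-quality metrics (filled by
#'   [fit_spectral_model()]).
#' @return An object of class `spectral_model_params`.
#' @export
spectral_model_params <- function(a0, m, k, amp, mu, sigma,
                                  adj_r2 = NA_real_, sse = NA_real_) {
  check_range(a0, "a0", 0)
  check_range(m, "m", hi = 0)
  if (m >= 0) stop_config("m", "must be negative")
  check_range(k, "k")
  check_range(amp, "amp", 0, 10, len = 5)
  check_range(mu, "mu", len = 5)
  check_range(sigma, "sigma", len = 5)
  bad <- which(mu < .band_mu_bounds[, "lo"] | mu > .band_mu_bounds[, "hi"])
  if (length(bad))
    stop_config("mu", sprintf("outside band bounds for %s",
                              paste(.band_names[bad], collapse = ", ")))
  if (any(sigma <= 0) || any(sigma > .band_sigma_max))
    stop_config("sigma", "must be positive and within per-band maxima")
  structure(list(a0 = a0, m = m, k = k,
                 bands = data.frame(band = .band_names, amp = amp,
                                    mu = mu, sigma = sigma),
                 adj_r2 = adj_r2, sse = sse),
            class = "spectral_model_params")
}

#' Evaluate the spectral model on a frequency grid
#'
#' @param params A [spectral_model_params()] object.
#' @param freq Frequencies in Hz (must be positive).
#' @param alpha_gain Multiplier applied to the alpha-band Gaussian amplitude
#'   (used for per-channel topographic gains); all other bands are
#'   unaffected.
#' @return Numeric vector of log2-amplitude values.
#' @export
eval_spectral_model <- function(params, freq, alpha_gain = 1) {
  stopifnot(inherits(params, "spectral_model_params"), all(freq > 0))
  amp <- params$bands$amp
  amp[2] <- amp[2] * alpha_gain
  v <- params$a0 * (0.1 * freq)^params$m + params$k
  for (i in 1:5) {
    v <- v + amp[i] *
      exp(-0.5 * ((freq - params$bands$mu[i]) / params$bands$sigma[i])^2)
  }
  v
}

#' @export
print.spectral_model_params <- function(x, ...) {
  cat(sprintf("spectral model: A0=%.3g m=%.3g k=%.3g", x$a0, x$m, x$k))
  if (is.finite(x$adj_r2)) cat(sprintf("  (adj R2 = %.4f)", x$adj_r2))
  cat("\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}
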