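# Spectral estimation: autoregressive covariance-method PSD on a fine
# fixed grid, Welch's method on the FFT grid, the log2-amplitude
# transform, restingIAF-style normalization/smoothing, and SVD channel
# summarization. All PSDs are one-sided densities in uV^2/Hz.

#' The analysis frequency grid
#'
#' Frequencies from 0.1 to 45 Hz in 0.1 Hz steps (450 values); the fixed
#' grid on which AR spectra and the spectral model are evaluated.
#'
#' @param start,stop,step Grid definition in Hz.
#' @return Numeric vector of frequencies.
#' @export
frequency_grid <- function(start = 0.1, stop = 45, step = 0.1) {
  stopifnot(start > 0, stop > start, step > 0)
  round(seq(start, stop, by = step), 10)
}

#' Amplitude-spectrum container
#'
#' @param freq Strictly increasing frequencies in Hz.
#' @param values Frequency-by-channel matrix of log2-amplitude values
#'   (finite).
#' @param source One of `"AR"`, `"Welch"`, `"Welch_smoothed"`, `"model"`,
#'   `"SVD"`.
#' @return Object of class `amplitude_spectrum`.
#' @export
amplitude_spectrum <- function(freq, values,
                               source = c("AR", "Welch", "Welch_smoothed",
                                          "model", "SVD")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (any(diff(freq) <= 0)) stop("freq must be strictly increasing",
                                 call. = FALSE)
  if (length(freq) != nrow(values))
    stop("values must have one row per frequency", call. = FALSE)
  if (!all(is.finite(values))) stop("spectrum values must be finite",
                                    call. = FALSE)
  structure(list(freq = freq, values = values, source = source),
            class = "amplitude_spectrum")
}

#' Autoregressive PSD by the covariance method
#'
#' Fits AR coefficients of the given order by non-windowed least squares
#' (the covariance method) and evaluates the one-sided power spectral
#' density on the requested grid:
#' `PSD(f) = 2 sigma^2 / (fs |1 - sum_k phi_k e^(-i 2 pi k f / fs)|^2)`.
#' Order 256 at 500 Hz spans a 512 ms lag window.
#'
#' @param x Sample series (length > 2 * order).
#' @param order AR model order (default 256).
#' @param fs Sampling rate, Hz.
#' @param freq Evaluation grid, default [frequency_grid()].
#' @return List with `freq`, `power` (strictly positive), `sigma2`,
#'   `order`.
#' @export
ar_psd_covariance <- function(x, order = 256L, fs = 500,
                              freq = frequency_grid()) {
  x <- as.numeric(x)
  if (length(x) <= 2 * order)
    stop("signal length must exceed twice the AR order", call. = FALSE)
  fit <- ar_covariance_fit_cpp(x, as.integer(order))
  denom <- ar_transfer_denominator(fit$phi, freq, fs)
  power <- 2 * fit$sigma2 / (fs * denom)
  list(freq = freq, power = power, sigma2 = fit$sigma2,
       order = as.integer(order), phi = fit$phi)
}

ar_transfer_denominator <- function(phi, freq, fs) {
  p <- length(phi)
  E <- exp(-2i * pi * outer(freq, seq_len(p)) / fs)
  Mod(1 - as.vector(E %*% phi))^2
}

#' Convert power to log2 amplitude
#'
#' Amplitude is the square root of power; the result is its base-2
#' logarithm, i.e. `0.5 * log2(power)`. This compressed scale stops the
#' large low-frequency power from dominating downstream statistics.
#'
#' @param power Strictly positive power values.
#' @return log2-amplitude values.
#' @export
power_to_log2amplitude <- function(power) {
  if (any(!is.finite(power)) || any(power <= 0))
    stop("power must be strictly positive and finite", call. = FALSE)
  0.5 * log2(power)
}

#' Welch power spectral density
#'
#' Mean of Hamming-tapered, 50%-overlapped periodograms. The default
#' 4096 ms window (2048 samples at 500 Hz) yields a bin spacing of
#' 1/4.096 s ~ 0.244 Hz. Scaled as a one-sided density so that the PSD
#' integrates to the signal variance (taper power compensated); segment
#' means are not removed, so a constant signal puts all power in the DC
#' bin.
#'
#' @param x Sample series, at least one window long.
#' @param fs Sampling rate, Hz.
#' @param window_ms Window length in milliseconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List with `freq` (0 to fs/2) and `power`.
#' @export
welch_psd <- function(x, fs = 500, window_ms = 4096, overlap = 0.5) {
  x <- as.numeric(x)
  nper <- round(window_ms / 1000 * fs)
  if (length(x) < nper)
    stop(sprintf("signal (%d) shorter than the Welch window (%d)",
                 length(x), nper), call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  hop <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = hop)
  U <- sum(w^2)
  nf <- nper %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    X <- fft(x[s:(s + nper - 1)] * w)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  power <- acc / (length(starts) * fs * U)
  power[2:(nf - 1)] <- 2 * power[2:(nf - 1)]  # one-sided
  list(freq = (seq_len(nf) - 1) * fs / nper, power = power,
       n_segments = length(starts), window = nper)
}

#' Normalize and smooth a Welch spectrum
#'
#' Divides the PSD by its mean over the analysis band (0.1-45 Hz by
#' default, following the restingIAF practice) and applies a 5th-order,
#' 11-bin Savitzky-Golay smoother (+-2.69 Hz at the 0.244 Hz Welch
#' spacing).
#'
#' @param power PSD values.
#' @param freq Matching frequencies.
#' @param band Normalization band in Hz.
#' @param sg_order,sg_window Smoothing filter settings.
#' @return List with `freq` and normalized, smoothed `power`, restricted
#'   to the analysis band.
#' @export
normalize_and_smooth <- function(power, freq, band = c(0.1, 45),
                                 sg_order = 5L, sg_window = 11L) {
  stopifnot(length(power) == length(freq))
  keep <- freq >= band[1] & freq <= band[2]
  if (sum(keep) < sg_window)
    stop("need at least sg_window bins inside the band", call. = FALSE)
  p <- power[keep] / mean(power[keep])
  sm <- as.numeric(signal::sgolayfilt(p, p = sg_order, n = sg_window))
  list(freq = freq[keep], power = sm)
}

#' First SVD component of a channel-by-frequency matrix
#'
#' Singular value decomposition of the multichannel log2-amplitude
#' spectra; the leading right singular vector, scaled by its singular
#' value, is a common-variance-weighted summary spectrum. The sign is
#' fixed so the mean channel loading is positive.
#'
#' @param spectra Channels-by-frequencies numeric matrix (>= 2 channels).
#' @return Object of class `svd_summary` with `component_spectrum`
#'   (`sigma1 * v1`), unit-norm `channel_weights`, and
#'   `variance_fraction = sigma1^2 / sum(sigma_j^2)`.
#' @export
svd_first_component <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 channels", call. = FALSE)
  if (!all(is.finite(spectra))) stop("spectra must be finite", call. = FALSE)
  s <- svd(spectra)
  if (s$d[1] <= 0) stop("rank-0 input", call. = FALSE)
  sgn <- if (mean(s$u[, 1]) < 0) -1 else 1
  structure(list(component_spectrum = sgn * s$d[1] * s$v[, 1],
                 channel_weights = setNames(sgn * s$u[, 1],
                                            rownames(spectra)),
                 variance_fraction = s$d[1]^2 / sum(s$d^2),
                 singular_values = s$d),
            class = "svd_summary")
}

#' Per-channel AR log2-amplitude spectra of a cleaned segment
#'
#' Convenience wrapper: [ar_psd_covariance()] then
#' [power_to_log2amplitude()] for every row of a channels-by-samples
#' segment.
#'
#' @param segment Channels-by-samples matrix.
#' @param fs Sampling rate, Hz.
#' @param order AR model order.
#' @param freq Evaluation grid.
#' @return An [amplitude_spectrum()] (frequency by channel, source
#'   `"AR"`).
#' @export
channel_log2_spectra <- function(segment, fs, order = 256L,
                                 freq = frequency_grid()) {
  vals <- vapply(seq_len(nrow(segment)), function(ci)
    power_to_log2amplitude(
      ar_psd_covariance(segment[ci, ], order = order, fs = fs,
                        freq = freq)$power),
    numeric(length(freq)))
  colnames(vals) <- rownames(segment)
  amplitude_spectrum(freq, vals, source = "AR")
}
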