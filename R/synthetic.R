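# Synthetic cohort generator: demographics, ground-truth spectral
# parameters, per-channel amplitude spectra and raw multichannel EEG with
# planted slow drift and transient high-amplitude artifacts. Every
# downstream stage of the package can be exercised on its output.

#' Default synthetic montage
#'
#' A 19-channel 10-20 scalp layout with a posterior-dominant alpha gain:
#' the multiplier applied to the alpha Gaussian grows linearly from frontal
#' (0.5) to occipital (1.2) rows, mimicking the usual eyes-closed occipital
#' alpha maximum.
#'
#' @return A data frame with columns `label` and `alpha_gain`.
#' @export
default_montage <- function() {
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T7", "C3", "Cz", "C4", "T8",
              "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  row <- c(1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 4, 4, 4, 4, 4, 5, 5)
  data.frame(label = labels,
             alpha_gain = 0.5 + 0.7 * (row - 1) / 4)
}

#' Specify a synthetic cohort
#'
#' Collects every knob of the generator into a validated specification.
#' The default alpha-peak age trend is centre = 10.8 - 0.025 * age (Hz),
#' i.e. a 0.25 Hz slowing per decade, with Gaussian residual scatter.
#'
#' @param n_participants Cohort size (>= 2).
#' @param age_design `"stratified_by_decade"` (equal numbers per decade bin
#'   of `age_range`) or `"uniform"`.
#' @param age_range Two ages in years, default 20-78.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   bit for bit.
#' @param paf_slope,paf_intercept,paf_residual_sd Linear age trend of the
#'   true alpha centre frequency (Hz/year, Hz, Hz). Centres are clipped to
#'   `[7.2, 11.8]`.
#' @param band_param_distributions Named list (theta/alpha/beta1/beta2/
#'   gamma), each a list with two-element ranges `amp`, `mu`, `sigma`.
#'   The alpha `mu` range doubles as the clipping interval for the age
#'   trend. All `mu` ranges must sit inside the model's band bounds.
#' @param aperiodic_distribution List with ranges `a0`, `m`, `k`.
#' @param montage Data frame with `label` and `alpha_gain` columns.
#' @param artifact_rate Transient artifact events per minute.
#' @param drift_amplitude Standard deviation of the slow DC drift in uV.
#' @param recording_seconds Length of synthesized recordings.
#' @param target_rms RMS amplitude (uV) the spectrally-shaped EEG is scaled
#'   to (common factor across channels, so topographic relations survive).
#' @param qmci_model,nart_model,gds_model Linear-Gaussian demographic
#'   models: `list(intercept, slope, sd)` generating QMCI points and NART
#'   error counts from age, and `list(lambda)` for the Poisson GDS score.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 60,
                        age_design = c("stratified_by_decade", "uniform"),
                        age_range = c(20, 78),
                        seed = 1L,
                        paf_slope = -0.025,
                        paf_intercept = 10.8,
                        paf_residual_sd = 0.9,
                        band_param_distributions = default_band_distributions(),
                        aperiodic_distribution = list(a0 = c(3.5, 4.5),
                                                      m = c(-0.35, -0.18),
                                                      k = c(-2.5, -1.5)),
                        montage = default_montage(),
                        artifact_rate = 2,
                        drift_amplitude = 40,
                        recording_seconds = 240,
                        target_rms = 20,
                        qmci_model = list(intercept = 80, slope = -0.05, sd = 7),
                        nart_model = list(intercept = 22, slope = -0.17, sd = 5),
                        gds_model = list(lambda = 2)) {
  age_design <- match.arg(age_design)
  if (!is.numeric(n_participants) || n_participants < 2)
    stop_config("n_participants", "must be at least 2")
  check_range(age_range, "age_range", 0, 120, len = 2)
  if (diff(age_range) <= 0) stop_config("age_range", "must be increasing")
  check_range(paf_slope, "paf_slope")
  check_range(paf_intercept, "paf_intercept", 0)
  check_range(paf_residual_sd, "paf_residual_sd", 0)
  bd <- band_param_distributions
  if (!identical(names(bd), .band_names))
    stop_config("band_param_distributions",
                "must be a named list for theta, alpha, beta1, beta2, gamma")
  for (i in seq_along(bd)) {
    b <- bd[[i]]
    for (fld in c("amp", "mu", "sigma"))
      check_range(b[[fld]],
                  paste0("band_param_distributions$", .band_names[i], "$", fld),
                  len = 2)
    if (b$mu[1] < .band_mu_bounds[i, "lo"] || b$mu[2] > .band_mu_bounds[i, "hi"])
      stop_config(paste0("band_param_distributions$", .band_names[i], "$mu"),
                  "range must be nested in the model's band bounds")
    if (b$sigma[1] <= 0 || b$sigma[2] > .band_sigma_max[i])
      stop_config(paste0("band_param_distributions$", .band_names[i], "$sigma"),
                  "range must be positive and within the band's maximum width")
  }
  for (fld in c("a0", "m", "k"))
    check_range(aperiodic_distribution[[fld]],
                paste0("aperiodic_distribution$", fld), len = 2)
  if (aperiodic_distribution$m[2] >= 0)
    stop_config("aperiodic_distribution$m", "must be negative")
  if (!is.data.frame(montage) ||
      !all(c("label", "alpha_gain") %in% names(montage)) ||
      anyDuplicated(montage$label))
    stop_config("montage", "must be a data frame with unique labels and alpha_gain")
  check_range(artifact_rate, "artifact_rate", 0)
  check_range(drift_amplitude, "drift_amplitude", 0)
  check_range(recording_seconds, "recording_seconds", 10)
  check_range(target_rms, "target_rms", 0.1)
  structure(list(n_participants = as.integer(n_participants),
                 age_design = age_design, age_range = age_range,
                 seed = as.integer(seed),
                 paf_slope = paf_slope, paf_intercept = paf_intercept,
                 paf_residual_sd = paf_residual_sd,
                 band_param_distributions = bd,
                 aperiodic_distribution = aperiodic_distribution,
                 montage = montage,
                 artifact_rate = artifact_rate,
                 drift_amplitude = drift_amplitude,
                 recording_seconds = recording_seconds,
                 target_rms = target_rms,
                 qmci_model = qmci_model, nart_model = nart_model,
                 gds_model = gds_model),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_band_distributions <- function() {
  list(theta = list(amp = c(0, 0.5), mu = c(3, 6), sigma = c(1, 3)),
       alpha = list(amp = c(1, 3), mu = c(7.2, 11.8), sigma = c(0.8, 1.5)),
       beta1 = list(amp = c(0, 0.5), mu = c(15, 19), sigma = c(2, 5)),
       beta2 = list(amp = c(0, 0.5), mu = c(22, 28), sigma = c(3, 6)),
       gamma = list(amp = c(0, 0.3), mu = c(31, 43), sigma = c(3, 8)))
}

#' Generate a synthetic cohort
#'
#' Draws ages according to the design, plants the alpha-centre age trend
#' (`paf_intercept + paf_slope * age` plus Gaussian residual, clipped to
#' the alpha `mu` range), draws the remaining spectral parameters uniformly
#' from their configured ranges, and generates demographics (NART errors
#' and derived NART-IQ, QMCI, GDS-15) from the linear-Gaussian models.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `participants`
#'   (list of `synthetic_participant`) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_participants
    ages <- draw_ages(n, spec$age_design, spec$age_range)
    bd <- spec$band_param_distributions
    ap <- spec$aperiodic_distribution
    alpha_clip <- bd$alpha$mu
    participants <- vector("list", n)
    for (i in seq_len(n)) {
      age <- ages[i]
      mu <- vapply(bd, function(b) runif(1, b$mu[1], b$mu[2]), 0)
      amp <- vapply(bd, function(b) runif(1, b$amp[1], b$amp[2]), 0)
      sigma <- vapply(bd, function(b) runif(1, b$sigma[1], b$sigma[2]), 0)
      centre <- spec$paf_intercept + spec$paf_slope * age +
        rnorm(1, 0, spec$paf_residual_sd)
      mu[2] <- min(max(centre, alpha_clip[1]), alpha_clip[2])
      params <- spectral_model_params(a0 = runif(1, ap$a0[1], ap$a0[2]),
                                      m = runif(1, ap$m[1], ap$m[2]),
                                      k = runif(1, ap$k[1], ap$k[2]),
                                      amp = unname(amp), mu = unname(mu),
                                      sigma = unname(sigma))
      nart_errors <- max(0, round(spec$nart_model$intercept +
                                    spec$nart_model$slope * age +
                                    rnorm(1, 0, spec$nart_model$sd)))
      qmci <- min(100, max(0, spec$qmci_model$intercept +
                             spec$qmci_model$slope * age +
                             rnorm(1, 0, spec$qmci_model$sd)))
      gds <- min(15, rpois(1, spec$gds_model$lambda))
      participants[[i]] <- structure(
        list(participant_id = sprintf("P%03d", i),
             age = age,
             true_params = params,
             channel_gains = setNames(spec$montage$alpha_gain,
                                      spec$montage$label),
             nart_errors = nart_errors,
             nart_iq = nart_to_iq(nart_errors),
             qmci = qmci, gds = gds),
        class = "synthetic_participant")
    }
    structure(list(participants = participants, spec = spec),
              class = "synthetic_cohort")
  })
}

draw_ages <- function(n, design, range) {
  if (design == "uniform") return(round(runif(n, range[1], range[2])))
  decades <- seq(floor(range[1] / 10) * 10, range[2], by = 10)
  n_bins <- length(decades)
  per <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  ages <- unlist(lapply(seq_along(decades), function(d) {
    lo <- max(decades[d], range[1])
    hi <- min(decades[d] + 9, range[2])
    sample(lo:hi, per[d], replace = TRUE)
  }))
  as.numeric(ages)
}

#' Cohort summary table
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with one row per participant (id, age, NART errors,
#'   NART-IQ, QMCI, GDS, true alpha centre).
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  do.call(rbind, lapply(cohort$participants, function(p) {
    data.frame(participant_id = p$participant_id, age = p$age,
               nart_errors = p$nart_errors, nart_iq = p$nart_iq,
               qmci = p$qmci, gds = p$gds,
               true_alpha_mu = p$true_params$bands$mu[2])
  }))
}

#' Convert NART error count to NART-IQ
#'
#' Premorbid-intelligence conversion from National Adult Reading Test
#' errors: `IQ = 126.41 - 0.9775 * errors`.
#'
#' @param errors Non-negative error count(s).
#' @return IQ points.
#' @export
nart_to_iq <- function(errors) {
  if (!is.numeric(errors) || anyNA(errors) || any(errors < 0))
    stop("NART error count must be non-negative", call. = FALSE)
  126.41 - 0.9775 * errors
}

#' Synthesize a single-channel amplitude spectrum
#'
#' Evaluates the participant's ground-truth spectral model on the grid,
#' applies the channel's alpha gain, and adds optional Gaussian noise on
#' the log2-amplitude scale.
#'
#' @param participant A `synthetic_participant`.
#' @param channel Channel label (must belong to the participant's montage).
#' @param freq Frequency grid in Hz, default [frequency_grid()].
#' @param noise_sd Noise standard deviation (log2-amplitude units).
#' @param seed Optional seed for the noise draw.
#' @return An [amplitude_spectrum()] with a single channel.
#' @export
synthesize_spectrum <- function(participant, channel,
                                freq = frequency_grid(), noise_sd = 0,
                                seed = NULL) {
  stopifnot(inherits(participant, "synthetic_participant"))
  if (!channel %in% names(participant$channel_gains))
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  g <- participant$channel_gains[[channel]]
  v <- eval_spectral_model(participant$true_params, freq, alpha_gain = g)
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(freq), 0, noise_sd))
  amplitude_spectrum(freq, matrix(v, ncol = 1,
                                  dimnames = list(NULL, channel)),
                     source = "model")
}

#' Synthesize a raw multichannel EEG recording
#'
#' Per channel, the participant's model spectrum is realised in the time
#' domain by inverse-FFT spectral shaping with random phases (frequencies
#' 0.25-45 Hz; the region below is left to the drift term). One common
#' scale factor brings the cohort-average channel RMS to `target_rms`, so
#' relative channel amplitudes are preserved. A slow Gaussian-smoothed
#' random-walk drift (`drift_amplitude` uV SD, ~20 s timescale) and
#' Poisson-placed half-sine artifact pulses of 150-500 uV (100-300 ms,
#' applied across all channels, random sign) are then added; planted pulse
#' intervals are returned in the `artifact_log`.
#'
#' @param participant A `synthetic_participant`.
#' @param duration_s Recording length in seconds (>= 10).
#' @param fs Sampling rate, Hz.
#' @param drift_amplitude,artifact_rate,target_rms See [cohort_spec()].
#' @param seed Seed controlling phases, drift and artifact placement.
#' @return A [raw_eeg()] with an `artifact_log` attribute-like element:
#'   a data frame of planted intervals (`start`, `end` in samples,
#'   half-open, plus `amplitude` in uV).
#' @export
synthesize_timeseries <- function(participant, duration_s = 240, fs = 500,
                                  drift_amplitude = 40, artifact_rate = 2,
                                  target_rms = 20, seed = NULL) {
  stopifnot(inherits(participant, "synthetic_participant"))
  if (duration_s < 10) stop("duration_s must be at least 10", call. = FALSE)
  with_seed(seed, {
    n <- round(duration_s * fs)
    labels <- names(participant$channel_gains)
    nch <- length(labels)
    fft_freq <- (seq_len(n %/% 2)) * fs / n  # positive frequencies
    keep <- fft_freq >= 0.25 & fft_freq <= 45
    grid <- frequency_grid()
    data <- matrix(0, nrow = nch, ncol = n, dimnames = list(labels, NULL))
    for (ci in seq_len(nch)) {
      logamp <- eval_spectral_model(participant$true_params, grid,
                                    alpha_gain = participant$channel_gains[[ci]])
      amp <- numeric(length(fft_freq))
      amp[keep] <- 2^stats::approx(grid, logamp, xout = fft_freq[keep],
                                   rule = 2)$y
      # broadband measurement-noise floor (half the 45 Hz amplitude, i.e.
      # a quarter of its power): real amplifiers are not band-limited, and
      # without any out-of-band energy the record would be perfectly
      # linearly predictable, which degenerates AR estimation
      floor_amp <- 0.5 * 2^logamp[length(logamp)]
      amp <- sqrt(amp^2 + floor_amp^2)
      phases <- runif(length(fft_freq), 0, 2 * pi)
      spec <- complex(modulus = amp, argument = phases)
      full <- complex(real = numeric(n))
      full[2:(length(fft_freq) + 1)] <- spec
      idx_conj <- n:(n - length(fft_freq) + 2)
      full[idx_conj] <- Conj(spec[seq_len(length(idx_conj))])
      if (n %% 2 == 0) full[n / 2 + 1] <- abs(full[n / 2 + 1])
      data[ci, ] <- Re(fft(full, inverse = TRUE)) / n
    }
    scale <- target_rms / sqrt(mean(apply(data, 1, var)))
    data <- data * scale

    if (drift_amplitude > 0) {
      # drift lives on a tens-of-seconds timescale, so it is generated on
      # a decimated 2 Hz grid and interpolated back to the sampling rate
      fs_d <- 2
      nd <- ceiling(duration_s * fs_d) + 2L
      for (ci in seq_len(nch)) {
        walk <- cumsum(rnorm(nd))
        drift_d <- gaussian_smooth(walk, sd_samples = 10 * fs_d)
        s <- sd(drift_d)
        if (s > 0) {
          drift <- stats::approx(seq(0, by = 1 / fs_d, length.out = nd),
                                 drift_d * (drift_amplitude / s),
                                 xout = (seq_len(n) - 1) / fs)$y
          data[ci, ] <- data[ci, ] + drift
        }
      }
    }

    n_events <- if (artifact_rate > 0) rpois(1, artifact_rate * duration_s / 60)
                else 0L
    log <- data.frame(start = integer(0), end = integer(0),
                      amplitude = numeric(0), channels = character(0))
    if (n_events > 0) {
      for (e in seq_len(n_events)) {
        len <- round(runif(1, 0.1, 0.3) * fs)
        start <- sample.int(n - len, 1)
        ampl <- runif(1, 150, 500) * sample(c(-1, 1), 1)
        # most transients are local (1-3 electrodes); a minority are
        # movement-like events across the whole montage
        hit <- if (runif(1) < 0.05) seq_len(nch) else
          sample.int(nch, sample(1:3, 1))
        pulse <- ampl * sin(pi * seq_len(len) / (len + 1))
        idx <- start:(start + len - 1)
        data[hit, idx] <- sweep(data[hit, idx, drop = FALSE], 2, pulse, "+")
        log <- rbind(log, data.frame(
          start = start, end = start + len, amplitude = ampl,
          channels = paste(labels[hit], collapse = ",")))
      }
    }
    eeg <- raw_eeg(data, fs = fs, labels = labels)
    eeg$artifact_log <- log
    eeg
  })
}

# zero-phase Gaussian kernel smoothing via FFT convolution
gaussian_smooth <- function(x, sd_samples) {
  n <- length(x)
  half <- min(4L * ceiling(sd_samples), n - 1L)
  kern <- exp(-0.5 * ((-half):half / sd_samples)^2)
  kern <- kern / sum(kern)
  full <- fast_convolve_open(x, kern)
  full[(half + 1):(half + n)]
}
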