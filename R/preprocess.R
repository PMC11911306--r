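# Cleaning of DC-EEG recordings: per-channel demeaning, artifact flagging
# against a time-varying Savitzky-Golay baseline, greedy channel exclusion,
# extraction of the largest contiguous clean segment, and common-average
# re-referencing. The fixed stage order is
#   demean -> baseline -> flag -> channel exclusion -> crop -> re-reference;
# flagging never alters sample values, selection only crops.

#' Raw multichannel EEG container
#'
#' @param data Channels-by-samples numeric matrix in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (unique, one per row).
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (anyNA(data)) stop("EEG data must not contain missing samples",
                        call. = FALSE)
  if (length(labels) != nrow(data) || anyDuplicated(labels))
    stop("labels must be unique and match the number of channels",
         call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels), class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("raw_eeg: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# Least-squares polynomial smoothing weights. Returns the weight vector w
# such that the order-`order` polynomial fitted to x[idx] and evaluated at
# position `at` equals sum(w * x[idx]). Positions are scaled to [-1, 1]
# for conditioning.
.polyfit_weights <- function(idx, at, order) {
  u <- (idx - mean(idx)) / max(1, diff(range(idx)) / 2)
  P <- outer(u, 0:order, `^`)
  u0 <- (at - mean(idx)) / max(1, diff(range(idx)) / 2)
  p0 <- u0^(0:order)
  as.vector(p0 %*% solve(crossprod(P), t(P)))
}

# Cached central + edge Savitzky-Golay weights for a window/order pair.
.sg_weights <- function(window, order) {
  key <- sprintf("sg_%d_%d", window, order)
  if (!is.null(.eegage_cache[[key]])) return(.eegage_cache[[key]])
  half <- (window - 1L) %/% 2L
  central <- .polyfit_weights(seq_len(window), half + 1L, order)
  # truncated-window fits for the left edge; right edge uses the mirror
  edge <- lapply(seq_len(half), function(t)
    .polyfit_weights(seq_len(t + half), t, order))
  out <- list(central = central, edge = edge, half = half)
  .eegage_cache[[key]] <- out
  out
}

#' Savitzky-Golay baseline of a signal
#'
#' Least-squares polynomial smoothing with the stated window and order.
#' The default window of 1025 samples spans +-2.048 s at 500 Hz, slow
#' enough to track DC drift without following EEG rhythms. At the record
#' boundaries the polynomial is fitted on the truncated window (all
#' available samples within the half-window) rather than on padded data,
#' to avoid fabricated extremes.
#'
#' @param x Numeric sample series, at least `window` long.
#' @param window Odd window length in samples.
#' @param order Polynomial order.
#' @return Baseline series, same length as `x`.
#' @export
savgol_baseline <- function(x, window = 1025L, order = 3L) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (n < window)
    stop(sprintf("signal too short (%d) for window %d", n, window),
         call. = FALSE)
  w <- .sg_weights(as.integer(window), as.integer(order))
  half <- w$half
  # interior by FFT convolution with the symmetric central weights
  conv <- fast_convolve_open(x, rev(w$central))
  out <- numeric(n)
  out[(half + 1):(n - half)] <- conv[(window):(n)]
  for (t in seq_len(half)) {
    out[t] <- sum(w$edge[[t]] * x[seq_len(t + half)])
    out[n + 1 - t] <- sum(w$edge[[t]] * x[n + 1 - seq_len(t + half)])
  }
  out
}

#' Flag artifact samples against the Savitzky-Golay baseline
#'
#' Each channel is demeaned, its baseline computed with
#' [savgol_baseline()], and a sample flagged when the absolute deviation
#' from the baseline exceeds `threshold` microvolts. Flagging is applied
#' before re-referencing and is non-destructive.
#'
#' @param raw A [raw_eeg()].
#' @param threshold Deviation threshold in uV (default 120).
#' @param window,order Baseline filter settings.
#' @return Logical channels-by-samples matrix (`TRUE` = artifact).
#' @export
flag_artifacts <- function(raw, threshold = 120, window = 1025L, order = 3L) {
  stopifnot(inherits(raw, "raw_eeg"))
  mask <- matrix(FALSE, nrow = nrow(raw$data), ncol = ncol(raw$data),
                 dimnames = list(raw$labels, NULL))
  for (ci in seq_len(nrow(raw$data))) {
    x <- raw$data[ci, ] - mean(raw$data[ci, ])
    mask[ci, ] <- abs(x - savgol_baseline(x, window, order)) > threshold
  }
  mask
}

#' Largest contiguous segment clean on all retained channels
#'
#' A sample counts as clean only when it is unflagged on every retained
#' channel, so the returned run is usable as a common multichannel
#' segment. Ties are broken by the earliest start.
#'
#' @param mask Logical channels-by-samples matrix from [flag_artifacts()].
#' @param retained Labels (or row indices) of the channels to require
#'   clean; defaults to all.
#' @return List with `start`, `end` (1-based, inclusive) and `length`;
#'   `length = 0` with `NA` bounds when no clean sample exists.
#' @export
largest_clean_segment <- function(mask, retained = rownames(mask)) {
  stopifnot(is.matrix(mask), ncol(mask) >= 1)
  if (is.null(retained)) retained <- seq_len(nrow(mask))
  sub <- mask[retained, , drop = FALSE]
  clean <- colSums(sub) == 0
  if (!any(clean)) return(list(start = NA_integer_, end = NA_integer_,
                               length = 0L))
  r <- rle(clean)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the earliest tie
  list(start = starts[best], end = ends[best],
       length = r$lengths[best])
}

#' Greedy channel exclusion to reach a target clean duration
#'
#' While the best common clean segment is shorter than `target_seconds`,
#' drops the channel whose removal lengthens the segment the most,
#' stopping at the target, at `max_drop` exclusions, or when no single
#' drop helps.
#'
#' @param raw A [raw_eeg()] (used for `fs` and labels).
#' @param mask Optional precomputed artifact mask; computed from `raw`
#'   with the default threshold when missing.
#' @param target_seconds Target clean duration (default 100 s).
#' @param max_drop Maximum number of channels to drop (default 16).
#' @param threshold Flagging threshold passed to [flag_artifacts()].
#' @return List with `dropped_channels`, `interval` (as in
#'   [largest_clean_segment()]), `retained` labels and `reached` flag.
#'   A warning is raised when the target is unreachable.
#' @export
exclude_channels_for_target <- function(raw, mask = NULL,
                                        target_seconds = 100,
                                        max_drop = 16, threshold = 120) {
  stopifnot(inherits(raw, "raw_eeg"), target_seconds > 0)
  if (is.null(mask)) mask <- flag_artifacts(raw, threshold)
  target <- target_seconds * raw$fs
  retained <- raw$labels
  dropped <- character(0)
  best <- largest_clean_segment(mask, retained)
  repeat {
    if (best$length >= target) break
    if (length(dropped) >= max_drop || length(retained) <= 2) {
      warning(sprintf(
        "target duration %.0f s unreachable; best segment %.1f s",
        target_seconds, best$length / raw$fs), call. = FALSE)
      break
    }
    cand <- lapply(retained, function(ch)
      largest_clean_segment(mask, setdiff(retained, ch)))
    lens <- vapply(cand, `[[`, 0L, "length")
    if (max(lens) <= best$length) {
      warning(sprintf(
        "target duration %.0f s unreachable; best segment %.1f s",
        target_seconds, best$length / raw$fs), call. = FALSE)
      break
    }
    j <- which.max(lens)
    dropped <- c(dropped, retained[j])
    retained <- setdiff(retained, retained[j])
    best <- cand[[j]]
  }
  list(dropped_channels = dropped, interval = best, retained = retained,
       reached = best$length >= target)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel.
#'
#' @param segment Channels-by-samples matrix with at least two channels.
#' @return Re-referenced matrix.
#' @export
common_average_reference <- function(segment) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 2)
    stop("common-average reference requires at least 2 channels",
         call. = FALSE)
  sweep(segment, 2, colMeans(segment), `-`)
}

#' Clean a raw EEG recording
#'
#' Runs the full preparation chain: per-channel demeaning, artifact
#' flagging against the Savitzky-Golay baseline, greedy channel exclusion
#' towards the target duration, cropping to the largest common clean
#' segment, and common-average re-referencing (applied after cropping so
#' excluded channels cannot contaminate the average).
#'
#' @inheritParams exclude_channels_for_target
#' @return An object of class `clean_result`: `segment` (cleaned,
#'   re-referenced matrix), `interval`, `artifact_mask`,
#'   `dropped_channels`, retained `labels`, and `fs`.
#' @export
clean_eeg <- function(raw, threshold = 120, target_seconds = 100,
                      max_drop = 16) {
  stopifnot(inherits(raw, "raw_eeg"))
  demeaned <- raw$data - rowMeans(raw$data)
  mask <- flag_artifacts(raw, threshold)
  excl <- exclude_channels_for_target(raw, mask = mask,
                                      target_seconds = target_seconds,
                                      max_drop = max_drop)
  iv <- excl$interval
  if (iv$length == 0)
    stop("no artifact-free sample on the retained channels", call. = FALSE)
  seg <- demeaned[excl$retained, iv$start:iv$end, drop = FALSE]
  if (nrow(seg) >= 2) seg <- common_average_reference(seg)
  structure(list(segment = seg, interval = iv, artifact_mask = mask,
                 dropped_channels = excl$dropped_channels,
                 labels = excl$retained, fs = raw$fs,
                 reached_target = excl$reached),
            class = "clean_result")
}

#' @export
print.clean_result <- function(x, ...) {
  cat(sprintf(
    "clean_result: %d channels, samples %d-%d (%.1f s), %d dropped\n",
    nrow(x$segment), x$interval$start, x$interval$end,
    x$interval$length / x$fs, length(x$dropped_channels)))
  invisible(x)
}
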