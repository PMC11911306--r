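# Shared fixture builders: everything is generated in code at test time.

tiny_montage <- function() {
  data.frame(label = c("F3", "Cz", "Pz", "O1"),
             alpha_gain = c(0.6, 0.85, 1.05, 1.2))
}

tiny_spec <- function(n_participants = 6, recording_seconds = 30, ...) {
  cohort_spec(n_participants = n_participants, montage = tiny_montage(),
              recording_seconds = recording_seconds, ...)
}

# A participant with hand-picked ground-truth spectral parameters.
make_participant <- function(mu = c(4, 10, 16, 25, 35),
                             amp = c(0.3, 2, 0.3, 0.2, 0.1),
                             sigma = c(1.5, 1.1, 3, 3, 4),
                             a0 = 4, m = -0.25, k = -2,
                             gains = c(F3 = 0.6, Cz = 0.85, Pz = 1.05,
                                       O1 = 1.2),
                             age = 50) {
  structure(list(participant_id = "T001", age = age,
                 true_params = spectral_model_params(
                   a0 = a0, m = m, k = k, amp = amp, mu = mu, sigma = sigma),
                 channel_gains = gains,
                 nart_errors = 10, nart_iq = nart_to_iq(10),
                 qmci = 80, gds = 1),
            class = "synthetic_participant")
}

# Direct (quadratic-cost) sliding least-squares polynomial fit: the
# independent oracle for the Savitzky-Golay baseline.
oracle_savgol <- function(x, t, window, order) {
  half <- (window - 1) %/% 2
  idx <- max(1, t - half):min(length(x), t + half)
  fit <- lm(x[idx] ~ poly(idx, order, raw = TRUE))
  unname(predict(fit, newdata = data.frame(idx = t)))
}

# Brute-force longest clean run over all intervals.
oracle_longest_run <- function(clean) {
  best_len <- 0L; best_start <- NA_integer_
  n <- length(clean)
  for (s in seq_len(n)) {
    if (!clean[s]) next
    e <- s
    while (e < n && clean[e + 1]) e <- e + 1
    if (e - s + 1 > best_len) { best_len <- e - s + 1L; best_start <- s }
  }
  list(start = best_start, length = best_len)
}
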