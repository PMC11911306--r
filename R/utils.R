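# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL runs the code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept below 2^31.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * i) %% 2147483587)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_range <- function(x, field, lo = -Inf, hi = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x))
    stop_config(field, "must be numeric and non-missing")
  if (!is.null(len) && length(x) != len)
    stop_config(field, sprintf("must have length %d", len))
  if (any(x < lo) || any(x > hi))
    stop_config(field, sprintf("must lie in [%g, %g]", lo, hi))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear ("open") convolution via zero-padded FFT; returns length n+m-1.
# Padding to a highly composite length keeps the transform fast for the
# long EEG records this package works with.
fast_convolve_open <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- nextn(n + m - 1, c(2, 3, 5))
  xf <- fft(c(x, numeric(L - n)))
  kf <- fft(c(k, numeric(L - m)))
  Re(fft(xf * kf, inverse = TRUE))[seq_len(n + m - 1)] / L
}
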