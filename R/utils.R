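# internal helpers: seeds, validation, analytic signal

# Deterministically derive a sub-stage seed from a master seed.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483647L)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != round(x)) abort(sprintf("`%s` must be an integer, got %s.", name, x))
  as.integer(x)
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, inverse transform. Returns a complex
# vector whose angle is the instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Odd (point-symmetric) reflection padding, the standard zero-phase filtering
# edge treatment; p is the pad length in samples.
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  if (p <= 0L) return(list(x = x, p = 0L))
  head_pad <- 2 * x[1] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  list(x = c(head_pad, x, tail_pad), p = p)
}

# Zero-phase Butterworth filtering with reflection padding. A band-pass is
# realized as a cascade of the order-`order` high-pass and low-pass
# sections: with well-separated corners this matches the band-pass response
# in the passband while keeping the recursion numerically well conditioned
# (a directly designed band-pass with a very low normalized corner has
# poles so close to the unit circle that the filter loses precision).
butter_filtfilt <- function(x, fs, cutoff, type, order = 3L) {
  nyq <- fs / 2
  if (any(cutoff >= nyq)) {
    abort(sprintf("Filter cutoff (%s Hz) must lie below the Nyquist frequency (%s Hz).",
                  paste(cutoff, collapse = "-"), nyq))
  }
  # pad by ~3 time constants (1 / (2 pi f)) of the slowest cutoff
  p <- as.integer(ceiling(3 * fs / (2 * pi * min(cutoff))))
  padded <- reflect_pad(x, p)
  y <- padded$x
  if (type == "pass") {
    y <- signal::filtfilt(signal::butter(order, cutoff[1] / nyq, "high"), y)
    y <- signal::filtfilt(signal::butter(order, cutoff[2] / nyq, "low"), y)
  } else {
    y <- signal::filtfilt(signal::butter(order, cutoff / nyq, type = type), y)
  }
  if (padded$p > 0L) y <- y[(padded$p + 1L):(padded$p + length(x))]
  y
}

pair_index <- function(n) {
  # all unordered pairs i < j as a two-column matrix
  if (n < 2L) abort("Need at least 2 cells to form pairs.")
  idx <- utils::combn(n, 2L)
  cbind(idx[1L, ], idx[2L, ])
}

off_diag_mean <- function(m) mean(m[lower.tri(m)])

wrap_degrees <- function(x) ((x %% 360) + 360) %% 360
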