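# Internal helpers: seeded evaluation, seed derivation, analytic signal,
# zero-phase FIR filtering via zero-padded FFT convolution.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed; keeps results < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + 1
              + (as.double(i) * 2654435761) %% 2147483647) %% 2147483647)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Weights that turn an FFT into the FFT of the analytic signal.
analytic_weights <- function(n) {
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((n + 1L) / 2L)] <- 2
  }
  w
}

# Analytic signal of a real series (complex); Mod() of it is the envelope.
analytic_signal <- function(x) {
  n <- length(x)
  stats::fft(stats::fft(x) * analytic_weights(n), inverse = TRUE) / n
}

#' Design the band-pass FIR filter used throughout the pipeline
#'
#' Linear-phase FIR band-pass (Hamming window design via
#' [signal::fir1()]) of the stated order. Order 62 is used for every band,
#' mirroring the filter applied to the alpha range in the source analyses.
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Filter order (number of taps minus one).
#' @return Numeric vector of `order + 1` filter coefficients.
#' @export
fir_bandpass <- function(fs, low, high, order = 62L) {
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
}

# Zero-phase kernel of a linear-phase FIR filter: h convolved with rev(h).
zero_phase_kernel <- function(h) {
  stats::convolve(h, rev(h), type = "open")
}

# Precompute the frequency-domain mask that band-filters (zero-phase) and
# forms the analytic signal of an epoch of length `len`, on a zero-padded
# transform of composite-friendly length.
envelope_mask <- function(len, h) {
  g <- zero_phase_kernel(h)
  npad <- stats::nextn(len + length(g) - 1L, c(2L, 3L, 5L))
  mask <- stats::fft(c(g, numeric(npad - length(g)))) * analytic_weights(npad)
  list(mask = mask, npad = npad, offset = length(h) - 1L, len = len)
}

# Apply an envelope_mask to a matrix of epochs (len x n_epochs): returns the
# amplitude envelope of the zero-phase band-filtered epochs, same shape.
envelope_apply <- function(E, em) {
  m <- ncol(E)
  P <- rbind(E, matrix(0, em$npad - nrow(E), m))
  A <- stats::mvfft(stats::mvfft(P) * em$mask, inverse = TRUE) / em$npad
  Mod(A[em$offset + seq_len(em$len), , drop = FALSE])
}

# Zero-phase FIR filter of a long one-dimensional signal (zero-padded
# linear convolution with the symmetric kernel); used for signal synthesis.
zero_phase_filter <- function(x, h) {
  g <- zero_phase_kernel(h)
  n <- length(x)
  npad <- stats::nextn(n + length(g) - 1L, c(2L, 3L, 5L))
  y <- Re(stats::fft(stats::fft(c(x, numeric(npad - n))) *
                       stats::fft(c(g, numeric(npad - length(g)))),
                     inverse = TRUE)) / npad
  y[(length(h) - 1L) + seq_len(n)]
}

# Tiny rolling hash of a character scalar, for config provenance stamps.
config_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
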