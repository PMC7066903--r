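#' @importFrom stats fft mvfft rnorm sd var cor coef
NULL

# FFT frequency axis for a length-n real series sampled at fs:
# bin k (1-based) has frequency (k-1)*fs/n for k <= n/2+1, negative above.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Zero-phase ideal band-pass of the columns of X (samples x channels) by
# spectral masking. If analytic = TRUE, returns the band-limited analytic
# signal (complex; positive frequencies doubled, negatives zeroed), whose
# modulus is the Hilbert amplitude envelope of the band-passed series.
fft_bandpass <- function(X, fs, f_lo, f_hi, analytic = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  f <- fft_freqs(n, fs)
  if (analytic) {
    keep <- f >= f_lo & f <= f_hi
    gain <- ifelse(keep, 2, 0)
    # do not double DC/Nyquist (not in any band with f_lo > 0, but be safe)
    gain[f == 0 | abs(f) == fs / 2] <- as.numeric(keep[f == 0 | abs(f) == fs / 2])
  } else {
    keep <- abs(f) >= f_lo & abs(f) <= f_hi
    gain <- as.numeric(keep)
  }
  Y <- mvfft(X) * gain
  Z <- mvfft(Y, inverse = TRUE) / n
  if (analytic) Z else Re(Z)
}

# Unit-variance narrowband Gaussian columns, synthesized directly in the
# frequency domain (iid complex Gaussian coefficients on the band bins,
# hermitian-symmetrized, one inverse FFT). Distributionally identical to
# spectral masking of white Gaussian noise, at half the FFT cost.
narrowband_matrix <- function(n, fs, band, ncols) {
  f <- fft_freqs(n, fs)
  pos <- which(f >= band$f_lo & f <= band$f_hi & f > 0 & f < fs / 2)
  if (!length(pos)) stop("band '", band$name, "' contains no frequency bin at n = ", n)
  Z <- matrix(0+0i, n, ncols)
  z <- matrix(complex(real = rnorm(length(pos) * ncols),
                      imaginary = rnorm(length(pos) * ncols)),
              length(pos), ncols)
  Z[pos, ] <- z
  Z[n - pos + 2L, ] <- Conj(z)
  X <- Re(mvfft(Z, inverse = TRUE))
  scale(X)
}

# Band-limited analytic signal of a single series or matrix columns.
analytic_signal <- function(X, fs, band) {
  band <- as_band(band)
  check_band_fs(band, fs)
  fft_bandpass(X, fs, band$f_lo, band$f_hi, analytic = TRUE)
}

#' Notch filter powerline contamination
#'
#' Removes a powerline frequency and all of its harmonics below the Nyquist
#' frequency with zero-phase (forward-backward) second-order Butterworth
#' band-stop filters. The stop bandwidth is `base/q` Hz around every harmonic,
#' so the total stopped bandwidth stays a small fraction of the spectrum.
#'
#' @param x numeric vector, or samples-by-channels matrix, or a [roi_ts()].
#' @param base powerline base frequency in Hz (e.g. 60); must be below Nyquist.
#' @param fs sampling rate in Hz (ignored when `x` is a `roi_ts`).
#' @param q quality factor of the fundamental notch; stop bandwidth = `base/q`.
#' @return Filtered object of the same shape/class as `x`.
#' @export
notch_filter <- function(x, base = 60, fs = NULL, q = 30) {
  if (inherits(x, "roi_ts")) {
    out <- x
    out$data <- t(notch_filter(t(x$data), base = base, fs = x$fs, q = q))
    return(out)
  }
  stopifnot(is.numeric(fs), fs > 0)
  if (base >= fs / 2) stop("notch base frequency ", base,
                           " Hz is at or above the Nyquist frequency ", fs / 2, " Hz")
  X <- as.matrix(x)
  bw <- base / q
  harmonics <- seq(base, fs / 2 - bw, by = base)
  for (f0 in harmonics) {
    flt <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "stop")
    for (j in seq_len(ncol(X))) X[, j] <- signal::filtfilt(flt, X[, j])
  }
  if (is.matrix(x)) X else drop(X)
}
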