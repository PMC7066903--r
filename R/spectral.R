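#' Welch power spectral density
#'
#' Hann-tapered Welch estimate per ROI (default 5-s windows, 50% overlap;
#' 0.2 Hz resolution at 1000 Hz). Windows overlapping rejected samples of
#' the keep-mask are discarded, so artifact segments never enter the
#' estimate; at least two valid windows are required. The one-sided density
#' satisfies Parseval: `sum(power) * df` approximates the signal variance.
#'
#' @param ts a [roi_ts()].
#' @param window_s window duration in seconds (default 5).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @param mask optional logical keep-mask over samples (see
#'   [mask_from_intervals()]).
#' @return An object of class `psd_estimate`: list with `freq` (Hz grid),
#'   `power` (ROI x frequency matrix, units^2/Hz), `window_s`, `overlap`,
#'   `n_windows`, `fs`.
#' @export
welch_psd <- function(ts, window_s = 5, overlap = 0.5, mask = NULL) {
  stopifnot(inherits(ts, "roi_ts"), window_s > 0, overlap >= 0, overlap < 1)
  fs <- ts$fs
  n <- ncol(ts$data)
  nw <- round(window_s * fs)
  if (nw > n) stop("recording (", n / fs, " s) is shorter than one window (",
                   window_s, " s)")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = hop)
  ok <- vapply(starts, function(s) all(mask[s:(s + nw - 1L)]), logical(1))
  starts <- starts[ok]
  if (length(starts) < 2)
    stop("fewer than 2 artifact-free Welch windows remain after masking")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))   # Hann taper
  scale <- 1 / (fs * sum(w^2))
  nf <- nw %/% 2 + 1L
  acc <- matrix(0, nrow(ts$data), nf)
  for (s in starts) {
    seg <- ts$data[, s:(s + nw - 1L), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(w, each = nrow(seg))
    P <- Mod(mvfft(t(seg)))^2 * scale
    P <- t(P[seq_len(nf), , drop = FALSE])
    P[, 2:(nf - 1L)] <- 2 * P[, 2:(nf - 1L)]   # one-sided doubling
    acc <- acc + P
  }
  power <- acc / length(starts)
  rownames(power) <- rownames(ts$data)
  structure(list(freq = (seq_len(nf) - 1L) * fs / nw, power = power,
                 window_s = window_s, overlap = overlap,
                 n_windows = length(starts), fs = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d ROIs, %g-%g Hz (df = %g Hz), %d Welch windows of %g s\n",
              nrow(x$power), min(x$freq), max(x$freq), x$freq[2] - x$freq[1],
              x$n_windows, x$window_s))
  invisible(x)
}

# indices of the closed band interval on the discrete frequency grid
band_bins <- function(freq, f_lo, f_hi) {
  idx <- which(freq >= f_lo - 1e-9 & freq <= f_hi + 1e-9)
  if (!length(idx)) stop("band ", f_lo, "-", f_hi,
                         " Hz contains no frequency grid point")
  idx
}

#' Relative band power
#'
#' Band-integrated PSD divided by the power integrated over the full
#' analysis range (default 2-90 Hz, the span of the six canonical bands).
#' Band intervals are closed on the discrete grid; inter-band gaps
#' contribute to the denominator only. Relative power is invariant to any
#' overall amplitude scaling of the signal.
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param bands list of [band_spec()]s (default the six canonical bands).
#' @param total_range length-2 numeric, denominator integration range in Hz.
#' @return ROI x band matrix of relative powers in `[0, 1]` (class
#'   `band_power_table`); rows sum to at most 1.
#' @export
relative_band_power <- function(psd, bands = canonical_bands(),
                                total_range = c(2, 90)) {
  stopifnot(inherits(psd, "psd_estimate"), length(total_range) == 2)
  for (b in bands)
    if (b$f_lo < total_range[1] - 1e-9 || b$f_hi > total_range[2] + 1e-9)
      stop("band '", b$name, "' lies outside the total power range")
  total <- rowSums(psd$power[, band_bins(psd$freq, total_range[1], total_range[2]),
                             drop = FALSE])
  out <- vapply(bands, function(b)
    rowSums(psd$power[, band_bins(psd$freq, b$f_lo, b$f_hi), drop = FALSE]) / total,
    numeric(nrow(psd$power)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(psd$power),
                        vapply(bands, `[[`, character(1), "name"))
  structure(out, class = c("band_power_table", "matrix", "array"))
}

#' Peak frequency within a band
#'
#' The frequency of the PSD maximum restricted to a band; ties are broken
#' toward the lower frequency.
#'
#' @param psd a `psd_estimate`.
#' @param band a [band_spec()] or canonical band name.
#' @param roi ROI name or index (default 1).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(psd, band, roi = 1) {
  stopifnot(inherits(psd, "psd_estimate"))
  band <- as_band(band)
  idx <- band_bins(psd$freq, band$f_lo, band$f_hi)
  p <- psd$power[roi, idx]
  psd$freq[idx[which.max(p)]]   # which.max takes the first (lowest-f) maximum
}
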