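#' Frequency band specification
#'
#' A band is a named closed frequency interval `[f_lo, f_hi]` in Hz. The six
#' canonical bands used throughout the resting-state DMN analysis are delta
#' (2-4 Hz), theta (5-7 Hz), alpha (8-12 Hz), beta (15-29 Hz), gamma1
#' (30-59 Hz) and gamma2 (60-90 Hz).
#'
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 12)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop("band edges must satisfy 0 < f_lo < f_hi (got [", f_lo, ", ", f_hi, "])")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical frequency bands
#'
#' @param fs optional sampling rate (Hz); if given, bands exceeding the
#'   Nyquist frequency `fs/2` are rejected with an error.
#' @return Named list of [band_spec()] objects: delta, theta, alpha, beta,
#'   gamma1, gamma2.
#' @examples
#' canonical_bands()$alpha
#' @export
canonical_bands <- function(fs = NULL) {
  bands <- list(
    delta  = band_spec("delta",   2,  4),
    theta  = band_spec("theta",   5,  7),
    alpha  = band_spec("alpha",   8, 12),
    beta   = band_spec("beta",   15, 29),
    gamma1 = band_spec("gamma1", 30, 59),
    gamma2 = band_spec("gamma2", 60, 90)
  )
  if (!is.null(fs)) for (b in bands) check_band_fs(b, fs)
  bands
}

# shared validation: band must fit under Nyquist
check_band_fs <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= fs / 2)
    stop("band '", band$name, "' (", band$f_lo, "-", band$f_hi,
         " Hz) exceeds the Nyquist frequency ", fs / 2, " Hz")
  invisible(band)
}

# coerce "alpha" or a band_spec to a band_spec
as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) {
    bands <- canonical_bands()
    if (!band %in% names(bands)) stop("unknown band name '", band, "'")
    return(bands[[band]])
  }
  stop("'band' must be a band_spec or a canonical band name")
}
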