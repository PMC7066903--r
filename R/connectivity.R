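#' Band-limited amplitude envelopes
#'
#' The amplitude envelope of a cortical oscillation is the modulus of the
#' analytic (Hilbert) signal of the band-pass-filtered series. Filtering
#' and the Hilbert transform are applied jointly in the frequency domain
#' (zero-phase), so envelope timing is not skewed across ROIs.
#'
#' @param ts a [roi_ts()].
#' @param band a [band_spec()] or canonical band name.
#' @return An `envelope_set`: list with `env` (ROI x samples nonnegative
#'   matrix), `band`, `fs`.
#' @export
amplitude_envelope <- function(ts, band) {
  stopifnot(inherits(ts, "roi_ts"))
  band <- as_band(band)
  check_band_fs(band, ts$fs)
  z <- analytic_signal(t(ts$data), ts$fs, band)
  env <- t(Mod(z))
  rownames(env) <- rownames(ts$data)
  structure(list(env = env, band = band, fs = ts$fs), class = "envelope_set")
}

# samples to trim at each edge before correlating envelopes: one filter
# transient length, max(1 s, 3 / f_lo)
envelope_trim <- function(band, fs) round(max(1, 3 / band$f_lo) * fs)

#' Amplitude envelope correlation matrix
#'
#' Pearson correlation between the band-limited amplitude envelopes of
#' every ROI pair, over the full continuous (masked) recording. One filter
#' transient length (`max(1 s, 3/f_lo)`) is trimmed at each edge before
#' correlating; at least 10 s must remain. The diagonal is zero by
#' convention so node strength needs no self-term handling. A constant
#' (zero-variance) envelope yields zero entries with a warning.
#'
#' @param ts a [roi_ts()] with at least 2 ROIs.
#' @param band a [band_spec()] or canonical band name.
#' @param mask optional logical keep-mask over samples; rejected samples are
#'   excluded from the correlation.
#' @return A symmetric ROI x ROI matrix (class `aec_matrix`) with attribute
#'   `band`.
#' @export
aec_matrix <- function(ts, band, mask = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(ts$data) < 2) stop("AEC needs at least 2 ROIs")
  band <- as_band(band)
  es <- amplitude_envelope(ts, band)
  n <- ncol(es$env)
  tr <- envelope_trim(band, ts$fs)
  keep <- rep(FALSE, n)
  keep[(tr + 1):(n - tr)] <- TRUE
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 10 * ts$fs)
    stop("fewer than 10 s of envelope remain after edge trimming/masking")
  E <- t(es$env[, keep, drop = FALSE])
  sds <- apply(E, 2, sd)
  if (any(sds == 0))
    warning("constant envelope in ROI(s) ",
            paste(rownames(ts$data)[sds == 0], collapse = ", "),
            "; AEC entries set to 0")
  A <- suppressWarnings(cor(E))
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2
  structure(A, band = band$name, class = c("aec_matrix", "matrix", "array"))
}

#' Graph node strength
#'
#' The strength of node i is the sum of AEC values on its incident edges,
#' `s_i = sum_{j != i} A_ij`; with a zero diagonal this is the plain row
#' sum. Bounded by +/-(N-1) for correlations.
#'
#' @param A symmetric adjacency matrix (e.g. an [aec_matrix()]); asymmetry
#'   beyond 1e-10 is an error.
#' @return Named numeric vector of node strengths.
#' @export
node_strength <- function(A) {
  A <- unclass(A)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency matrix is not symmetric")
  B <- A
  diag(B) <- 0
  rowSums(B)
}

#' Node-strength table for a cohort
#'
#' Computes per-subject, per-band AEC matrices and node strengths for every
#' ROI, returning the tidy feature table used by the group statistics and
#' ROC stages.
#'
#' @param cohort a `meg_cohort` from [simulate_cohort()], or a list of
#'   `subject_record`s.
#' @param bands list of [band_spec()]s (default the six canonical bands).
#' @param mask optional keep-mask applied to every subject.
#' @return data.frame with columns `subject`, `group`, `roi`, `band`,
#'   `strength`.
#' @export
cohort_node_strength <- function(cohort, bands = canonical_bands(), mask = NULL) {
  out <- lapply(cohort, function(rec) {
    per_band <- lapply(bands, function(b) {
      s <- node_strength(aec_matrix(rec$roi_ts, b, mask = mask))
      data.frame(subject = rec$subject_id, group = rec$group,
                 roi = names(s), band = b$name, strength = unname(s),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_band)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-edge AEC values for a cohort
#'
#' @param cohort a `meg_cohort` or list of `subject_record`s.
#' @param band a [band_spec()] or canonical band name.
#' @param mask optional keep-mask.
#' @return data.frame with columns `subject`, `group`, `roi_i`, `roi_j`
#'   (`roi_i` before `roi_j` in ROI order), `band`, `aec`.
#' @export
cohort_edge_aec <- function(cohort, band, mask = NULL) {
  band <- as_band(band)
  out <- lapply(cohort, function(rec) {
    A <- aec_matrix(rec$roi_ts, band, mask = mask)
    rois <- rownames(rec$roi_ts$data)
    idx <- which(upper.tri(A), arr.ind = TRUE)
    data.frame(subject = rec$subject_id, group = rec$group,
               roi_i = rois[idx[, 1]], roi_j = rois[idx[, 2]],
               band = band$name, aec = A[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
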