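#' ROI time-series container
#'
#' The pipeline's central currency: a matrix of region-of-interest (ROI)
#' source-density time series (rows = ROIs, columns = samples) together with
#' its sampling rate. Constructed directly, by the synthetic cohort
#' simulator, or by [roi_average()] after source inversion.
#'
#' @param data numeric matrix, ROIs x samples; rownames are ROI labels
#'   (generated as `ROI1..ROIk` when absent).
#' @param fs sampling rate in Hz.
#' @return An object of class `roi_ts` with elements `data`, `fs`.
#' @export
roi_ts <- function(data, fs) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(rownames(data))) rownames(data) <- paste0("ROI", seq_len(nrow(data)))
  structure(list(data = data, fs = fs), class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  ROIs:", paste(rownames(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Canonical DMN region labels
#'
#' The 12 default-mode-network regions used in the analysis: bilateral
#' posterior cingulate cortex (PCC), precuneus (PCu), inferior parietal
#' lobule (IPL), medial temporal cortex (MTC), medial frontal cortex (MFC)
#' and lateral temporal cortex (LTC). Suffixes `_L`/`_R` denote hemisphere.
#'
#' @return Character vector of 12 ROI labels.
#' @export
dmn_roi_names <- function() {
  as.vector(outer(c("PCC", "PCu", "IPL", "MTC", "MFC", "LTC"),
                  c("L", "R"), paste, sep = "_"))
}

#' Read / write ROI time series as delimited text
#'
#' The on-disk format is a comment header line `# fs=<Hz>`, a CSV header row
#' of ROI names, then one row per sample. `read_roi_timeseries()` validates
#' the header and rejects ragged rows with the offending line number.
#'
#' @param x a [roi_ts()] object.
#' @param path file path.
#' @param digits significant digits written (default 15, round-trip safe).
#' @return `read_roi_timeseries()` returns a `roi_ts`;
#'   `write_roi_timeseries()` returns `path` invisibly.
#' @export
write_roi_timeseries <- function(x, path, digits = 15) {
  stopifnot(inherits(x, "roi_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", x$fs), con)
  writeLines(paste(rownames(x$data), collapse = ","), con)
  utils::write.table(signif(t(x$data), digits), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @export
read_roi_timeseries <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#\\s*fs=", lines[1L]))
    stop("missing '# fs=<Hz>' header line in ", path)
  fs <- as.numeric(sub("^#\\s*fs=", "", lines[1L]))
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in header of ", path)
  rois <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  body <- readLines(path)[-(1:2)]
  rows <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(rois))
  if (length(bad))
    stop("ragged row in ", path, ": line ", bad[1L] + 2L, " has ", nf[bad[1L]],
         " fields, expected ", length(rois))
  m <- matrix(as.numeric(unlist(rows)), ncol = length(rois), byrow = TRUE,
              dimnames = list(NULL, rois))
  roi_ts(t(m), fs)
}

#' Sample masks for artifact-contaminated segments
#'
#' Visual-inspection segment rejection is modeled as a boolean keep-mask over
#' samples, honored by all downstream windowing. Masks are stored as JSON
#' lists of 1-based inclusive `[start, stop]` sample intervals marking the
#' *rejected* segments.
#'
#' @param n_samples recording length in samples.
#' @param intervals list of length-2 integer vectors (rejected segments),
#'   or a path to a JSON file of such intervals.
#' @return Logical vector of length `n_samples`; `TRUE` = keep.
#' @export
mask_from_intervals <- function(n_samples, intervals) {
  if (is.character(intervals))
    intervals <- jsonlite::fromJSON(intervals, simplifyMatrix = FALSE)
  keep <- rep(TRUE, n_samples)
  for (iv in intervals) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1L] > iv[2L])
      stop("mask interval must be [start, stop] with start <= stop")
    if (iv[1L] < 1L || iv[2L] > n_samples)
      stop("mask interval [", iv[1L], ", ", iv[2L],
           "] lies outside the recording (1..", n_samples, ")")
    keep[iv[1L]:iv[2L]] <- FALSE
  }
  keep
}
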