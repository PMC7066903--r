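# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-subject seed from the cohort master seed (Lehmer-style
# integer hash; all arithmetic stays below 2^53 so doubles are exact).
subject_seed <- function(master_seed, index) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  h <- (h * 48271 + as.numeric(index)) %% m
  as.integer(max(h, 1))
}

#' Narrowband Gaussian noise
#'
#' Generates a zero-mean, unit-variance Gaussian series whose spectral
#' content is confined to a single frequency band, by zero-phase spectral
#' masking of white Gaussian noise. The result is the ideal band-limited
#' Gaussian process: all of its Welch spectral mass lies inside the band.
#'
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @param band a [band_spec()] or canonical band name; must lie below `fs/2`.
#' @param seed integer RNG seed.
#' @return Numeric vector of length `fs * duration`, standardized to mean 0,
#'   variance 1.
#' @export
make_narrowband_noise <- function(fs, duration, band, seed) {
  band <- as_band(band)
  check_band_fs(band, fs)
  n <- round(fs * duration)
  x <- with_seed(seed, rnorm(n))
  x <- fft_bandpass(x, fs, band$f_lo, band$f_hi)
  as.vector(scale(x))
}

#' Envelope-coupling specification
#'
#' Declares latent Gaussian signal correlations between ROI pairs within one
#' frequency band. For a pair with latent correlation `r`, the two ROIs'
#' band components are built as `sqrt(1 - r) * own + sqrt(r) * shared`, so
#' their signal correlation is exactly `r` and the large-sample amplitude
#' envelope correlation (AEC) converges to `r^2` (Gaussian narrowband
#' identity). If the same pair appears in several specs (e.g. baseline plus
#' an SCD elevation), the correlations add.
#'
#' @param band band name or [band_spec()].
#' @param roi_i,roi_j character vectors of ROI labels (recycled); must differ
#'   element-wise.
#' @param r latent signal correlation(s) in `[0, 1]`.
#' @return A data.frame with columns `band`, `roi_i`, `roi_j`, `r`.
#' @export
coupling_spec <- function(band, roi_i, roi_j, r) {
  band <- vapply(band, function(b) as_band(b)$name, character(1))
  df <- data.frame(band = band, roi_i = roi_i, roi_j = roi_j, r = r,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (any(df$roi_i == df$roi_j)) stop("coupling pairs must reference distinct ROIs")
  if (any(df$r < 0 | df$r > 1)) stop("latent correlations must lie in [0, 1]")
  df
}

#' Default coupling structure of the synthetic cohort
#'
#' `default_baseline_coupling()` gives every subject a weak within-DMN
#' scaffold in all six bands: homotopic (left-right) pairs plus PCC-hub
#' edges. `default_scd_coupling()` is the extra coupling received only by
#' SCD subjects: a strong right PCu - right PCC elevation at delta, gamma1
#' and gamma2, with weaker LTC-PCC elevations, mirroring the edges reported
#' as increased in SCD. Effect sizes are package choices (see the methods
#' vignette); the study quantifies directions, not generative magnitudes.
#'
#' @return A coupling data.frame (see [coupling_spec()]).
#' @export
default_baseline_coupling <- function() {
  bands <- names(canonical_bands())
  base_one <- rbind(
    coupling_spec("delta", "PCC_L", "PCC_R", 0.06),
    coupling_spec("delta", c("PCu_L", "IPL_L", "MTC_L", "MFC_L", "LTC_L"),
                  c("PCu_R", "IPL_R", "MTC_R", "MFC_R", "LTC_R"), 0.06),
    coupling_spec("delta", c("PCC_L", "PCC_R"), c("PCu_L", "PCu_R"), 0.05),
    coupling_spec("delta", c("PCC_L", "PCC_R"), c("LTC_L", "LTC_R"), 0.05),
    coupling_spec("delta", c("PCC_L", "PCC_R"), c("IPL_L", "IPL_R"), 0.04)
  )
  do.call(rbind, lapply(bands, function(b) transform(base_one, band = b)))
}

#' @rdname default_baseline_coupling
#' @export
default_scd_coupling <- function() {
  rbind(
    coupling_spec("delta",  "PCu_R", "PCC_R", 0.60),
    coupling_spec("delta",  c("LTC_L", "LTC_R"), c("PCC_R", "PCC_L"), 0.15),
    coupling_spec("gamma1", "PCu_R", "PCC_R", 0.60),
    coupling_spec("gamma1", c("LTC_L", "LTC_L"), c("PCC_L", "PCC_R"), 0.15),
    coupling_spec("gamma2", "PCu_R", "PCC_R", 0.60),
    coupling_spec("gamma2", "LTC_L", "PCC_L", 0.15)
  )
}

#' Synthetic two-group cohort configuration
#'
#' Describes a full mechanistic cohort: group sizes, recording parameters,
#' ROI set, per-band envelope coupling for all subjects
#' (`baseline_coupling`) and the additional coupling received by SCD
#' subjects (`scd_extra_coupling`), a complaint-count model, and the master
#' seed from which per-subject seeds are derived. Defaults follow the study
#' conditions: 26 HC and 27 SCD subjects, 5-minute recordings digitized at
#' 1000 Hz, 12 DMN regions.
#'
#' @param n_hc,n_scd group sizes (each >= 2).
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds; must allow >= 10 Welch windows
#'   of 5 s at 50% overlap (i.e. >= 27.5 s).
#' @param roi_names ROI labels; the canonical DMN set has 12.
#' @param bands list of [band_spec()]s composing the signal.
#' @param baseline_coupling,scd_extra_coupling coupling data.frames
#'   ([coupling_spec()]).
#' @param noise_floor standard deviation of additive broadband white noise
#'   (0 disables it).
#' @param complaint_model numeric `c(intercept, slope, noise_sd)` linking
#'   gamma1 PCC node strength to the Poisson mean of an SCD subject's
#'   complaint count (clipped to 1..12), or `NULL` to skip complaints.
#' @param seed master integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 26, n_scd = 27, fs = 1000, duration = 300,
                          roi_names = dmn_roi_names(),
                          bands = canonical_bands(),
                          baseline_coupling = default_baseline_coupling(),
                          scd_extra_coupling = default_scd_coupling(),
                          noise_floor = 0,
                          complaint_model = c(intercept = 2, slope = 4, noise_sd = 0.25),
                          seed = 1) {
  stopifnot(n_hc >= 2, n_scd >= 2, fs > 0, length(roi_names) >= 2,
            !anyDuplicated(roi_names))
  if (duration < 27.5)
    stop("duration ", duration, " s allows fewer than 10 Welch windows (5 s, 50% overlap)")
  for (b in bands) check_band_fs(b, fs)
  band_names <- vapply(bands, `[[`, character(1), "name")
  for (cp in list(baseline = baseline_coupling, scd_extra = scd_extra_coupling)) {
    if (is.null(cp) || !nrow(cp)) next
    bad <- setdiff(c(cp$roi_i, cp$roi_j), roi_names)
    if (length(bad)) stop("coupling references unknown ROI(s): ",
                          paste(bad, collapse = ", "))
    if (!all(cp$band %in% band_names))
      stop("coupling references band(s) not in the config band list")
  }
  if (!is.null(complaint_model)) {
    stopifnot(length(complaint_model) == 3)
    if (!"gamma1" %in% band_names)
      stop("complaint_model requires a 'gamma1' band in the config")
  }
  structure(list(n_hc = n_hc, n_scd = n_scd, fs = fs, duration = duration,
                 roi_names = roi_names, bands = bands,
                 baseline_coupling = baseline_coupling,
                 scd_extra_coupling = scd_extra_coupling,
                 noise_floor = noise_floor, complaint_model = complaint_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d HC + %d SCD, %g s @ %g Hz, %d ROIs, %d bands, seed %d\n",
              x$n_hc, x$n_scd, x$duration, x$fs, length(x$roi_names),
              length(x$bands), x$seed))
  invisible(x)
}

# Combine baseline (+ SCD extra) coupling for one band into a canonical
# table: pair order fixed by sorted ROI indices, duplicate pairs summed.
resolved_coupling <- function(config, group, band_name) {
  cp <- config$baseline_coupling
  if (identical(group, "SCD")) cp <- rbind(cp, config$scd_extra_coupling)
  if (is.null(cp) || !nrow(cp)) return(NULL)
  cp <- cp[cp$band == band_name, , drop = FALSE]
  if (!nrow(cp)) return(NULL)
  i <- match(cp$roi_i, config$roi_names)
  j <- match(cp$roi_j, config$roi_names)
  lo <- pmin(i, j); hi <- pmax(i, j)
  agg <- stats::aggregate(r ~ lo + hi, data = data.frame(lo, hi, r = cp$r), sum)
  agg <- agg[order(agg$lo, agg$hi), , drop = FALSE]
  if (any(agg$r > 1))
    stop("conflicting couplings: pair (", config$roi_names[agg$lo[which.max(agg$r)]],
         ", ", config$roi_names[agg$hi[which.max(agg$r)]], ") in band '", band_name,
         "' has summed correlation ", max(agg$r), " > 1")
  tot <- tapply(c(agg$r, agg$r), c(agg$lo, agg$hi), sum)
  if (any(tot > 1)) {
    bad <- names(tot)[which.max(tot)]
    stop("conflicting couplings: ROI '", config$roi_names[as.integer(bad)],
         "' in band '", band_name, "' has total shared variance ",
         round(max(tot), 3), " > 1 (own-noise mixing weight would be imaginary)")
  }
  agg
}

#' Simulate one subject's ROI time series
#'
#' Builds each ROI's signal as a sum of unit-variance narrowband Gaussian
#' components, one per band. Within a band, coupling pairs share a common
#' narrowband component: for pair correlation `r` the mixture is
#' `sqrt(1 - sum(r)) * own + sum over pairs of sqrt(r) * shared`, applied in
#' pair order sorted by ROI indices, so each pair's latent signal
#' correlation is exactly its `r`. SCD subjects receive the baseline plus
#' the SCD extra coupling. For SCD subjects a complaint count in 1..12 is
#' drawn from a Poisson model on the subject's realized gamma1 PCC node
#' strength.
#'
#' @param config a [cohort_config()].
#' @param group `"HC"` or `"SCD"`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id optional id string.
#' @return A list (class `subject_record`) with elements `subject_id`,
#'   `group`, `roi_ts` ([roi_ts()]) and `complaint_count` (`NA` for HC).
#' @export
simulate_subject <- function(config, group = c("HC", "SCD"), subject_seed,
                             subject_id = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  n <- round(config$fs * config$duration)
  k <- length(config$roi_names)
  with_seed(subject_seed, {
    X <- matrix(0, n, k)
    for (b in config$bands) {
      pairs <- resolved_coupling(config, group, b$name)
      p <- if (is.null(pairs)) 0L else nrow(pairs)
      W <- narrowband_matrix(n, config$fs, b, k + p)
      # mixing matrix: rows = components (k own, then p shared), cols = ROIs
      M <- matrix(0, k + p, k)
      if (p > 0) for (q in seq_len(p)) {
        M[k + q, pairs$lo[q]] <- sqrt(pairs$r[q])
        M[k + q, pairs$hi[q]] <- sqrt(pairs$r[q])
      }
      shared <- colSums(M[k + seq_len(p), , drop = FALSE]^2)
      M[cbind(seq_len(k), seq_len(k))] <- sqrt(1 - shared)
      X <- X + W %*% M
    }
    if (config$noise_floor > 0)
      X <- X + config$noise_floor * matrix(rnorm(n * k), n, k)
    ts <- roi_ts(structure(t(X), dimnames = list(config$roi_names, NULL)), config$fs)
    complaint <- NA_integer_
    if (group == "SCD" && !is.null(config$complaint_model)) {
      cm <- unname(config$complaint_model)
      A <- aec_matrix(ts, "gamma1")
      s <- node_strength(A)
      pcc <- mean(s[grepl("^PCC", names(s))])
      lambda <- max(cm[1] + cm[2] * pcc + rnorm(1, 0, cm[3]), 0.1)
      complaint <- as.integer(min(max(stats::rpois(1, lambda), 1L), 12L))
    }
    structure(list(subject_id = subject_id %||% paste0(group, "_", subject_seed),
                   group = group, roi_ts = ts, complaint_count = complaint),
              class = "subject_record")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-group cohort
#'
#' HC subjects receive the baseline coupling only; SCD subjects receive
#' baseline plus the SCD extra coupling. Per-subject seeds are derived
#' deterministically from the master seed, so an identical configuration
#' reproduces the cohort bit-identically.
#'
#' @param config a [cohort_config()].
#' @return A list of `subject_record`s (class `meg_cohort`), HC first, with
#'   the config attached as attribute `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("HC", config$n_hc), rep("SCD", config$n_scd))
  ids <- c(sprintf("HC%02d", seq_len(config$n_hc)),
           sprintf("SCD%02d", seq_len(config$n_scd)))
  subjects <- lapply(seq_along(groups), function(i)
    simulate_subject(config, groups[i], subject_seed(config$seed, i), ids[i]))
  structure(subjects, class = "meg_cohort", config = config)
}

#' @export
print.meg_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<meg_cohort> %d subjects (%d HC, %d SCD)\n",
              length(x), sum(groups == "HC"), sum(groups == "SCD")))
  invisible(x)
}

#' Printed node-strength group summaries
#'
#' The group mean and standard deviation of DMN node strength for every
#' (band, ROI) cell reported as significantly different between HC and SCD:
#' bilateral PCC at delta; left PCC at theta; left LTC, right PCu and
#' bilateral PCC at gamma1 and gamma2. These summaries drive the
#' summary-level cohort generator and the ROC benchmark.
#'
#' @return data.frame with columns `band`, `roi`, `hc_mean`, `hc_sd`,
#'   `scd_mean`, `scd_sd`.
#' @export
dmn_strength_summaries <- function() {
  utils::read.csv(text =
"band,roi,hc_mean,hc_sd,scd_mean,scd_sd
delta,PCC_L,3.1,0.9,4.4,1.6
delta,PCC_R,3.2,1.0,4.3,1.6
theta,PCC_L,3.0,0.8,4.2,1.6
gamma1,LTC_L,1.5,0.3,2.6,1.7
gamma1,PCu_R,1.7,0.4,2.7,1.5
gamma1,PCC_L,2.4,0.9,3.5,1.4
gamma1,PCC_R,2.4,1.0,3.4,1.4
gamma2,LTC_L,1.6,0.4,2.9,1.7
gamma2,PCu_R,1.9,0.5,3.0,1.6
gamma2,PCC_L,2.6,1.0,3.7,1.5
gamma2,PCC_R,2.6,1.1,3.7,1.4
", stringsAsFactors = FALSE)
}

#' Summary-level cohort configuration
#'
#' Describes a cohort generated directly at the node-strength level:
#' independent Gaussian draws per (group, ROI, band) cell from stated means
#' and standard deviations. Defaults are the printed group summaries
#' ([dmn_strength_summaries()]).
#'
#' @param cells data.frame with columns `band`, `roi`, `hc_mean`, `hc_sd`,
#'   `scd_mean`, `scd_sd`; all sds must be positive.
#' @param n_hc,n_scd group sizes.
#' @param seed integer seed.
#' @return An object of class `summary_cohort_config`.
#' @export
summary_cohort_config <- function(cells = dmn_strength_summaries(),
                                  n_hc = 26, n_scd = 27, seed = 1) {
  need <- c("band", "roi", "hc_mean", "hc_sd", "scd_mean", "scd_sd")
  stopifnot(all(need %in% names(cells)), n_hc >= 2, n_scd >= 2)
  if (any(cells$hc_sd <= 0) || any(cells$scd_sd <= 0))
    stop("all cell standard deviations must be positive")
  structure(list(cells = cells, n_hc = n_hc, n_scd = n_scd,
                 seed = as.integer(seed)),
            class = "summary_cohort_config")
}

#' Draw node strengths from group summary statistics
#'
#' @param config a [summary_cohort_config()].
#' @return A long data.frame (`subject`, `group`, `roi`, `band`, `strength`)
#'   with one row per subject and cell; deterministic given the seed.
#' @export
simulate_strength_summaries <- function(config) {
  stopifnot(inherits(config, "summary_cohort_config"))
  with_seed(config$seed, {
    out <- lapply(seq_len(nrow(config$cells)), function(i) {
      cell <- config$cells[i, ]
      data.frame(
        subject = c(sprintf("HC%02d", seq_len(config$n_hc)),
                    sprintf("SCD%02d", seq_len(config$n_scd))),
        group = c(rep("HC", config$n_hc), rep("SCD", config$n_scd)),
        roi = cell$roi, band = cell$band,
        strength = c(rnorm(config$n_hc, cell$hc_mean, cell$hc_sd),
                     rnorm(config$n_scd, cell$scd_mean, cell$scd_sd)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
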