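# Small configurations reused across tests. Sampling at 200-250 Hz keeps the
# gamma2 band (60-90 Hz) below Nyquist while making simulations fast.

# single coupled ROI pair in one band
pair_config <- function(r, band = "alpha", fs = 250, duration = 300) {
  cohort_config(
    n_hc = 2, n_scd = 2, fs = fs, duration = duration,
    roi_names = c("A", "B"),
    bands = canonical_bands()[band],
    baseline_coupling = if (r > 0) coupling_spec(band, "A", "B", r) else NULL,
    scd_extra_coupling = NULL, complaint_model = NULL)
}

# small full-DMN cohort with the default coupling structure
tiny_cohort_config <- function(n_hc = 3, n_scd = 3, seed = 1, duration = 30,
                               complaint_model = NULL, ...) {
  cohort_config(n_hc = n_hc, n_scd = n_scd, fs = 200, duration = duration,
                seed = seed, complaint_model = complaint_model, ...)
}

# brute-force Benjamini-Hochberg step-up: reject H_(1..k) for the largest k
# with p_(k) <= k/m * alpha
bh_reject_bruteforce <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# brute-force AUC by enumerating all (positive, negative) score pairs
auc_bruteforce <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
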