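---
title: "Methods: resting-state MEG DMN connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state MEG DMN connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdmn)
```

## The analysis

`megdmn` implements a resting-state magnetoencephalography (MEG) analysis of
the default mode network (DMN), aimed at separating individuals with
subjective cognitive decline (SCD) from healthy controls (HC). The pipeline
runs:

1. **Preprocessing** — zero-phase notch filters at the powerline frequency
   and its harmonics; PCA-based signal-space projection of stereotyped
   artifacts (heartbeat, blinks); segment rejection represented as a boolean
   keep-mask honored by all downstream windowing.
2. **Source reconstruction** — depth-weighted minimum-norm estimation (MNE)
   on a user-supplied leadfield, `W = R G' (G R G' + lambda^2 C)^{-1}`, and
   plain averaging of source current density within each of 12 DMN regions
   (bilateral PCC, PCu, inferior parietal lobule, medial temporal cortex,
   medial frontal cortex, LTC).
3. **Spectra** — Welch power spectral density (5-s Hann windows, 50%
   overlap) and relative band power in six bands: delta 2-4, theta 5-7,
   alpha 8-12, beta 15-29, gamma1 30-59, gamma2 60-90 Hz.
4. **Connectivity** — amplitude envelope correlation (AEC): the Pearson
   correlation between Hilbert amplitude envelopes of band-limited ROI
   signals, collected into a symmetric 12 x 12 adjacency matrix per band,
   summarized by node strength (sum of incident AEC values).
5. **Statistics** — per-(ROI, band) one-way ANOVA with Benjamini-Hochberg
   FDR across the ROI x band family; edge-level t tests at a Bonferroni
   threshold `alpha/m` with declared `m`; demographics t/chi-squared tests;
   one-tailed Spearman correlation between PCC strength and complaint
   counts.
6. **Discrimination** — ROC analysis of PCC node strength (SCD positive),
   with the Mann-Whitney AUC and a Youden-index operating point.

Because no subject-level recordings are distributed, a synthetic cohort
module generates data with the statistical structure the analysis assumes,
at two levels of mechanism (below).

## Synthetic cohorts

### Mechanistic generator

Each subject's ROI signal is a sum of independent unit-variance narrowband
Gaussian components, one per band. Narrowband components are synthesized
directly in the frequency domain: iid complex Gaussian coefficients on the
band's frequency bins, hermitian-symmetrized and inverse-transformed. This
is the ideal zero-phase band filter applied to white Gaussian noise — band
purity is exact, no filter transient exists, and the Gaussian
envelope-correlation identity below holds without FIR design error.

Envelope coupling is induced by shared components. For a pair (i, j) with
latent signal correlation `r`, both ROIs mix a common narrowband component:

    x_i = sqrt(1 - sum_j r_ij) * own_i + sum_j sqrt(r_ij) * shared_ij

with pair order fixed by sorted ROI indices and one shared component per
neighbor. The pairwise signal correlation is exactly `r_ij`, and for
narrowband Gaussian signals the amplitude envelope correlation converges to
`r^2` (the modulus-squared coherence identity for Rayleigh envelopes). The
variance bookkeeping requires `sum_j r_ij <= 1` per ROI and band;
configurations violating it are rejected (the own-noise mixing weight would
be imaginary).

SCD subjects receive the baseline coupling plus an SCD-specific elevation.
The defaults place a strong right PCu - right PCC elevation (latent r +0.60)
at delta, gamma1 and gamma2, plus weaker LTC-PCC elevations (+0.15),
mirroring the edges reported as increased in SCD; alpha and beta receive no
elevation. The published study quantifies effect *directions* and
group-level strength summaries, not generative coupling magnitudes, so these
values are package choices made once: they were set so that (a) the per-ROI
shared-variance budget is respected, and (b) the elevated PCC edges produce
strength differences comparable, in standardized terms, to the reported
group separations. The per-pair shared-component construction bounds the sum
of latent correlations per ROI at 1, which caps achievable absolute node
strengths well below the printed means (~3-4); reproducing those *absolute*
levels is therefore delegated to the summary-level generator, and the
mechanistic generator is used for structure-recovery properties only.

Complaint counts for SCD subjects follow a Poisson model on the subject's
realized gamma1 PCC node strength, `lambda = 2 + 4 * strength` plus Gaussian
jitter (sd 0.25), clipped to 1..12. The slope was chosen so that the implied
Spearman association between gamma1 PCC strength and complaints is weakly
positive (around 0.2-0.3), qualitatively matching the reported association
without overclaiming.

Per-subject seeds are a deterministic integer hash of the master seed and
subject index, so cohorts are bit-identical given their configuration and
subjects can be regenerated independently.

Defaults follow the study conditions: 26 HC + 27 SCD, 300-s recordings at
1000 Hz, 12 DMN ROIs.

What the generator does **not** emulate: 1/f background spectra (only an
optional white-noise floor), between-subject biological variability in
coupling (group differences are driven by the coupling structure plus
estimation noise alone; real cohorts have larger within-group strength
variance), sensor-level physics, and nonstationarity. Passing
structure-recovery tests therefore demonstrates correctness of the analysis
chain under its own assumptions, not expected performance on real
recordings.

### Summary-level generator

For (group, ROI, band) cells with published node-strength means and SDs, the
summary generator draws independent Gaussians per subject and cell. This is
the basis of the ROC benchmark: Monte-Carlo cohorts (26 + 27 subjects)
scored by PCC node strength — left PCC for delta, bilateral sum (left and
right drawn independently, then summed) for gamma2 — averaged over 10,000
replicate AUCs. The closed-form binormal AUC
`pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))` is the analytic oracle.

## Numerical choices

* **Regularization.** `lambda2 = 1/SNR` with default SNR 3, i.e. 0.33,
  following the convention stated with the original analysis; the more
  common `1/SNR^2` convention is available via
  `inverse_config(lambda_convention = "inverse_snr2")`.
* **Depth weighting.** `R_ii = ||g_i||^{-2 gamma}`, gamma = 0.5 (a standard
  default; the source analysis names depth weighting without an exponent),
  normalized so `max R_ii = 1`. A rank-deficient noise covariance is
  diagonally loaded with `1e-6 * trace(C)/n`.
* **ROI averaging** is the plain arithmetic mean of member source series;
  sources with opposite orientation signs cancel. This is documented, not
  corrected: no sign-flip option is applied by default.
* **Welch PSD** uses Hann tapers, per-segment mean removal, one-sided
  density scaling (Parseval-consistent within 5% on white noise). The
  relative-power denominator integrates 2-90 Hz — the span of the six
  analysis bands; the denominator range is not stated with the original
  analysis, so it is an explicit, changeable argument
  (`total_range`). Band integration uses closed intervals on the discrete
  grid; inter-band gaps (4-5, 7-8, 12-15, 29-30 Hz) count only toward the
  denominator.
* **Envelopes.** Band-pass filtering and the Hilbert transform are applied
  jointly as one frequency-domain operation (zero negative frequencies,
  double positive in-band ones), which is exactly zero-phase. Before
  correlating, `max(1 s, 3/f_lo)` is trimmed at each edge; at least 10 s
  must remain. AEC is computed over the full continuous (masked) recording
  rather than epoch averages. No leakage orthogonalization is applied — the
  analysis uses plain AEC.
* **AEC degeneracies.** Constant envelopes give correlation 0 with a
  warning; the diagonal is fixed at 0 so node strength is a plain row sum.
* **Peak frequency** ties break toward the lower frequency.
* **Statistics.** The two-group "ANOVA" is one-way ANOVA (F equals the
  squared pooled t); FDR is Benjamini-Hochberg over all ROI x band cells per
  measure (12 x 6). The Bonferroni comparison count `m` for edge tests is a
  declared configuration value (conventionally 11, giving the 0.0045
  threshold) rather than recomputed, because the edge-selection count is a
  reporting convention, not derivable from the data alone. Chi-squared tests
  omit the continuity correction by default (matching the reported
  demographics convention); a flag restores it.
* **ROC.** Midrank Mann-Whitney AUC (identical to the trapezoidal area
  under the empirical curve); the operating point maximizes Youden's J with
  ties broken toward higher specificity. The score definition (left, right,
  or bilateral-sum PCC strength) is a configuration switch because the
  laterality underlying each published AUC is not stated; the benchmark
  pins left PCC for delta and the bilateral sum for gamma2.

## Problem sizes

Simulation-based tests run at reduced scale chosen to preserve the relevant
asymptotics: 200-250 Hz sampling (the gamma2 band tops out at 90 Hz, so
Nyquist is safe), 30-300 s recordings, and 20 cohort replicates of 26 + 27
subjects at 60 s for the structure-recovery check. The envelope-correlation
calibration uses 50 seeds at 300 s against a 10x-duration oracle. The ROC
benchmark uses 3,000-10,000 Monte-Carlo replicates at the full cohort size.

## Known limitations

* The mechanistic generator cannot reach the published absolute node
  strength levels (see the shared-variance budget above); absolute-level
  claims rest on the summary-level generator.
* AEC converges to `r^2` only in the narrowband Gaussian limit; the
  identity degrades slightly for very wide bands relative to their center
  frequency (the envelope-correlation bias at r = 0.7 is below the
  Monte-Carlo tolerance used here).
* No cross-validation or confidence intervals on AUC; the ROC stage
  reports in-sample discrimination, as did the original analysis.
* The source-inversion stage operates on toy-scale leadfields; realistic
  forward models (BEM/overlapping spheres, ~15,000 vertices) are out of
  scope, and the pipeline can start directly from ROI time series.
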