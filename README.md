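# megdmn

Resting-state MEG analysis of the default mode network (DMN) for separating
individuals with **subjective cognitive decline (SCD)** — self-perceived
cognitive worsening with normal neuropsychological performance — from
healthy controls (HC). SCD is a candidate pre-MCI stage, and
electrophysiological connectivity of the DMN, particularly around the
posterior cingulate cortex (PCC), is a promising marker where spectral
power alone does not separate the groups.

The package implements the full analysis chain as composable, tested
functions:

* **Synthetic cohorts** — narrowband Gaussian ROI signals with programmable
  envelope coupling (for a pair with latent signal correlation *r*, the
  amplitude envelope correlation converges to *r*²), two-group cohorts with
  SCD-specific coupling elevations, and summary-level cohorts drawn from
  published group statistics.
* **Preprocessing** — zero-phase notch filters (powerline + harmonics),
  PCA-based signal-space projection of heartbeat/blink artifacts, boolean
  sample masks for rejected segments.
* **Source reconstruction** — depth-weighted minimum-norm estimation,
  `W = R Gᵀ (G R Gᵀ + λ²C)⁻¹` with `λ² = 1/SNR` (0.33 at the default
  SNR 3) and depth weights `R_ii = ‖g_i‖^(−2γ)`, plus ROI averaging.
* **Spectra** — Welch PSD (5-s Hann windows, 50 % overlap) and relative
  band power over delta (2–4), theta (5–7), alpha (8–12), beta (15–29),
  gamma1 (30–59) and gamma2 (60–90 Hz).
* **Connectivity** — amplitude envelope correlation (AEC): Pearson
  correlation of Hilbert envelopes of band-limited ROI signals, 12×12
  adjacency per band, node strength `s_i = Σ_{j≠i} A_ij`.
* **Statistics** — per-cell ANOVA with Benjamini–Hochberg FDR, edge t tests
  at the Bonferroni threshold `α/m` (0.05/11 = 0.0045), demographics
  t/chi-squared tests, one-tailed Spearman correlation.
* **Discrimination** — ROC analysis with the Mann–Whitney AUC
  (`AUC = U/(n₀n₁)`), a Youden-index operating point, and the closed-form
  binormal oracle `AUC = Φ(Δμ/√(σ₀²+σ₁²))`.

See `vignettes/megdmn-methods.Rmd` for the model, parameter choices and
limitations.

## Worked example

Simulate a small two-group cohort (8 + 8 subjects, 60 s at 200 Hz) in which
SCD subjects carry elevated PCC–PCu and PCC–LTC coupling at delta and gamma
bands, then run the whole pipeline:

```r
library(megdmn)
cfg <- run_config(cohort = cohort_config(n_hc = 8, n_scd = 8, fs = 200,
                                         duration = 60, seed = 42))
bundle <- run_pipeline(cfg)
print(bundle)
#> <results_bundle> 16 subjects; 72 strength cells (5 significant)
#>   ROC [delta]: AUC = 0.609 (sens 0.250, spec 1.000)
#>   ROC [gamma1]: AUC = 0.578 (sens 0.375, spec 0.875)
#>   ROC [gamma2]: AUC = 0.438 (sens 0.125, spec 1.000)

ss <- bundle$strength_stats
ss[ss$significant, c("roi", "band", "mean_HC", "mean_SCD", "F", "q")]
#>      roi   band mean_HC mean_SCD     F        q
#> 7  PCC_R  delta  0.0364    0.488  14.3 2.93e-02
#> 55 PCC_R gamma1  0.0192    0.440 224.1 1.88e-08
#> 56 PCu_R gamma1  0.0196    0.409 108.1 1.04e-06
#> 67 PCC_R gamma2  0.0279    0.419 194.2 3.23e-08
#> 68 PCu_R gamma2  0.0446    0.430 337.2 2.46e-09
```

The FDR-corrected strength comparison recovers exactly the planted
structure: right-PCC (and right-PCu) node strength is elevated in SCD at
delta, gamma1 and gamma2 — and at no alpha or beta cell. (At this toy
cohort size the in-sample ROC of a 16-subject cohort is noisy; the
benchmark below uses the full cohort size.)

The headline discrimination result — how well PCC node strength separates
SCD from HC — is benchmarked from the published group summaries (26 HC,
27 SCD), averaging the empirical AUC over 10,000 Monte-Carlo cohorts:

```r
b <- pcc_auc_benchmark("delta", side = "left", reps = 10000, seed = 1)
sprintf("delta left-PCC: mean AUC %.3f (binormal %.3f)", b$mean_auc, b$binormal_auc)
#> "delta left-PCC: mean AUC 0.761 (binormal 0.761)"
```

A command-line entry point for the pipeline is provided at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --config run.yaml
--out results/`).

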