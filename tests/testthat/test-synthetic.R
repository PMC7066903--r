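test_that("narrowband noise is band-pure, standardized and seed-deterministic", {
  x <- make_narrowband_noise(1000, 60, "alpha", seed = 1)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_lt(abs(var(x) - 1), 0.02)
  psd <- welch_psd(roi_ts(matrix(x, 1), 1000))
  rel <- relative_band_power(psd, total_range = c(0.2, 499))
  expect_gte(rel[1, "alpha"], 0.95)

  d <- make_narrowband_noise(1000, 60, "delta", seed = 7)
  expect_lt(abs(var(d) - 1), 0.02)

  expect_identical(make_narrowband_noise(250, 30, "theta", seed = 3),
                   make_narrowband_noise(250, 30, "theta", seed = 3))
  expect_error(make_narrowband_noise(100, 30, "gamma2", seed = 1), "Nyquist")
})

test_that("canonical bands match the analysis definition and Nyquist checks work", {
  b <- canonical_bands()
  edges <- t(vapply(b, function(x) c(x$f_lo, x$f_hi), numeric(2)))
  expect_identical(rownames(edges),
                   c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"))
  expect_equal(unname(edges),
               cbind(c(2, 5, 8, 15, 30, 60), c(4, 7, 12, 29, 59, 90)))
  expect_error(canonical_bands(fs = 100), "Nyquist")
  expect_error(band_spec("bad", 10, 5), "f_lo < f_hi")
})

test_that("pair coupling r yields signal correlation r and AEC near r^2", {
  # r = 1: both ROIs carry the identical narrowband component
  rec1 <- simulate_subject(pair_config(1, duration = 60), "HC", 11)
  A1 <- aec_matrix(rec1$roi_ts, "alpha")
  expect_equal(A1[1, 2], 1.0)

  # uncoupled: AEC near 0 (Monte-Carlo, 3 SE bound)
  a0 <- vapply(1:10, function(s) {
    rec <- simulate_subject(pair_config(0, duration = 60), "HC", s)
    aec_matrix(rec$roi_ts, "alpha")[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(a0)), 3 * sd(a0) / sqrt(10))
  expect_lt(mean(abs(a0)), 0.05)

  # r = 0.7: signal correlation ~0.7, AEC ~0.49
  rec <- simulate_subject(pair_config(0.7), "HC", 5)
  expect_lt(abs(cor(rec$roi_ts$data[1, ], rec$roi_ts$data[2, ]) - 0.7), 0.02)
  expect_lt(abs(aec_matrix(rec$roi_ts, "alpha")[1, 2] - 0.49), 0.05)
})

test_that("conflicting couplings are rejected before mixing weights go imaginary", {
  cfg <- cohort_config(
    n_hc = 2, n_scd = 2, fs = 250, duration = 30,
    roi_names = c("A", "B", "C"), bands = canonical_bands()["alpha"],
    baseline_coupling = coupling_spec("alpha", c("A", "A"), c("B", "C"),
                                      c(0.7, 0.6)),
    scd_extra_coupling = NULL, complaint_model = NULL)
  expect_error(simulate_subject(cfg, "HC", 1), "imaginary")
  expect_error(coupling_spec("alpha", "A", "A", 0.5), "distinct")
  expect_error(coupling_spec("alpha", "A", "B", 1.5), "\\[0, 1\\]")
})

test_that("cohort defaults encode the study conditions and cohorts are deterministic", {
  cc <- cohort_config()
  expect_equal(cc$n_hc, 26)
  expect_equal(cc$n_scd, 27)
  expect_equal(cc$fs, 1000)
  expect_equal(cc$duration, 300)
  expect_length(cc$roi_names, 12)

  cfg <- tiny_cohort_config(n_hc = 2, n_scd = 2, seed = 42)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_length(coh1, 4)
  expect_identical(vapply(coh1, `[[`, character(1), "group"),
                   c("HC", "HC", "SCD", "SCD"))
  expect_identical(coh1[[3]]$roi_ts$data, coh2[[3]]$roi_ts$data)
  expect_equal(nrow(coh1[[1]]$roi_ts$data), 12)

  # recording too short for the Welch windows the analysis assumes
  expect_error(cohort_config(duration = 20), "Welch")
})

test_that("SCD coupling elevation raises delta PCC strength in nearly all replicates", {
  hits <- vapply(1:20, function(s) {
    coh <- simulate_cohort(tiny_cohort_config(n_hc = 4, n_scd = 4, seed = 100 + s))
    st <- cohort_node_strength(coh, canonical_bands()["delta"])
    pcc <- st[st$roi == "PCC_R", ]
    mean(pcc$strength[pcc$group == "SCD"]) > mean(pcc$strength[pcc$group == "HC"])
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("null cohorts (no SCD extra coupling) show no group effect", {
  ps <- vapply(1:6, function(s) {
    coh <- simulate_cohort(tiny_cohort_config(
      n_hc = 4, n_scd = 4, seed = 200 + s, scd_extra_coupling = NULL))
    st <- cohort_node_strength(coh, canonical_bands()["delta"])
    pcc <- st[st$roi == "PCC_R", ]
    t.test(strength ~ group, data = pcc)$p.value
  }, numeric(1))
  expect_lte(sum(ps < 0.01), 1)
})

test_that("SCD subjects report 1-12 complaints tied to gamma1 PCC strength", {
  cfg <- tiny_cohort_config(n_hc = 2, n_scd = 6, seed = 3,
                            complaint_model = c(2, 4, 0.25))
  coh <- simulate_cohort(cfg)
  complaints <- vapply(coh, `[[`, integer(1), "complaint_count")
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_true(all(is.na(complaints[groups == "HC"])))
  scd_c <- complaints[groups == "SCD"]
  expect_true(all(scd_c >= 1 & scd_c <= 12))
})

test_that("summary-level generator reproduces the printed moments", {
  cells <- dmn_strength_summaries()
  expect_equal(nrow(cells), 11)
  one <- cells[cells$band == "delta" & cells$roi == "PCC_L", ]
  cfg <- summary_cohort_config(cells = one, n_hc = 1e5, n_scd = 1e5, seed = 9)
  tab <- simulate_strength_summaries(cfg)
  m_hc <- mean(tab$strength[tab$group == "HC"])
  m_scd <- mean(tab$strength[tab$group == "SCD"])
  expect_lt(abs(m_hc - 3.1) / 3.1, 0.01)
  expect_lt(abs(m_scd - 4.4) / 4.4, 0.01)
  expect_lt(abs(sd(tab$strength[tab$group == "HC"]) - 0.9), 0.02)

  bad <- one; bad$hc_sd <- 0
  expect_error(summary_cohort_config(cells = bad), "positive")

  cfg2 <- summary_cohort_config(n_hc = 10, n_scd = 10, seed = 4)
  expect_identical(simulate_strength_summaries(cfg2),
                   simulate_strength_summaries(cfg2))
})
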