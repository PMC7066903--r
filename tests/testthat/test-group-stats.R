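make_cell_table <- function(values_by_group, roi = "PCC_L", band = "delta") {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(subject = paste0(g, seq_along(v)), group = g, roi = roi,
               band = band, strength = v, stringsAsFactors = FALSE)
  }))
}

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(30)
  tab <- make_cell_table(list(HC = rnorm(12), SCD = rnorm(14, 0.5)))
  res <- compare_cells(tab)
  t <- t.test(strength ~ group, data = tab, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(t)^2, tolerance = 1e-10)
  expect_equal(res$q, res$p)   # single cell: BH leaves p unchanged
  expect_true(all(res$q >= res$p))
})

test_that("BH-FDR agrees with the brute-force step-up definition", {
  p_example <- c(0.001, 0.01, 0.02, 0.03, 0.5, 0.9)
  expect_equal(sum(bh_reject_bruteforce(p_example, 0.05)), 4)
  expect_equal(p.adjust(p_example, "BH") < 0.05,
               bh_reject_bruteforce(p_example, 0.05))

  # exhaustive small grid; step-up rejection p_(k) <= k/m*alpha is
  # equivalent to q <= alpha (inclusive at the boundary)
  grid <- c(0.004, 0.03, 0.2, 0.9)
  for (len in 1:5) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (i in seq_len(nrow(combos))) {
      p <- combos[i, ]
      expect_identical(unname(p.adjust(p, "BH") <= 0.05),
                       unname(bh_reject_bruteforce(p, 0.05)))
    }
  }
})

test_that("cell-wise rejection rate is calibrated under the null", {
  set.seed(31)
  n <- 40; cells <- 12
  base <- matrix(rnorm(n * cells), n, cells)
  rates <- replicate(250, {
    g <- sample(rep(c("HC", "SCD"), each = n / 2))
    tab <- do.call(rbind, lapply(seq_len(cells), function(c)
      data.frame(subject = paste0("s", seq_len(n)), group = g, roi = paste0("R", c),
                 band = "delta", strength = base[, c], stringsAsFactors = FALSE)))
    mean(compare_cells(tab)$p < 0.05)
  })
  rate <- mean(rates)
  se <- sqrt(0.05 * 0.95 / (250 * cells))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("edge comparisons apply the declared Bonferroni threshold", {
  expect_equal(round(0.05 / 11, 4), 0.0045)
  set.seed(32)
  tab <- data.frame(subject = rep(paste0("s", 1:20), 2),
                    group = rep(rep(c("HC", "SCD"), each = 10), 2),
                    roi_i = rep(c("PCC_R", "PCC_R"), each = 20),
                    roi_j = rep(c("PCu_R", "LTC_L"), each = 20),
                    band = "delta", aec = rnorm(40), stringsAsFactors = FALSE)
  res <- compare_edges(tab, m = 11)
  expect_equal(unique(res$threshold), 0.05 / 11)
  expect_equal(round(unique(res$threshold), 4), 0.0045)
  expect_equal(compare_edges(tab, m = 1)$threshold[1], 0.05)
  expect_error(compare_edges(tab, m = 0), "positive")
  expect_identical(res$significant, res$p < 0.05 / 11)
})

test_that("family-wise error of the Bonferroni edge stage stays at or below alpha", {
  set.seed(33)
  n <- 30; m <- 11
  fwer_hits <- replicate(250, {
    g <- rep(c("HC", "SCD"), each = n / 2)
    tab <- do.call(rbind, lapply(seq_len(m), function(e)
      data.frame(subject = paste0("s", seq_len(n)), group = g,
                 roi_i = "PCC_R", roi_j = paste0("R", e), band = "delta",
                 aec = rnorm(n), stringsAsFactors = FALSE)))
    any(compare_edges(tab, m = m)$significant)
  })
  fwer <- mean(fwer_hits)
  expect_lt(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 250))
})

test_that("one-tailed Spearman handles monotone, reversed, tied and constant input", {
  x <- 1:10
  up <- spearman_one_tailed(x, 2 * x + 3)
  expect_equal(up$rho, 1)
  expect_equal(up$p, 0)
  down <- spearman_one_tailed(x, -x)
  expect_equal(down$rho, -1)
  expect_equal(down$p, 1)

  hand <- spearman_one_tailed(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(hand$rho, 0.8)   # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 = 4
  # agrees with the standard estimator
  expect_equal(hand$rho, cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman"))

  expect_warning(res <- spearman_one_tailed(rep(1, 6), 1:6), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_one_tailed(1:3, 1:3), "at least 5")
})

test_that("demographics tests reproduce the published cohort comparisons", {
  # sex 9/17 vs 9/18 by chi-squared without continuity correction
  sex <- data.frame(
    group = c(rep("HC", 26), rep("SCD", 27)),
    sex = c(rep("M", 9), rep("F", 17), rep("M", 9), rep("F", 18)),
    stringsAsFactors = FALSE)
  res <- compare_demographics(sex)
  expect_equal(res$test, "chisq")
  expect_equal(res$p, 0.92, tolerance = 0.005)

  # education 13.27 +/- 2.97 (n=26) vs 12.85 +/- 3.28 (n=27) by summary t-test
  edu <- t_test_summary(13.27, 2.97, 26, 12.85, 3.28, 27)
  expect_equal(edu$p, 0.63, tolerance = 0.005)
  expect_equal(edu$df, 51)

  ident <- data.frame(group = rep(c("HC", "SCD"), each = 5),
                      mmse = rep(c(28, 29, 30, 28, 29), 2))
  expect_equal(compare_demographics(ident)$p, 1.0)

  sparse <- data.frame(group = rep(c("HC", "SCD"), each = 3),
                       rare = c("y", "n", "n", "n", "n", "n"))
  expect_warning(compare_demographics(sparse), "exact test")
})
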