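#' Cell-wise group comparison with FDR correction
#'
#' One-way ANOVA of HC vs SCD for every (ROI, band) cell of a feature table
#' (relative power or node strength), with Benjamini-Hochberg FDR
#' correction across the whole ROI-by-band family. With two groups the
#' ANOVA F statistic equals the square of the pooled two-sample t
#' statistic.
#'
#' @param table long data.frame with columns `subject`, `group`, `roi`,
#'   `band`, and a value column (last column, e.g. `strength`).
#' @param alpha significance level for the FDR-adjusted q-values.
#' @return data.frame (class `stat_table`) with one row per (roi, band):
#'   group means/SDs, F statistic, raw `p`, BH-adjusted `q`, `significant`
#'   flag (`q < alpha`).
#' @export
compare_cells <- function(table, alpha = 0.05) {
  stopifnot(all(c("subject", "group", "roi", "band") %in% names(table)))
  value_col <- setdiff(names(table), c("subject", "group", "roi", "band"))[1]
  groups <- sort(unique(table$group))
  if (length(groups) != 2) stop("expected exactly 2 groups, got ", length(groups))
  if (any(tapply(table$subject, table$group, function(s) length(unique(s))) < 2))
    stop("need at least 2 subjects per group")
  cells <- unique(table[, c("roi", "band")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$roi == cells$roi[i] & table$band == cells$band[i], ]
    v <- sub[[value_col]]
    g <- factor(sub$group, levels = groups)
    m <- tapply(v, g, mean); s <- tapply(v, g, sd)
    ftab <- tryCatch(summary(stats::aov(v ~ g))[[1]],
                     error = function(e) NULL)
    F <- if (!is.null(ftab) && is.finite(ftab$`F value`[1])) ftab$`F value`[1] else NA_real_
    p <- if (!is.null(ftab)) ftab$`Pr(>F)`[1] else NA_real_
    data.frame(roi = cells$roi[i], band = cells$band[i],
               mean_1 = m[[1]], sd_1 = s[[1]], mean_2 = m[[2]], sd_2 = s[[2]],
               F = F, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3:6] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                       paste0("mean_", groups[2]), paste0("sd_", groups[2]))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  class(out) <- c("stat_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Edge-level AEC group comparison with Bonferroni control
#'
#' Two-sample (pooled) t tests of AEC values per edge, flagged significant
#' at the Bonferroni threshold `alpha/m`. The comparison count `m` is a
#' declared input (the analysis convention fixes m = 11, giving the 0.0045
#' threshold at alpha = 0.05) rather than recomputed from the edge list.
#'
#' @param aec_values long data.frame with columns `subject`, `group`,
#'   `roi_i`, `roi_j`, `band`, `aec`.
#' @param m declared number of comparisons (> 0).
#' @param alpha family-wise level.
#' @return data.frame (class `edge_comparison`) with per-edge group means,
#'   raw `p`, the Bonferroni `threshold`, and `significant` flag
#'   (`p < alpha/m`).
#' @export
compare_edges <- function(aec_values, m = 11, alpha = 0.05) {
  if (m <= 0) stop("comparison count m must be positive")
  stopifnot(all(c("subject", "group", "roi_i", "roi_j", "band", "aec") %in%
                  names(aec_values)))
  groups <- sort(unique(aec_values$group))
  stopifnot(length(groups) == 2)
  threshold <- alpha / m
  edges <- unique(aec_values[, c("roi_i", "roi_j", "band")])
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    sub <- aec_values[aec_values$roi_i == edges$roi_i[i] &
                      aec_values$roi_j == edges$roi_j[i] &
                      aec_values$band == edges$band[i], ]
    v1 <- sub$aec[sub$group == groups[1]]
    v2 <- sub$aec[sub$group == groups[2]]
    p <- stats::t.test(v1, v2, var.equal = TRUE)$p.value
    data.frame(roi_i = edges$roi_i[i], roi_j = edges$roi_j[i],
               band = edges$band[i], mean_1 = mean(v1), mean_2 = mean(v2),
               p = p, threshold = threshold, significant = p < threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- paste0("mean_", groups)
  class(out) <- c("edge_comparison", "data.frame")
  out
}

#' One-tailed Spearman correlation
#'
#' Rank correlation with average ranks for ties and a one-tailed p-value
#' for positive association, via the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom. Used to
#' test whether higher PCC node strength goes with more cognitive
#' complaints.
#'
#' @param x,y numeric vectors of equal length, n >= 5; ties allowed.
#' @return list with `rho`, `p` (one-tailed, positive association), `n`.
#' @export
spearman_one_tailed <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete observations, got ", n)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman rho is undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    if (rho > 0) 0 else 1
  } else {
    stats::pt(rho * sqrt((n - 2) / (1 - rho^2)), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-sample pooled t test from summary statistics
#'
#' Compares two groups from reported mean, SD and n (as in a demographics
#' table), using the pooled-variance t statistic on `n1 + n2 - 2` degrees
#' of freedom.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Demographics comparison table
#'
#' Per-variable group comparison in the style of a cohort demographics
#' table: numeric variables by independent two-sample t test (pooled
#' variance), categorical variables by chi-squared test without continuity
#' correction (a correction flag is available). A warning recommends an
#' exact test when any expected cell count falls below 1.
#'
#' @param data data.frame of per-subject rows; one column named by `group`
#'   holds the group labels, every other column is compared.
#' @param group name of the grouping column (default `"group"`).
#' @param correct logical; apply Yates continuity correction in 2x2
#'   chi-squared tests (default `FALSE`).
#' @return data.frame with columns `variable`, `test`, `p`.
#' @export
compare_demographics <- function(data, group = "group", correct = FALSE) {
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  stopifnot(nlevels(g) == 2)
  vars <- setdiff(names(data), group)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- stats::t.test(x ~ g, var.equal = TRUE)$p.value
      data.frame(variable = v, test = "t", p = p, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x), g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 1))
        warning("variable '", v, "' has expected cell counts < 1; ",
                "an exact test is recommended")
      p <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
      data.frame(variable = v, test = "chisq", p = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
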