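#' ROC analysis of a group-discriminating score
#'
#' Empirical ROC curve and AUC for discriminating SCD from HC, with the SCD
#' group as the positive class (higher score = more SCD-like). The AUC is
#' computed through the Mann-Whitney U statistic with midrank tie handling,
#' `AUC = U / (n0 * n1)`, which equals the trapezoidal area under the
#' empirical curve. The reported operating point maximizes the Youden index
#' `J = sensitivity + specificity - 1`; ties are broken toward higher
#' specificity (higher threshold). A subject is called positive when the
#' score is at or above the threshold.
#'
#' @param scores numeric score per subject (e.g. PCC node strength).
#' @param labels group per subject: logical, 0/1, or factor/character where
#'   `positive` names the positive class.
#' @param positive label of the positive class (default `"SCD"`; ignored
#'   for logical/numeric labels).
#' @return An object of class `roc_result`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `criterion`, and `curve` (data.frame of
#'   `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
roc_auc <- function(scores, labels, positive = "SCD") {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels == 1
         else labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(c) mean(scores[pos] >= c), numeric(1))
  fpr <- vapply(thr, function(c) mean(scores[!pos] >= c), numeric(1))
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  J <- tpr + (1 - fpr) - 1
  best <- which(J == max(J))
  best <- best[which.max(thr[best])]   # tie -> higher threshold = higher specificity
  structure(list(auc = auc, sensitivity = tpr[best], specificity = 1 - fpr[best],
                 threshold = thr[best], criterion = "youden", curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f; sensitivity = %.3f, specificity = %.3f at threshold %.3g (%s)\n",
              x$auc, x$sensitivity, x$specificity, x$threshold, x$criterion))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Closed-form binormal AUC
#'
#' For Gaussian score distributions N(mu0, sd0) in controls and
#' N(mu1, sd1) in patients, the AUC is `pnorm((mu1 - mu0) /
#' sqrt(sd0^2 + sd1^2))`. Serves as the analytic oracle for cohorts drawn
#' from summary statistics.
#'
#' @param mu0,sd0 control mean and SD.
#' @param mu1,sd1 patient mean and SD.
#' @return AUC in `[0, 1]`.
#' @examples
#' binormal_auc(3.1, 0.9, 4.4, 1.6)  # ~0.76
#' @export
binormal_auc <- function(mu0, sd0, mu1, sd1) {
  stopifnot(sd0 > 0, sd1 > 0)
  stats::pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Monte-Carlo ROC benchmark from printed node-strength summaries
#'
#' Repeatedly draws two-group cohorts of PCC node strengths from the
#' reported group means and SDs ([dmn_strength_summaries()]) and averages
#' the empirical AUC over replicates. `side = "left"` or `"right"` scores
#' subjects by the corresponding PCC strength; `side = "bilateral"` draws
#' left and right independently per subject and scores by their sum.
#'
#' @param band `"delta"`, `"gamma1"` or `"gamma2"` (bands with reported PCC
#'   summaries).
#' @param side `"left"`, `"right"` or `"bilateral"`.
#' @param n_hc,n_scd group sizes per replicate.
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list with `mean_auc`, `sd_auc` (across replicates), `reps`,
#'   `binormal_auc` (the analytic value for the score distribution).
#' @export
pcc_auc_benchmark <- function(band = c("delta", "gamma1", "gamma2"),
                              side = c("left", "bilateral", "right"),
                              n_hc = 26, n_scd = 27, reps = 10000, seed = 1) {
  band <- match.arg(band)
  side <- match.arg(side)
  cells <- dmn_strength_summaries()
  cl <- cells[cells$band == band & cells$roi == "PCC_L", ]
  cr <- cells[cells$band == band & cells$roi == "PCC_R", ]
  stopifnot(nrow(cl) == 1, nrow(cr) == 1)
  n <- n_hc + n_scd
  pos <- c(rep(FALSE, n_hc), rep(TRUE, n_scd))
  draw <- function(cell) {
    m <- ifelse(pos, cell$scd_mean, cell$hc_mean)
    s <- ifelse(pos, cell$scd_sd, cell$hc_sd)
    matrix(rnorm(reps * n, mean = rep(m, each = reps), sd = rep(s, each = reps)),
           reps, n)
  }
  with_seed(seed, {
    scores <- switch(side,
      left = draw(cl),
      right = draw(cr),
      bilateral = draw(cl) + draw(cr))
    n1 <- sum(pos)
    aucs <- apply(scores, 1, function(x)
      (sum(rank(x)[pos]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1)))
    analytic <- switch(side,
      left = binormal_auc(cl$hc_mean, cl$hc_sd, cl$scd_mean, cl$scd_sd),
      right = binormal_auc(cr$hc_mean, cr$hc_sd, cr$scd_mean, cr$scd_sd),
      bilateral = binormal_auc(cl$hc_mean + cr$hc_mean,
                               sqrt(cl$hc_sd^2 + cr$hc_sd^2),
                               cl$scd_mean + cr$scd_mean,
                               sqrt(cl$scd_sd^2 + cr$scd_sd^2)))
    list(mean_auc = mean(aucs), sd_auc = sd(aucs), reps = reps,
         binormal_auc = analytic)
  })
}
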