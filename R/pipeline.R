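#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters in one structure. Can be built
#' directly or loaded from a YAML file whose top-level keys match the
#' arguments (nested keys map to the list arguments).
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort, or a
#'   directory of subject files written by a previous run (with
#'   `manifest.json`).
#' @param notch `NULL` to skip powerline filtering, or a list with `base`
#'   (Hz) and optional `q`.
#' @param mask_intervals list of rejected `[start, stop]` sample intervals
#'   applied to every subject (or `NULL`).
#' @param bands list of [band_spec()]s.
#' @param welch list with `window_s`, `overlap`.
#' @param stats list with `alpha` (cell-wise FDR level) and `m` (declared
#'   Bonferroni comparison count for edge tests).
#' @param roc list with `roi` (default `"PCC"`), `side` (`"left"`,
#'   `"right"` or `"bilateral"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       notch = NULL,
                       mask_intervals = NULL,
                       bands = canonical_bands(),
                       welch = list(window_s = 5, overlap = 0.5),
                       stats = list(alpha = 0.05, m = 11),
                       roc = list(roi = "PCC", side = "left")) {
  structure(list(cohort = cohort, notch = notch,
                 mask_intervals = mask_intervals, bands = bands,
                 welch = welch, stats = stats, roc = roc),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- if (is.null(y$bands)) canonical_bands()
           else lapply(y$bands, function(b) band_spec(b$name, b$f_lo, b$f_hi))
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$roi_names)) cohort_args$roi_names <- unlist(cohort_args$roi_names)
  cohort_args$bands <- bands
  cfg <- run_config(cohort = do.call(cohort_config, cohort_args),
                    notch = y$notch, mask_intervals = y$mask_intervals,
                    bands = bands)
  if (!is.null(y$welch)) cfg$welch <- utils::modifyList(cfg$welch, y$welch)
  if (!is.null(y$stats)) cfg$stats <- utils::modifyList(cfg$stats, y$stats)
  if (!is.null(y$roc)) cfg$roc <- utils::modifyList(cfg$roc, y$roc)
  cfg
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
}

#' Run the full resting-state DMN analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> Welch spectra ->
#' envelope connectivity -> group statistics -> ROC, writing every stage's
#' output as CSV/JSON under `out_dir` along with a reproducibility
#' manifest (configuration, seeds, package version). A rerun with the same
#' configuration reproduces the outputs bit-identically. Stage failures
#' abort with the stage name (and subject id where applicable).
#'
#' @param config a [run_config()] or path to a YAML run configuration.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   all file output.
#' @return A `results_bundle` list: `cohort`, `band_power` (long
#'   data.frame), `strength` (long data.frame), `edge_aec`, `power_stats`,
#'   `strength_stats`, `edge_stats`, `roc` (per band with a significant PCC
#'   strength difference), `complaint_assoc`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("simulate", {
    if (inherits(config$cohort, "cohort_config")) simulate_cohort(config$cohort)
    else read_cohort(config$cohort)
  })
  n_samples <- ncol(cohort[[1]]$roi_ts$data)
  mask <- if (is.null(config$mask_intervals)) NULL
          else mask_from_intervals(n_samples, config$mask_intervals)

  if (!is.null(config$notch)) cohort <- stage("preprocess", {
    lapply_cohort(cohort, function(rec) {
      rec$roi_ts <- notch_filter(rec$roi_ts, base = config$notch$base,
                                 q = config$notch$q %||% 30)
      rec
    })
  })

  band_power <- stage("spectra", {
    rows <- lapply(cohort, function(rec) {
      psd <- welch_psd(rec$roi_ts, window_s = config$welch$window_s,
                       overlap = config$welch$overlap, mask = mask)
      bp <- relative_band_power(psd, config$bands)
      data.frame(subject = rec$subject_id, group = rec$group,
                 roi = rep(rownames(bp), ncol(bp)),
                 band = rep(colnames(bp), each = nrow(bp)),
                 power = as.vector(unclass(bp)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  # AEC matrices are computed once per subject and band, then reused for
  # node strength and edge-level tests
  aecs <- stage("connect", lapply_cohort(cohort, function(rec)
    lapply(config$bands, function(b) aec_matrix(rec$roi_ts, b, mask = mask))))

  strength <- stage("connect", {
    rows <- mapply(function(rec, Ab) {
      per_band <- mapply(function(A, b) {
        s <- node_strength(A)
        data.frame(subject = rec$subject_id, group = rec$group,
                   roi = names(s), band = b$name, strength = unname(s),
                   stringsAsFactors = FALSE)
      }, Ab, config$bands, SIMPLIFY = FALSE)
      do.call(rbind, per_band)
    }, cohort, aecs, SIMPLIFY = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  power_stats <- stage("stats", compare_cells(band_power, config$stats$alpha))
  strength_stats <- stage("stats", compare_cells(strength, config$stats$alpha))

  # edge tests: AEC edges incident to ROIs with significant strength
  # differences, per band (Bonferroni with declared m)
  sig <- strength_stats[strength_stats$significant, ]
  edge_aec <- NULL; edge_stats <- NULL
  if (nrow(sig) > 0) {
    band_names <- vapply(config$bands, `[[`, character(1), "name")
    edge_aec <- stage("connect", {
      rows <- mapply(function(rec, Ab) {
        per_band <- lapply(unique(sig$band), function(bn) {
          A <- Ab[[match(bn, band_names)]]
          rois <- rownames(rec$roi_ts$data)
          idx <- which(upper.tri(A), arr.ind = TRUE)
          data.frame(subject = rec$subject_id, group = rec$group,
                     roi_i = rois[idx[, 1]], roi_j = rois[idx[, 2]],
                     band = bn, aec = A[idx], stringsAsFactors = FALSE)
        })
        do.call(rbind, per_band)
      }, cohort, aecs, SIMPLIFY = FALSE)
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    })
    keep <- mapply(function(ri, rj, b)
      any(sig$band == b & (sig$roi == ri | sig$roi == rj)),
      edge_aec$roi_i, edge_aec$roi_j, edge_aec$band)
    edge_stats <- stage("stats",
      compare_edges(edge_aec[keep, ], m = config$stats$m, alpha = config$stats$alpha))
  }

  roc <- stage("roc", {
    roc_bands <- unique(sig$band[grepl(paste0("^", config$roc$roi), sig$roi)])
    out <- lapply(roc_bands, function(b) {
      wide <- pcc_scores(strength, b, config$roc$roi, config$roc$side)
      roc_auc(wide$score, wide$group)
    })
    names(out) <- roc_bands
    out
  })

  complaint_assoc <- stage("stats", {
    complaints <- vapply(cohort, `[[`, integer(1), "complaint_count")
    scd <- vapply(cohort, `[[`, character(1), "group") == "SCD"
    if (all(is.na(complaints[scd])) || sum(scd) < 5) NULL
    else {
      wide <- pcc_scores(strength, "gamma1", "PCC", "bilateral")
      s <- wide$score[match(vapply(cohort[scd], `[[`, character(1), "subject_id"),
                            wide$subject)] / 2
      spearman_one_tailed(s, complaints[scd])
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("megdmn")),
    seed = if (inherits(config$cohort, "cohort_config")) config$cohort$seed else NA,
    subject_seeds = if (inherits(config$cohort, "cohort_config"))
      vapply(seq_along(cohort), function(i)
        subject_seed(config$cohort$seed, i), integer(1)) else NULL,
    subjects = data.frame(
      subject = vapply(cohort, `[[`, character(1), "subject_id"),
      group = vapply(cohort, `[[`, character(1), "group"),
      complaint_count = vapply(cohort, `[[`, integer(1), "complaint_count")),
    config = serialize_config(config))

  bundle <- structure(list(cohort = cohort, band_power = band_power,
                           strength = strength, edge_aec = edge_aec,
                           power_stats = power_stats,
                           strength_stats = strength_stats,
                           edge_stats = edge_stats, roc = roc,
                           complaint_assoc = complaint_assoc,
                           manifest = manifest),
                      class = "results_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

lapply_cohort <- function(cohort, f) {
  out <- lapply(cohort, function(rec)
    tryCatch(f(rec), error = function(e)
      stop("subject ", rec$subject_id, ": ", conditionMessage(e), call. = FALSE)))
  attributes(out) <- attributes(cohort)
  out
}

# per-subject PCC score for ROC: left/right strength or bilateral sum
pcc_scores <- function(strength, band, roi = "PCC", side = "left") {
  rois <- switch(side,
    left = paste0(roi, "_L"), right = paste0(roi, "_R"),
    bilateral = paste0(roi, c("_L", "_R")),
    stop("unknown ROC side '", side, "'"))
  sub <- strength[strength$band == band & strength$roi %in% rois, ]
  agg <- stats::aggregate(strength ~ subject + group, data = sub, sum)
  data.frame(subject = agg$subject, group = agg$group, score = agg$strength,
             stringsAsFactors = FALSE)
}

serialize_config <- function(config) {
  list(
    cohort = if (inherits(config$cohort, "cohort_config"))
      config$cohort[c("n_hc", "n_scd", "fs", "duration", "roi_names",
                      "noise_floor", "seed")] else config$cohort,
    notch = config$notch, mask_intervals = config$mask_intervals,
    bands = lapply(config$bands, unclass),
    welch = config$welch, stats = config$stats, roc = config$roc)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d subjects; %d strength cells (%d significant)\n",
              length(x$cohort), nrow(x$strength_stats),
              sum(x$strength_stats$significant)))
  if (length(x$roc))
    for (b in names(x$roc))
      cat(sprintf("  ROC [%s]: AUC = %.3f (sens %.3f, spec %.3f)\n", b,
                  x$roc[[b]]$auc, x$roc[[b]]$sensitivity, x$roc[[b]]$specificity))
  invisible(x)
}

# Write every bundle table plus the manifest under out_dir.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(bundle$band_power, p("band_power.csv"), row.names = FALSE)
  utils::write.csv(bundle$strength, p("node_strength.csv"), row.names = FALSE)
  utils::write.csv(bundle$power_stats, p("power_stats.csv"), row.names = FALSE)
  utils::write.csv(bundle$strength_stats, p("strength_stats.csv"), row.names = FALSE)
  if (!is.null(bundle$edge_stats))
    utils::write.csv(bundle$edge_stats, p("edge_stats.csv"), row.names = FALSE)
  if (length(bundle$roc)) {
    roc_json <- lapply(bundle$roc, function(r)
      r[c("auc", "sensitivity", "specificity", "threshold", "criterion")])
    jsonlite::write_json(roc_json, p("roc.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Write / read a simulated cohort as delimited text
#'
#' One CSV per subject (samples x ROI columns with an `fs` header line, see
#' [write_roi_timeseries()]) plus a JSON manifest recording subject id,
#' group, seed and complaint count.
#'
#' @param cohort a `meg_cohort`.
#' @param dir target directory.
#' @return `write_cohort()` the directory (invisibly); `read_cohort()` a
#'   `meg_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(cohort, "config")
  manifest <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    file <- paste0(rec$subject_id, ".csv")
    write_roi_timeseries(rec$roi_ts, file.path(dir, file))
    list(subject_id = rec$subject_id, group = rec$group, file = file,
         seed = if (!is.null(config)) subject_seed(config$seed, i) else NA,
         complaint_count = if (is.na(rec$complaint_count)) NULL
                           else rec$complaint_count)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = FALSE)
  subjects <- lapply(manifest, function(m) {
    cc <- m$complaint_count
    structure(list(subject_id = m$subject_id, group = m$group,
                   roi_ts = read_roi_timeseries(file.path(dir, m$file)),
                   complaint_count = if (length(cc)) as.integer(cc) else NA_integer_),
              class = "subject_record")
  })
  structure(subjects, class = "meg_cohort")
}
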