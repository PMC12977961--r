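#' Pipeline configuration
#'
#' Collects the paths, thresholds and seed driving [run_pipeline()]. The
#' defaults are the analysis constants used throughout the package: atlas
#' binarization at 50% probability, probability-map trimming at 0.01,
#' 1 mm prior-mask dilation, an 80% reliable-change confidence interval and
#' a 0.05 Welch gate for harmonization.
#'
#' @param data_dir directory holding the per-subject files and
#'   `manifest.csv` (as written by [gen_cohort()]).
#' @param out_dir output directory for stage tables and the report.
#' @param manifest path to the cohort manifest CSV; defaults to
#'   `manifest.csv` inside `data_dir`.
#' @param atlas_threshold disconnection-probability binarization threshold.
#' @param prob_threshold bundle probability-map retention threshold.
#' @param dilation_mm prior-mask dilation radius in mm.
#' @param rci_confidence reliable-change confidence level.
#' @param harmonization_alpha Welch-gate significance level.
#' @param eb empirical-Bayes flag for harmonization.
#' @param seed seed recorded in the provenance block.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            manifest = file.path(data_dir, "manifest.csv"),
                            atlas_threshold = 0.5,
                            prob_threshold = 0.01,
                            dilation_mm = 1,
                            rci_confidence = 0.80,
                            harmonization_alpha = 0.05,
                            eb = TRUE,
                            seed = 1L) {
  stopifnot(atlas_threshold >= 0, atlas_threshold <= 1,
            prob_threshold >= 0, prob_threshold <= 1,
            dilation_mm >= 0,
            rci_confidence > 0, rci_confidence < 1,
            harmonization_alpha > 0, harmonization_alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

read_manifest <- function(config) {
  if (!file.exists(config$manifest))
    stop("manifest not found: ", config$manifest, call. = FALSE)
  utils::read.csv(config$manifest, stringsAsFactors = FALSE)
}

subject_file <- function(config, man, i, col, stage) {
  f <- file.path(config$data_dir, man[[col]][i])
  if (!file.exists(f))
    stop("stage '", stage, "' halted: file ", man[[col]][i],
         " for subject ", man$subject_id[i], " not found", call. = FALSE)
  f
}

#' Per-subject metric extraction stage
#'
#' For every subject in the manifest: reads the bundle and resection mask,
#' computes the streamline transection percentage, the bundle mask (via the
#' probability-map threshold), its volume normalized to intracranial volume,
#' and — when FA/MD maps are present — median tract FA and MD.
#'
#' @param config a [pipeline_config()].
#' @return data.frame, one row per subject; also written to
#'   `metrics.csv` in `out_dir`.
#' @export
stage_metrics <- function(config) {
  man <- read_manifest(config)
  icv_path <- file.path(config$data_dir, "icv.nii.gz")
  icv <- if (file.exists(icv_path)) read_mask(icv_path) else NULL
  has_maps <- all(c("fa_file", "md_file") %in% names(man))
  rows <- lapply(seq_len(nrow(man)), function(i) {
    t0 <- proc.time()[["elapsed"]]
    bundle <- read_tractogram(subject_file(config, man, i, "bundle_file",
                                           "metrics"))
    mask <- read_mask(subject_file(config, man, i, "resection_file",
                                   "metrics"))
    tf <- transection_fraction(bundle, mask)
    pmap <- bundle_probability_map(bundle, mask)
    bmask <- threshold_probability_map(pmap, config$prob_threshold)
    nvol <- if (is.null(icv)) NA_real_ else normalized_tract_volume(bmask, icv)
    med_fa <- med_md <- NA_real_
    if (has_maps) {
      fa <- read_volume(subject_file(config, man, i, "fa_file", "metrics"))
      md <- read_volume(subject_file(config, man, i, "md_file", "metrics"))
      med_fa <- tract_median_metric(bundle, fa)
      med_md <- tract_median_metric(bundle, md)
    }
    message(sprintf("metrics %s percent_cut=%.1f %.2fs", man$subject_id[i],
                    tf$percent_cut, proc.time()[["elapsed"]] - t0))
    data.frame(subject_id = man$subject_id[i],
               percent_cut = tf$percent_cut,
               n_pre = tf$n_pre, n_post = tf$n_post,
               normalized_volume = nvol,
               median_fa = med_fa, median_md = med_md,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rescaled_volume <- if (all(is.na(out$normalized_volume))) NA_real_ else
    cohort_rescale(out$normalized_volume)
  utils::write.csv(out, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  out
}

#' Cohort atlas stage
#'
#' Builds the probabilistic tract atlas from every subject's thresholded
#' bundle mask and writes it as NIfTI.
#'
#' @param config a [pipeline_config()].
#' @return the `probabilistic_atlas`; written to `atlas.nii.gz`.
#' @export
stage_atlas <- function(config) {
  man <- read_manifest(config)
  masks <- lapply(seq_len(nrow(man)), function(i) {
    bundle <- read_tractogram(subject_file(config, man, i, "bundle_file",
                                           "atlas"))
    mask <- read_mask(subject_file(config, man, i, "resection_file", "atlas"))
    threshold_probability_map(bundle_probability_map(bundle, mask),
                              config$prob_threshold)
  })
  atlas <- build_atlas(masks)
  write_volume(atlas, file.path(config$out_dir, "atlas.nii.gz"))
  atlas
}

#' Atlas-based disconnection stage
#'
#' Scores every subject's resection mask against the cohort atlas with the
#' maximum-probability rule and binarizes at the configured threshold.
#'
#' @param config a [pipeline_config()].
#' @param atlas the atlas from [stage_atlas()]; recomputed when missing.
#' @return data.frame per subject; written to `disconnection.csv`.
#' @export
stage_disconnect <- function(config, atlas = NULL) {
  man <- read_manifest(config)
  if (is.null(atlas)) atlas <- stage_atlas(config)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    mask <- read_mask(subject_file(config, man, i, "resection_file",
                                   "disconnect"))
    dr <- disconnection_probability(mask, atlas, config$atlas_threshold)
    message(sprintf("disconnect %s p=%.2f", man$subject_id[i],
                    dr$probability))
    data.frame(subject_id = man$subject_id[i],
               probability = dr$probability,
               disconnected = dr$disconnected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(config$out_dir, "disconnection.csv"),
                   row.names = FALSE)
  out
}

#' Harmonization stage
#'
#' Welch-gates the tract metrics for scanner-batch differences and removes
#' significant batch effects with the ComBat-style adjustment, preserving
#' age covariates. Adjustment parameters are serialized to a JSON sidecar.
#'
#' @param config a [pipeline_config()].
#' @param metrics the [stage_metrics()] table; recomputed when missing.
#' @return the metrics table with harmonized columns; written to
#'   `metrics_harmonized.csv` (+ `harmonization.json`).
#' @export
stage_harmonize <- function(config, metrics = NULL) {
  man <- read_manifest(config)
  if (is.null(metrics)) metrics <- stage_metrics(config)
  feat_cols <- intersect(c("percent_cut", "normalized_volume",
                           "median_fa", "median_md"), names(metrics))
  feat_cols <- feat_cols[vapply(feat_cols,
                                function(cn) !anyNA(metrics[[cn]]),
                                logical(1))]
  out <- metrics
  if (length(feat_cols) && length(unique(man$scanner_batch)) == 2L) {
    hz <- harmonize_features(as.matrix(metrics[feat_cols]),
                             man$scanner_batch,
                             covariates = cbind(age_surgery = man$age_surgery,
                                                age_onset = man$age_onset),
                             alpha = config$harmonization_alpha,
                             eb = config$eb)
    out[feat_cols] <- as.data.frame(hz$adjusted)
    side <- list(p_values = as.list(hz$p_values),
                 harmonized_features = hz$harmonized_features,
                 alpha = config$harmonization_alpha, eb = config$eb)
    if (!is.null(hz$adjustment))
      side$parameters <- list(gamma_star = hz$adjustment$gamma_star,
                              delta_star = hz$adjustment$delta_star,
                              var_pooled = hz$adjustment$var_pooled)
    jsonlite::write_json(side, file.path(config$out_dir,
                                         "harmonization.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  utils::write.csv(out, file.path(config$out_dir, "metrics_harmonized.csv"),
                   row.names = FALSE)
  out
}

#' Reliable-change stage
#'
#' Per task and postoperative timepoint, regresses the change score on age
#' at surgery, resection volume and the preoperative score with MM-robust
#' regression, and classifies residuals at the configured confidence level.
#'
#' @param config a [pipeline_config()].
#' @return data.frame (subject, task, timepoint, residual, classification);
#'   written to `rci.csv`.
#' @export
stage_rci <- function(config) {
  man <- read_manifest(config)
  long <- cohort_long(man)
  out <- list()
  for (task in unique(long$task)) {
    for (tp in levels(long$timepoint)) {
      d <- long[long$task == task & long$timepoint == tp &
                  !is.na(long$change_z), , drop = FALSE]
      if (nrow(d) < 5L) next
      fit <- robust_fit(change_z ~ age_surgery + resection_volume + pre_z, d)
      cls <- rci_classify(fit, confidence = config$rci_confidence)
      out[[paste(task, tp)]] <- data.frame(subject_id = d$subject_id,
                                           task = task, timepoint = tp,
                                           residual = cls$residual,
                                           classification = cls$classification,
                                           stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  utils::write.csv(res, file.path(config$out_dir, "rci.csv"),
                   row.names = FALSE)
  res
}

#' Mixed-model stage
#'
#' Per task: fits the confound-only and confound-plus-transection linear
#' mixed models on the change scores, compares them with a likelihood ratio
#' test, and fits the logistic mixed model of RCI decline on atlas-based
#' disconnection. Estimates and test statistics are written as CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param metrics harmonized metrics table (from [stage_harmonize()]).
#' @param disconnection the [stage_disconnect()] table.
#' @param rci the [stage_rci()] table.
#' @return list of fitted models and LRTs per task; summary written to
#'   `models.csv` and `models.json`.
#' @export
stage_fit <- function(config, metrics = NULL, disconnection = NULL,
                      rci = NULL) {
  man <- read_manifest(config)
  if (is.null(metrics)) metrics <- stage_harmonize(config)
  if (is.null(disconnection)) disconnection <- stage_disconnect(config)
  if (is.null(rci)) rci <- stage_rci(config)
  man2 <- man
  man2$percent_cut <- metrics$percent_cut[match(man$subject_id,
                                                metrics$subject_id)]
  long <- cohort_long(man2)
  long <- merge(long, disconnection, by = "subject_id", sort = FALSE)
  long <- merge(long,
                rci[, c("subject_id", "task", "timepoint", "classification")],
                by = c("subject_id", "task", "timepoint"),
                all.x = TRUE, sort = FALSE)
  long$rci_decline <- as.integer(long$classification == -1L)

  fits <- list()
  summ <- list()
  for (task in unique(long$task)) {
    d <- long[long$task == task, , drop = FALSE]
    null_fit <- fit_change_lmm(d)
    full_fit <- fit_change_lmm(d, tract_term = "transection")
    lrt <- likelihood_ratio_test(null_fit, full_fit)
    glmm <- NULL
    dd <- d[!is.na(d$rci_decline), , drop = FALSE]
    if (length(unique(dd$rci_decline)) == 2L)
      glmm <- tryCatch(suppressWarnings(
        fit_binary_glmm(dd, outcome = "rci_decline")),
        error = function(e) NULL)
    fits[[task]] <- list(null = null_fit, full = full_fit, lrt = lrt,
                         glmm = glmm)
    est <- full_fit$coefficients["transection", "Estimate"]
    se <- full_fit$coefficients["transection", "Std. Error"]
    summ[[task]] <- data.frame(task = task,
                               transection_estimate = est,
                               transection_se = se,
                               chi_sq = lrt$chi_sq, df = lrt$df, p = lrt$p,
                               glmm_logodds = if (is.null(glmm)) NA_real_ else
                                 glmm$coefficients["disconnected", "Estimate"],
                               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, summ)
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(config$out_dir, "models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(fits, function(f) {
    list(null = list(logLik = f$null$logLik,
                     converged = f$null$converged),
         full = list(estimates = as.data.frame(f$full$coefficients),
                     logLik = f$full$logLik,
                     converged = f$full$converged),
         lrt = unclass(f$lrt))
  }), file.path(config$out_dir, "models.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fits
}

#' Run the full disconnectome pipeline
#'
#' Stages, in order: per-subject metric extraction, cohort atlas and
#' atlas-based disconnection, harmonization gate, reliable-change
#' classification, mixed models with likelihood-ratio comparison, and a
#' report with a provenance block (config hash + seed). Every stage writes
#' its table to `out_dir`; rerunning with the same configuration reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-subject log lines.
#' @return a `pipeline_report` list with all stage tables, the model fits
#'   and the provenance block; also written to `report.json`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  run <- function(expr) if (quiet) suppressMessages(expr) else expr

  metrics <- run(stage_metrics(config))
  atlas <- run(stage_atlas(config))
  disconnection <- run(stage_disconnect(config, atlas))
  harmonized <- run(stage_harmonize(config, metrics))
  rci <- run(stage_rci(config))
  fits <- run(stage_fit(config, harmonized, disconnection, rci))

  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_json)),
                     seed = config$seed,
                     n_subjects = nrow(metrics),
                     package_version =
                       as.character(utils::packageVersion("disconnectr")))
  report <- structure(list(metrics = metrics,
                           disconnection = disconnection,
                           harmonized = harmonized,
                           rci = rci,
                           models = fits,
                           provenance = provenance),
                      class = "pipeline_report")
  jsonlite::write_json(list(provenance = provenance,
                            disconnection_rate = mean(disconnection$disconnected),
                            mean_percent_cut = mean(metrics$percent_cut),
                            rci_decline_rate = mean(rci$classification == -1L)),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects; disconnected %.0f%%; mean cut %.1f%%\n",
              x$provenance$n_subjects,
              100 * mean(x$disconnection$disconnected),
              mean(x$metrics$percent_cut)))
  invisible(x)
}
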