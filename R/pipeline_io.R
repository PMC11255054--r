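# Orchestration and file formats: NIfTI loading with grid validation, the
# end-to-end cohort run, and report/table writers.

#' A 4D DSC series with its acquisition metadata
#'
#' @param data 4D numeric array (x, y, z, dynamics).
#' @param acq An [acquisition_params()].
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(data, acq) {
  pq_check(length(dim(data)) == 4, "pq_format_error",
           "DSC series must be a 4D array")
  pq_check(dim(data)[4] == acq$n_dynamics, "pq_format_error",
           "series has %d dynamics but acquisition says %d",
           dim(data)[4], acq$n_dynamics)
  structure(list(data = data, acq = acq), class = "dsc_series")
}

# write one simulated patient as NIfTI triplet
write_patient_nifti <- function(pat, dir) {
  acq <- pat$dsc$acq
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(-1, 1.75, 1.75, 5, acq$tr, 0, 0, 0)))
  img <- RNifti::asNifti(pat$dsc$data, reference = hdr)
  RNifti::writeNifti(img, file.path(dir, "dsc.nii.gz"))
  hdr3 <- RNifti::niftiHeader(list(pixdim = c(-1, 1.75, 1.75, 5, 0, 0, 0, 0)))
  RNifti::writeNifti(RNifti::asNifti(pat$tumor_mask, reference = hdr3),
                     file.path(dir, "tumor_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(pat$nawm_mask, reference = hdr3),
                     file.path(dir, "nawm_mask.nii.gz"))
  invisible(dir)
}

#' Load one patient's DSC series and masks from NIfTI
#'
#' Validates that the series is 4D, that both masks are 3D on the same
#' spatial grid, and that the affines agree within `1e-4`. The repetition
#' time is taken from the series header (`pixdim[4]`) unless overridden via
#' `acq`.
#'
#' @param dsc_path,tumor_path,nawm_path NIfTI file paths.
#' @param acq Optional [acquisition_params()] overriding header-derived
#'   timing (TE is never stored in NIfTI and defaults from
#'   [acquisition_params()]).
#' @param te Echo time in seconds when `acq` is not given.
#' @return A list with `dsc` (a `dsc_series`), `tumor_mask`, `nawm_mask`.
#' @export
load_patient <- function(dsc_path, tumor_path, nawm_path, acq = NULL,
                         te = 0.040) {
  img <- RNifti::readNifti(dsc_path)
  pq_check(length(dim(img)) == 4, "pq_format_error",
           "'%s' is not a 4D series", dsc_path)
  tum <- RNifti::readNifti(tumor_path)
  naw <- RNifti::readNifti(nawm_path)
  for (m in list(tum, naw)) {
    pq_check(length(dim(m)) == 3, "pq_format_error", "masks must be 3D")
    pq_check(all(dim(m) == dim(img)[1:3]), "pq_grid_mismatch",
             "mask grid %s does not match series grid %s",
             paste(dim(m), collapse = "x"),
             paste(dim(img)[1:3], collapse = "x"))
  }
  aff <- RNifti::xform(img)[1:3, 1:3]
  for (m in list(tum, naw)) {
    pq_check(max(abs(RNifti::xform(m)[1:3, 1:3] - aff)) <= 1e-4,
             "pq_grid_mismatch", "mask affine differs from series affine")
  }
  if (is.null(acq)) {
    tr <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1.5
    acq <- acquisition_params(te = te, tr = tr, n_dynamics = dim(img)[4])
  }
  list(dsc = dsc_series(array(as.numeric(img), dim(img)), acq),
       tumor_mask = array(as.integer(tum != 0), dim(tum)),
       nawm_mask = array(as.integer(naw != 0), dim(naw)))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param cohort_dir Directory of per-patient subdirectories, each holding
#'   `dsc.nii.gz`, `tumor_mask.nii.gz`, `nawm_mask.nii.gz` (the layout
#'   [simulate_cohort()] writes), plus a cohort `truth.csv` with class
#'   labels.
#' @param out_dir Output directory for tables and the report.
#' @param seed Seed for every stochastic stage (mandatory).
#' @param k Cross-validation folds.
#' @param auc_min,p_max Candidate-filter thresholds.
#' @param n_keep Number of features kept by recursive elimination.
#' @param qc_depth_snr Voxel QC threshold (bolus depth in baseline-noise
#'   units).
#' @param te Echo time in seconds.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cohort_dir, out_dir, seed, k = 10, auc_min = 0.8,
                       p_max = 0.005, n_keep = 5, qc_depth_snr = 5,
                       te = 0.040) {
  pq_check(!missing(seed) && is.numeric(seed), "pq_param_error",
           "seed is mandatory")
  pq_check(auc_min >= 0.5 && auc_min < 1, "pq_param_error",
           "auc_min must be in [0.5, 1)")
  pq_check(p_max > 0 && p_max <= 1, "pq_param_error",
           "p_max must be in (0, 1]")
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 seed = as.integer(seed), k = k, auc_min = auc_min,
                 p_max = p_max, n_keep = n_keep,
                 qc_depth_snr = qc_depth_snr, te = te),
            class = "run_config")
}

# extract the 44-feature row for one patient directory
patient_features <- function(pdir, te, qc_depth_snr) {
  pat <- load_patient(file.path(pdir, "dsc.nii.gz"),
                      file.path(pdir, "tumor_mask.nii.gz"),
                      file.path(pdir, "nawm_mask.nii.gz"), te = te)
  metrics <- extract_voxel_metrics(pat$dsc, pat$tumor_mask, pat$nawm_mask,
                                   qc_depth_snr = qc_depth_snr)
  percentile_features(metrics)
}

#' Run the full pipeline on a cohort directory
#'
#' Extraction (per-voxel nrCBV and PSR, per-tumor 44-feature vectors), group
#' statistics over all features, candidate filtering, recursive feature
#' elimination and gradient-boosted classification. Writes `features.csv`,
#' `stats.csv`, `whisker.csv` (per-feature, per-class box-plot statistics)
#' and `report.json` into the configured output directory.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A list with `features`, `stats`, `candidates`, `selected`,
#'   `report` (invisible).
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  truth <- utils::read.csv(file.path(config$cohort_dir, "truth.csv"))
  say <- function(...) if (verbose) message(sprintf(...))

  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pdir <- file.path(config$cohort_dir, truth$patient_id[i])
    say("extracting %s", truth$patient_id[i])
    feats <- tryCatch(
      patient_features(pdir, config$te, config$qc_depth_snr),
      perfquant_error = function(e) {
        pq_stop(class(e)[1], "stage extract, patient %s: %s",
                truth$patient_id[i], conditionMessage(e))
      })
    rows[[i]] <- cbind(data.frame(patient_id = truth$patient_id[i],
                                  class = truth$class[i]), feats)
  }
  features <- do.call(rbind, rows)

  say("group statistics over %d features", length(feature_names()))
  stats_tab <- tryCatch(
    feature_group_stats(features, k = config$k, seed = config$seed),
    perfquant_error = function(e) {
      pq_stop(class(e)[1], "stage group_stats: %s", conditionMessage(e))
    })

  candidates <- filter_candidates(stats_tab, config$auc_min, config$p_max)
  say("%d candidate features", length(candidates))
  selected <- rfe_top5(features, candidates, seed = config$seed,
                       n_keep = config$n_keep)
  report <- train_eval_gbm(features, selected, k = config$k,
                           seed = config$seed)

  whisker <- do.call(rbind, lapply(feature_names(), function(fn) {
    do.call(rbind, lapply(unique(features$class), function(cl) {
      v <- features[[fn]][features$class == cl]
      data.frame(feature = fn, class = cl, min = min(v),
                 q1 = stats::quantile(v, 0.25, names = FALSE),
                 median = stats::median(v),
                 q3 = stats::quantile(v, 0.75, names = FALSE), max = max(v))
    }))
  }))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(whisker, file.path(config$out_dir, "whisker.csv"),
                     row.names = FALSE)
    json_report <- list(
      config = unclass(config),
      candidates = candidates,
      selected = report$features,
      importances = as.list(report$importances),
      fold_aucs = report$fold_aucs,
      auc_mean = report$auc_mean, auc_sd = report$auc_sd,
      auc_ci95 = report$auc_ci95, auc_pooled = report$auc_pooled,
      best_fold_auc = report$best_fold_auc,
      hyperparameters = report$hyperparameters, seed = config$seed)
    jsonlite::write_json(json_report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(features = features, stats = stats_tab,
                 candidates = candidates, selected = report$features,
                 report = report, whisker = whisker))
}
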