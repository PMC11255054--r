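# Voxel-wise metric extraction over a tumor mask and per-tumor histogram
# percentile features.

# dynamics x voxels matrix of curves for the given 3D mask
mask_curves <- function(dsc, mask) {
  d <- dim(dsc$data)
  pq_check(length(dim(mask)) == 3 && all(dim(mask) == d[1:3]),
           "pq_shape_error", "mask dimensions do not match the series grid")
  idx <- which(mask != 0)
  m <- matrix(dsc$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  list(curves = t(m), idx = idx)
}

#' NAWM reference concentration curve and reference CBV
#'
#' Averages the concentration curves of all normal-appearing white-matter
#' voxels (each converted against its own baseline) into the reference curve
#' used by the BSW fit, and averages their uncorrected trapezoidal CBVs into
#' the normalization denominator.
#'
#' @param dsc A `dsc_series`.
#' @param nawm_mask 3D mask (nonzero = NAWM voxel) on the series grid.
#' @return A list of class `nawm_reference`: `ref_rcbv` (scalar), `ref_conc`
#'   (a `conc_curve`), `markers` (landmarks of the mean NAWM curve),
#'   `n_used`, `n_failed`.
#' @export
nawm_reference <- function(dsc, nawm_mask) {
  mc <- mask_curves(dsc, nawm_mask)
  pq_check(ncol(mc$curves) > 0, "pq_reference_unavailable",
           "NAWM mask is empty")
  nawm_reference_from_curves(mc$curves, dsc$acq)
}

#' NAWM reference from a curve matrix
#'
#' Matrix-level worker behind [nawm_reference()], usable directly on
#' [simulate_tumor()] output.
#'
#' @param curves Numeric matrix of NAWM curves, dynamics in rows.
#' @param acq An [acquisition_params()].
#' @return A `nawm_reference` object (see [nawm_reference()]).
#' @export
nawm_reference_from_curves <- function(curves, acq) {
  pq_check(ncol(curves) > 0, "pq_reference_unavailable",
           "NAWM mask is empty")
  concs <- matrix(NA_real_, nrow(curves), ncol(curves))
  rcbvs <- rep(NA_real_, ncol(curves))
  for (v in seq_len(ncol(curves))) {
    cv <- time_curve(curves[, v], acq$tr, acq$te)
    mk <- tryCatch(detect_bolus_markers(cv, n_discard = acq$n_discard),
                   perfquant_error = function(e) NULL)
    if (is.null(mk)) next
    cc <- signal_to_delta_r2star(cv, mk)
    concs[, v] <- cc$delta_r2star
    rcbvs[v] <- uncorrected_cbv(cc, mk)
  }
  ok <- !is.na(rcbvs)
  if (!any(ok)) {
    pq_stop("pq_reference_unavailable",
            "no NAWM voxel passed bolus detection")
  }
  ref_vals <- rowMeans(concs[, ok, drop = FALSE])
  # landmark the mean NAWM signal curve for window bookkeeping
  mean_sig <- rowMeans(curves[, ok, drop = FALSE])
  ref_mk <- detect_bolus_markers(time_curve(mean_sig, acq$tr, acq$te),
                                 n_discard = acq$n_discard)
  structure(list(ref_rcbv = mean(rcbvs[ok]),
                 ref_conc = structure(list(delta_r2star = ref_vals,
                                           dt = acq$tr),
                                      class = "conc_curve"),
                 markers = ref_mk, n_used = sum(ok), n_failed = sum(!ok)),
            class = "nawm_reference")
}

# run the whole per-curve chain for one voxel; returns a one-row list
analyze_voxel_curve <- function(values, acq, ref, qc_depth_snr) {
  cv <- time_curve(values, acq$tr, acq$te)
  mk <- tryCatch(detect_bolus_markers(cv, n_discard = acq$n_discard),
                 perfquant_error = function(e) {
                   if (inherits(e, "pq_curve_too_short")) "short_curve"
                   else "no_bolus"
                 })
  if (is.character(mk)) {
    return(list(rcbv_corrected = NA_real_, nrcbv = NA_real_, psr = NA_real_,
                k1 = NA_real_, k2 = NA_real_, qc_flag = mk))
  }
  depth <- mk$s0 - values[mk$t_min]
  if (mk$sd_baseline > 0 && depth / mk$sd_baseline < qc_depth_snr) {
    return(list(rcbv_corrected = NA_real_, nrcbv = NA_real_, psr = NA_real_,
                k1 = NA_real_, k2 = NA_real_, qc_flag = "low_depth"))
  }
  cc <- signal_to_delta_r2star(cv, mk)
  fit <- fit_bsw(cc, ref$ref_conc, mk)
  rcbv <- corrected_cbv(cc, fit, mk)
  psr <- compute_psr(cv, mk)
  list(rcbv_corrected = rcbv, nrcbv = rcbv / ref$ref_rcbv, psr = psr,
       k1 = fit$k1, k2 = fit$k2, qc_flag = "ok")
}

#' Per-voxel nrCBV and PSR over a tumor mask
#'
#' Runs bolus detection, concentration conversion, the BSW leakage fit
#' against the NAWM reference, leakage-corrected CBV and early PSR for every
#' voxel in the tumor mask. Voxels whose bolus depth is below
#' `qc_depth_snr` baseline standard deviations, or where no bolus is
#' detectable, are flagged and carry no metric values.
#'
#' @param dsc A `dsc_series`.
#' @param tumor_mask,nawm_mask 3D masks on the series grid.
#' @param qc_depth_snr Minimum bolus depth in baseline-noise units.
#' @param ref Optionally a precomputed [nawm_reference()].
#' @return A data frame of class `voxel_metrics`: voxel coordinates,
#'   `rcbv_corrected`, `nrcbv`, `psr`, `k1`, `k2`, `qc_flag`.
#' @export
extract_voxel_metrics <- function(dsc, tumor_mask, nawm_mask,
                                  qc_depth_snr = 5, ref = NULL) {
  mc <- mask_curves(dsc, tumor_mask)
  pq_check(ncol(mc$curves) > 0, "pq_shape_error", "tumor mask is empty")
  if (is.null(ref)) ref <- nawm_reference(dsc, nawm_mask)
  out <- voxel_metrics_from_curves(mc$curves, dsc$acq, ref, qc_depth_snr)
  d <- dim(dsc$data)[1:3]
  coords <- arrayInd(mc$idx, d)
  out$x <- coords[, 1]
  out$y <- coords[, 2]
  out$z <- coords[, 3]
  out[, c("x", "y", "z", "rcbv_corrected", "nrcbv", "psr", "k1", "k2",
          "qc_flag")]
}

#' Voxel metrics from a curve matrix
#'
#' Matrix-level worker behind [extract_voxel_metrics()], usable directly on
#' [simulate_tumor()] output (dynamics x voxels).
#'
#' @param curves Numeric matrix, dynamics in rows, voxels in columns.
#' @param acq An [acquisition_params()].
#' @param ref A [nawm_reference()] (or a list with `ref_conc`, `ref_rcbv`).
#' @param qc_depth_snr Minimum bolus depth in baseline-noise units.
#' @return A data frame of class `voxel_metrics`.
#' @export
voxel_metrics_from_curves <- function(curves, acq, ref, qc_depth_snr = 5) {
  n <- ncol(curves)
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    rows[[v]] <- analyze_voxel_curve(curves[, v], acq, ref, qc_depth_snr)
  }
  out <- data.frame(
    rcbv_corrected = vapply(rows, `[[`, numeric(1), "rcbv_corrected"),
    nrcbv = vapply(rows, `[[`, numeric(1), "nrcbv"),
    psr = vapply(rows, `[[`, numeric(1), "psr"),
    k1 = vapply(rows, `[[`, numeric(1), "k1"),
    k2 = vapply(rows, `[[`, numeric(1), "k2"),
    qc_flag = vapply(rows, `[[`, character(1), "qc_flag"))
  class(out) <- c("voxel_metrics", "data.frame")
  out
}

#' Per-tumor histogram feature vector
#'
#' Mean, minimum, maximum and the 5th..95th percentiles (steps of 5, linear
#' interpolation between order statistics) of nrCBV and PSR over the
#' QC-passing voxels: 44 features named `nrCBV_mean`, `nrCBV_min`,
#' `nrCBV_max`, `nrCBV_p5` .. `nrCBV_p95`, and likewise `PSR_*`.
#'
#' @param metrics A `voxel_metrics` data frame.
#' @param min_voxels Minimum number of QC-passing voxels required.
#' @return A one-row data frame with 44 feature columns plus `n_voxels_ok`
#'   and `n_voxels_rejected`.
#' @export
percentile_features <- function(metrics, min_voxels = 10) {
  ok <- metrics[metrics$qc_flag == "ok", , drop = FALSE]
  pq_check(nrow(ok) >= min_voxels, "pq_too_few_voxels",
           "only %d QC-passing voxels (need >= %d)", nrow(ok), min_voxels)
  probs <- seq(5, 95, by = 5)
  summarize <- function(x, prefix) {
    qs <- stats::quantile(x, probs / 100, type = 7, names = FALSE)
    vals <- c(mean(x), min(x), max(x), qs)
    names(vals) <- c(paste0(prefix, "_mean"), paste0(prefix, "_min"),
                     paste0(prefix, "_max"), paste0(prefix, "_p", probs))
    vals
  }
  vals <- c(summarize(ok$nrcbv, "nrCBV"), summarize(ok$psr, "PSR"))
  out <- as.data.frame(as.list(vals), check.names = FALSE)
  out$n_voxels_ok <- nrow(ok)
  out$n_voxels_rejected <- nrow(metrics) - nrow(ok)
  class(out) <- c("tumor_features", "data.frame")
  out
}

#' All feature column names in canonical order
#' @return Character vector of the 44 feature names.
#' @export
feature_names <- function() {
  probs <- seq(5, 95, by = 5)
  c(paste0("nrCBV_", c("mean", "min", "max", paste0("p", probs))),
    paste0("PSR_", c("mean", "min", "max", paste0("p", probs))))
}
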