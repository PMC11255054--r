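# Forward simulator: voxel curves, whole tumors, and two-class cohorts with
# known ground truth.
#
# Signal model: monoexponential T2* decay, S(t) = s0 * exp(-TE * dR2*(t)),
# with voxel concentration
#   dR2*(t) = cbv * C1(t - d) + (mu + k2_leak * A) * Qn(t - d)
# where C1 is the shared tissue template (bolus_template), Qn its normalized
# cumulative and A its area. mu is solved per voxel so that the early PSR
# measured at the first-pass end the detection rule finds on the noiseless
# curve equals psr_true exactly; k2_leak adds a linear leakage term on the
# same cumulative basis (the family the BSW correction removes exactly).

#' Ground truth for one simulated voxel
#'
#' @param cbv_ratio True blood-volume ratio relative to NAWM (dimensionless).
#' @param psr_true True early signal-recovery fraction at first-pass end.
#' @param leak_k2 Linear leakage coefficient (1/s per unit integrated
#'   reference concentration).
#' @param bolus_delay Bolus arrival delay in seconds.
#' @return An object of class `voxel_truth`.
#' @export
voxel_truth <- function(cbv_ratio, psr_true, leak_k2 = 0, bolus_delay = 0) {
  pq_check(is.numeric(cbv_ratio) && cbv_ratio >= 0, "pq_param_error",
           "cbv_ratio must be >= 0")
  pq_check(is.numeric(psr_true) && psr_true >= 0 && psr_true <= 1.3,
           "pq_param_error", "psr_true must be in [0, 1.3]")
  pq_check(is.finite(leak_k2), "pq_param_error", "leak_k2 must be finite")
  pq_check(bolus_delay >= 0, "pq_param_error", "bolus_delay must be >= 0")
  structure(list(cbv_ratio = cbv_ratio, psr_true = psr_true,
                 leak_k2 = leak_k2, bolus_delay = bolus_delay),
            class = "voxel_truth")
}

#' Population preset for one tumor class
#'
#' Describes the population distribution of per-tumor mean nrCBV and PSR,
#' the within-tumor voxel dispersion, and the frequency/magnitude of the
#' voxel-level leakage term.
#'
#' @param label `"astrocytoma"` or `"oligodendroglioma"`.
#' @param mean_nrcbv_mu,mean_nrcbv_sd Population mean and SD of the
#'   per-tumor mean CBV ratio.
#' @param psr_mu,psr_sd Population mean and SD of the per-tumor mean PSR.
#' @param intra_tumor_cbv_cv Coefficient of variation of voxel CBV within a
#'   tumor (lognormal).
#' @param intra_tumor_psr_sd Within-tumor PSR spread (truncated normal).
#' @param leak_prob,leak_scale Probability that a voxel carries a leakage
#'   term, and the SD of its (signed) magnitude.
#' @return An object of class `class_preset`.
#' @export
class_preset <- function(label, mean_nrcbv_mu, mean_nrcbv_sd, psr_mu, psr_sd,
                         intra_tumor_cbv_cv = 0.3, intra_tumor_psr_sd = 0.08,
                         leak_prob = 0.3, leak_scale = 0.005) {
  pq_check(label %in% c("astrocytoma", "oligodendroglioma"),
           "pq_param_error", "unknown class label '%s'", label)
  pq_check(all(c(mean_nrcbv_sd, psr_sd, intra_tumor_cbv_cv,
                 intra_tumor_psr_sd, leak_scale) >= 0),
           "pq_param_error", "spread parameters must be >= 0")
  pq_check(leak_prob >= 0 && leak_prob <= 1, "pq_param_error",
           "leak_prob must be in [0, 1]")
  structure(list(label = label, mean_nrcbv_mu = mean_nrcbv_mu,
                 mean_nrcbv_sd = mean_nrcbv_sd, psr_mu = psr_mu,
                 psr_sd = psr_sd, intra_tumor_cbv_cv = intra_tumor_cbv_cv,
                 intra_tumor_psr_sd = intra_tumor_psr_sd,
                 leak_prob = leak_prob, leak_scale = leak_scale,
                 cbv_range = c(0.2, 8), psr_range = c(0.05, 1.25)),
            class = "class_preset")
}

#' Calibrated presets for the two glioma classes
#'
#' Returns the pair of [class_preset()] objects the cohort simulator uses by
#' default: per-tumor mean nrCBV 2.05 +/- 0.58 and PSR 0.68 +/- 0.21 for
#' 1p19q-codeleted oligodendrogliomas, 1.55 +/- 0.58 and 0.81 +/- 0.19 for
#' IDH-mutant astrocytomas. Within-tumor dispersions (CBV CV 0.35 / 0.30,
#' PSR SD 0.08) are chosen so that simulated upper-quartile percentile
#' features sit near nrCBV p75 of about 2.5 (oligodendroglioma) and 1.9
#' (astrocytoma).
#'
#' @return A named list with elements `oligodendroglioma` and `astrocytoma`.
#' @export
glioma_class_presets <- function() {
  list(
    oligodendroglioma = class_preset(
      "oligodendroglioma", mean_nrcbv_mu = 2.05, mean_nrcbv_sd = 0.58,
      psr_mu = 0.68, psr_sd = 0.21, intra_tumor_cbv_cv = 0.35,
      intra_tumor_psr_sd = 0.08),
    astrocytoma = class_preset(
      "astrocytoma", mean_nrcbv_mu = 1.55, mean_nrcbv_sd = 0.58,
      psr_mu = 0.81, psr_sd = 0.19, intra_tumor_cbv_cv = 0.30,
      intra_tumor_psr_sd = 0.08)
  )
}

#' Simulate one voxel's DSC time-intensity curve
#'
#' Forward-simulates a signal curve from a [voxel_truth()] under the shared
#' [bolus_template()]. The recovery coefficient is solved by fixed-point
#' iteration so that the early PSR computed at the first-pass end found by
#' [detect_bolus_markers()] on the noiseless curve equals `psr_true`
#' (leakage, when present, is added afterwards and shifts the observed PSR,
#' as it does in vivo). The leading non-steady-state dynamics are held at
#' the baseline level.
#'
#' @param truth A [voxel_truth()].
#' @param template A [bolus_template()].
#' @param acq An [acquisition_params()]; defaults to the template's.
#' @param noise_sd Additive Gaussian noise SD; defaults to `acq$noise_sd`.
#'   Pass 0 for a noiseless curve.
#' @return A list with `signal` (length `n_dynamics`), `mu` (the solved
#'   recovery coefficient, 1/s), and `markers` from the noiseless curve
#'   (`NULL` when no bolus is detectable, e.g. zero blood volume).
#' @export
simulate_curve <- function(truth, template, acq = template$acq,
                           noise_sd = acq$noise_sd) {
  stopifnot(inherits(truth, "voxel_truth"), inherits(template, "bolus_template"))
  tpl <- if (truth$bolus_delay > 0)
    template_delayed(template, truth$bolus_delay)
  else
    list(conc = template$conc, cum_norm = template$cum_norm)

  mu <- 0
  markers <- NULL
  fpe_prev <- -1L
  for (it in 1:25) {
    conc <- truth$cbv_ratio * tpl$conc + mu * tpl$cum_norm
    s <- acq$s0 * exp(-acq$te * conc)
    s[seq_len(acq$n_discard)] <- acq$s0
    mk <- tryCatch(
      detect_bolus_markers(s, acq = acq, n_discard = acq$n_discard),
      perfquant_error = function(e) NULL)
    if (is.null(mk)) break
    markers <- mk
    s_min <- s[mk$t_min]
    s_target <- s_min + truth$psr_true * (acq$s0 - s_min)
    mu_new <- (-log(s_target / acq$s0) / acq$te -
                 truth$cbv_ratio * tpl$conc[mk$fpe]) / tpl$cum_norm[mk$fpe]
    done <- mk$fpe == fpe_prev && abs(mu_new - mu) < 1e-9
    mu <- mu_new
    if (done) break
    fpe_prev <- mk$fpe
  }

  conc <- truth$cbv_ratio * tpl$conc +
    (mu + truth$leak_k2 * template$area) * tpl$cum_norm
  s <- acq$s0 * exp(-acq$te * conc)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
  s[seq_len(acq$n_discard)] <- acq$s0 +
    if (noise_sd > 0) stats::rnorm(acq$n_discard, 0, noise_sd) else 0
  list(signal = s, mu = mu, markers = markers)
}

# draw one tumor's voxel truths from a preset (no curves)
draw_tumor_truths <- function(preset, n_voxels, delay_max = 0.15) {
  rng <- preset$cbv_range
  mean_cbv <- min(max(stats::rnorm(1, preset$mean_nrcbv_mu,
                                   preset$mean_nrcbv_sd), rng[1]), rng[2])
  prng <- preset$psr_range
  mean_psr <- min(max(stats::rnorm(1, preset$psr_mu, preset$psr_sd),
                      prng[1]), prng[2])
  if (preset$intra_tumor_cbv_cv > 0) {
    sig <- sqrt(log(1 + preset$intra_tumor_cbv_cv^2))
    cbv <- stats::rlnorm(n_voxels, log(mean_cbv) - sig^2 / 2, sig)
    cbv <- pmin(pmax(cbv, rng[1]), rng[2])
  } else {
    cbv <- rep(mean_cbv, n_voxels)
  }
  psr <- pmin(pmax(stats::rnorm(n_voxels, mean_psr,
                                preset$intra_tumor_psr_sd), prng[1]), prng[2])
  leak <- ifelse(stats::runif(n_voxels) < preset$leak_prob,
                 stats::rnorm(n_voxels, 0, preset$leak_scale), 0)
  delay <- stats::runif(n_voxels, 0, delay_max)
  list(mean_cbv = mean_cbv, mean_psr = mean_psr,
       truths = data.frame(voxel = seq_len(n_voxels), cbv_ratio = cbv,
                           psr_true = psr, leak_k2 = leak,
                           bolus_delay = delay))
}

#' Simulate a whole tumor plus its NAWM reference voxels
#'
#' Draws the tumor's mean nrCBV and PSR from the preset's population
#' distributions, then per-voxel truths (lognormal CBV around the tumor
#' mean, truncated-normal PSR), and forward-simulates every curve. NAWM
#' voxels are generated with `cbv_ratio = 1` and the reference tissue's
#' natural recovery (`psr_true = 0.9`), no leakage, no delay.
#'
#' @param preset A [class_preset()].
#' @param n_voxels Number of tumor voxels (at least 10).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param template A [bolus_template()]; built from `acq` if missing.
#' @param acq An [acquisition_params()].
#' @param n_nawm Number of NAWM reference voxels.
#' @param delay_max Upper bound (seconds) of the per-voxel uniform bolus
#'   arrival jitter.
#' @param noise_sd Noise SD override (defaults to `acq$noise_sd`).
#' @return A list of class `sim_tumor`: `curves` (dynamics x voxels),
#'   `nawm_curves`, `truth` (per-voxel data frame), `mean_cbv`, `mean_psr`,
#'   `label`, `acq`, `template`.
#' @export
simulate_tumor <- function(preset, n_voxels, seed,
                           acq = acquisition_params(),
                           template = bolus_template(acq),
                           n_nawm = 20, delay_max = 0.15,
                           noise_sd = acq$noise_sd) {
  pq_check(n_voxels >= 10, "pq_param_error",
           "n_voxels must be >= 10 (got %d)", n_voxels)
  set.seed(seed)
  drawn <- draw_tumor_truths(preset, n_voxels, delay_max)
  curves <- matrix(NA_real_, acq$n_dynamics, n_voxels)
  for (v in seq_len(n_voxels)) {
    tr_v <- voxel_truth(drawn$truths$cbv_ratio[v], drawn$truths$psr_true[v],
                        drawn$truths$leak_k2[v], drawn$truths$bolus_delay[v])
    curves[, v] <- simulate_curve(tr_v, template, acq, noise_sd)$signal
  }
  nawm <- matrix(NA_real_, acq$n_dynamics, n_nawm)
  nawm_truth <- voxel_truth(1, 0.9, 0, 0)
  for (v in seq_len(n_nawm)) {
    nawm[, v] <- simulate_curve(nawm_truth, template, acq, noise_sd)$signal
  }
  structure(list(curves = curves, nawm_curves = nawm, truth = drawn$truths,
                 mean_cbv = drawn$mean_cbv, mean_psr = drawn$mean_psr,
                 label = preset$label, acq = acq, template = template),
            class = "sim_tumor")
}

# ellipsoid tumor mask + two NAWM boxes on contiguous slices
cohort_geometry <- function(dim3, n_voxels_target) {
  ctr <- (dim3 + 1) / 2
  a <- (n_voxels_target / (4 / 3 * pi * 0.6))^(1 / 3)
  ax <- c(a, a, max(a * 0.6, 1.2))
  idx <- as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                               z = seq_len(dim3[3])))
  d2 <- ((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
    ((idx[, 3] - ctr[3]) / ax[3])^2
  tumor <- array(0L, dim3)
  tumor[idx[d2 <= 1, , drop = FALSE]] <- 1L

  nawm <- array(0L, dim3)
  z0 <- max(1, dim3[3] - 2)
  xs <- 2:min(6, dim3[1])
  nawm[xs, 2, z0] <- 1L
  nawm[xs, 2, min(z0 + 1, dim3[3])] <- 1L
  if (any(tumor & nawm)) nawm[tumor == 1L] <- 0L
  list(tumor = tumor, nawm = nawm)
}

#' Assemble one simulated patient as a 4D series plus masks
#'
#' Builds an ellipsoid tumor mask and two contiguous-slice NAWM boxes inside
#' a volume of dimension `dim3`, simulates curves for every mask voxel via
#' [simulate_tumor()], and fills the background with baseline-level signal.
#'
#' @inheritParams simulate_tumor
#' @param dim3 Spatial dimensions of the volume.
#' @param n_voxels_target Approximate tumor size in voxels (the ellipsoid is
#'   scaled to this count).
#' @return A list of class `sim_patient`: `dsc` (a `dsc_series`),
#'   `tumor_mask`, `nawm_mask`, `truth`, `mean_cbv`, `mean_psr`, `label`.
#' @export
simulate_patient <- function(preset, n_voxels_target = 350, seed,
                             dim3 = c(24, 24, 10),
                             acq = acquisition_params(),
                             template = bolus_template(acq),
                             noise_sd = acq$noise_sd, delay_max = 0.15) {
  geom <- cohort_geometry(dim3, n_voxels_target)
  n_tum <- sum(geom$tumor)
  n_nawm <- sum(geom$nawm)
  sim <- simulate_tumor(preset, n_tum, seed, acq, template,
                        n_nawm = n_nawm, delay_max = delay_max,
                        noise_sd = noise_sd)
  vol <- array(acq$s0, c(dim3, acq$n_dynamics))
  if (noise_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), 0, noise_sd)
  }
  tum_idx <- which(geom$tumor == 1L)
  nawm_idx <- which(geom$nawm == 1L)
  nvox_slice <- prod(dim3)
  for (tt in seq_len(acq$n_dynamics)) {
    off <- (tt - 1L) * nvox_slice
    vol[off + tum_idx] <- sim$curves[tt, ]
    vol[off + nawm_idx] <- sim$nawm_curves[tt, ]
  }
  dsc <- dsc_series(vol, acq)
  structure(list(dsc = dsc, tumor_mask = geom$tumor, nawm_mask = geom$nawm,
                 truth = sim$truth, mean_cbv = sim$mean_cbv,
                 mean_psr = sim$mean_psr, label = preset$label),
            class = "sim_patient")
}

#' Simulate a two-class cohort, optionally persisted as NIfTI
#'
#' Generates `n_astro` astrocytoma-preset and `n_oligo`
#' oligodendroglioma-preset patients. When `out_dir` is given, each patient
#' directory receives `dsc.nii.gz`, `tumor_mask.nii.gz`, `nawm_mask.nii.gz`
#' and `voxel_truth.csv`; the cohort root receives `truth.csv` (per-patient
#' mean truths) and `cohort.json` (the configuration echo). Identical seeds
#' produce byte-identical truth tables.
#'
#' @param n_astro,n_oligo Patients per class (defaults mirror a 52-patient
#'   cohort of 28 astrocytomas and 24 oligodendrogliomas).
#' @param presets A list with elements `astrocytoma` and `oligodendroglioma`.
#' @param seed Cohort seed; per-patient seeds are derived from it.
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @param keep_data Return the full per-patient objects (memory-heavy for
#'   large cohorts); forced `TRUE` when `out_dir` is `NULL`.
#' @inheritParams simulate_patient
#' @return A list of class `sim_cohort` with `truth` (per-patient data
#'   frame), `config`, and `patients` (when kept).
#' @export
simulate_cohort <- function(n_astro = 28, n_oligo = 24,
                            presets = glioma_class_presets(), seed = 1,
                            out_dir = NULL, n_voxels_target = 350,
                            dim3 = c(24, 24, 10),
                            acq = acquisition_params(),
                            keep_data = is.null(out_dir)) {
  pq_check(n_astro >= 1 && n_oligo >= 1, "pq_param_error",
           "need at least one patient per class")
  if (is.null(out_dir)) keep_data <- TRUE
  template <- bolus_template(acq)
  n_pat <- n_astro + n_oligo
  labels <- c(rep("astrocytoma", n_astro), rep("oligodendroglioma", n_oligo))
  set.seed(seed)
  pat_seeds <- sample.int(.Machine$integer.max - 1L, n_pat)

  if (!is.null(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) {
      pq_stop("pq_io_error", "cannot create output directory '%s'", out_dir)
    }
  }

  patients <- if (keep_data) vector("list", n_pat) else NULL
  truth <- data.frame(patient_id = sprintf("patient_%03d", seq_len(n_pat)),
                      class = labels, seed = pat_seeds,
                      mean_cbv = NA_real_, mean_psr = NA_real_)
  for (i in seq_len(n_pat)) {
    pat <- simulate_patient(presets[[labels[i]]], n_voxels_target,
                            pat_seeds[i], dim3, acq, template)
    truth$mean_cbv[i] <- pat$mean_cbv
    truth$mean_psr[i] <- pat$mean_psr
    if (!is.null(out_dir)) {
      pdir <- file.path(out_dir, truth$patient_id[i])
      dir.create(pdir, showWarnings = FALSE)
      write_patient_nifti(pat, pdir)
      utils::write.csv(pat$truth, file.path(pdir, "voxel_truth.csv"),
                       row.names = FALSE)
    }
    if (keep_data) patients[[i]] <- pat
  }
  config <- list(n_astro = n_astro, n_oligo = n_oligo, seed = seed,
                 n_voxels_target = n_voxels_target, dim3 = dim3,
                 te = acq$te, tr = acq$tr, n_dynamics = acq$n_dynamics,
                 n_baseline = acq$n_baseline, s0 = acq$s0,
                 noise_sd = acq$noise_sd)
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(truth = truth, config = config, patients = patients),
            class = "sim_cohort")
}
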