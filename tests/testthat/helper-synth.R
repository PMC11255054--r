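# Shared fixtures: all synthetic, built in code at test time.

t_acq <- acquisition_params()
t_tpl <- bolus_template(t_acq)

conc_of <- function(values, dt = t_acq$tr) {
  structure(list(delta_r2star = values, dt = dt), class = "conc_curve")
}

markers_of <- function(arrival, t_min, fpe, s0 = 100, sd_baseline = 0,
                       discard_n = 3) {
  structure(list(discard_n = discard_n, baseline_start = discard_n + 1,
                 baseline_end = arrival - 3, s0 = s0,
                 sd_baseline = sd_baseline, arrival = arrival,
                 t_min = t_min, fpe = fpe, fpe_fallback = FALSE),
            class = "bolus_markers")
}

# a clean synthetic bolus curve: flat baseline, sharp dip, recovery, plateau
dip_curve <- function(n = 60, s0 = 100, baseline_n = 13,
                      dip = c(85, 70, 55, 40), recovery = c(55, 70, 82, 88),
                      plateau = 90) {
  c(rep(s0, baseline_n), dip, recovery,
    rep(plateau, n - baseline_n - length(dip) - length(recovery)))
}

# per-tumor feature table via the curve-matrix path (fast; no volumes)
sim_feature_cohort <- function(n_per_class, n_voxels, seed,
                               presets = glioma_class_presets(),
                               noise_sd = t_acq$noise_sd) {
  rows <- list()
  i <- 0
  for (lab in names(presets)) {
    for (p in seq_len(n_per_class)) {
      i <- i + 1
      sim <- simulate_tumor(presets[[lab]], n_voxels, seed * 100000 + i,
                            acq = t_acq, template = t_tpl,
                            noise_sd = noise_sd)
      ref <- nawm_reference_from_curves(sim$nawm_curves, t_acq)
      met <- voxel_metrics_from_curves(sim$curves, t_acq, ref)
      feats <- percentile_features(met)
      rows[[i]] <- cbind(data.frame(patient_id = sprintf("p%03d", i),
                                    class = lab), feats)
    }
  }
  do.call(rbind, rows)
}

# Gaussian feature table for classifier tests: `informative` columns shift
# between classes by `sep` SDs, the rest are pure noise
gauss_cohort <- function(n_per_class, features, informative, sep, seed) {
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- rep(c("astrocytoma", "oligodendroglioma"), each = n_per_class)
  tab <- data.frame(patient_id = sprintf("p%03d", seq_len(n)), class = cls)
  for (f in features) {
    shift <- if (f %in% informative) sep else 0
    tab[[f]] <- stats::rnorm(n) + ifelse(cls == "oligodendroglioma", shift, 0)
  }
  tab
}
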