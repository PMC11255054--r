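# perfquant

Voxel-wise DSC-MRI perfusion quantification for presurgical glioma
subtyping.

## What it does

Differentiating IDH-mutant astrocytomas from 1p19q-codeleted
oligodendrogliomas before surgery is an open problem in neuro-oncology.
Dynamic susceptibility contrast perfusion-weighted imaging (DSC-PWI) yields
a T2\*-weighted time-intensity curve per voxel during a gadolinium bolus;
`perfquant` turns these curves into two complementary vascular readouts and
a classifier:

* **nrCBV** — leakage-corrected relative cerebral blood volume. Each
  voxel's curve is converted to concentration,
  ΔR₂\*(t) = −ln(S(t)/S₀)/TE, corrected for contrast leakage with the
  Boxerman–Schmainda–Weisskoff model
  (ΔR₂\* ≈ K₁·R̄(t) − K₂·∫R̄, correction adds back K₂·∫R̄), integrated, and
  normalized to normal-appearing white matter (NAWM).
* **PSR** — early percentage of signal recovery,
  (S_fpe − S_min)/(S₀ − S_min), read at the automatically detected end of
  the first vascular pass (where the mean ascending slope of the recovering
  curve falls below its own SD).

Per tumor, both metrics are summarized over a 3D segmentation by mean,
minimum, maximum and percentiles p5…p95 in steps of five (44 features).
Features are compared between classes (Mann-Whitney U, stratified 10-fold
cross-validated AUC-ROC, Bonferroni correction, Youden operating points,
DeLong AUC comparison), filtered (AUC > 0.8, p < 0.005), reduced to five by
recursive feature elimination, and combined in a gradient-boosted
classifier with stratified 10-fold cross-validation. Oligodendrogliomas
show higher nrCBV and lower PSR than astrocytomas, and percentile features
separate the classes better than means or extremes.

Clinical DSC data cannot be redistributed, so the package includes a
calibrated forward simulator (`simulate_curve`, `simulate_tumor`,
`simulate_patient`, `simulate_cohort`) with known per-voxel ground truth;
class presets reproduce published population statistics (per-tumor mean
nrCBV 2.05 ± 0.58 / PSR 0.68 ± 0.21 for oligodendrogliomas, 1.55 ± 0.58 /
0.81 ± 0.19 for astrocytomas). See the vignette
(`vignettes/dsc-perfusion-pipeline.Rmd`) for the model, its assumptions and
the calibration rationale.

## Worked example

```r
library(perfquant)

presets <- glioma_class_presets()
pat <- simulate_patient(presets$oligodendroglioma,
                        n_voxels_target = 350, seed = 7)

metrics <- extract_voxel_metrics(pat$dsc, pat$tumor_mask, pat$nawm_mask)
head(metrics[, c("x", "y", "z", "nrcbv", "psr", "qc_flag")], 3)
#>    x  y z    nrcbv       psr qc_flag
#> 1 11 10 3 2.460427 0.4100730      ok
#> 2 12 10 3 2.605591 0.4197096      ok
#> 3 13 10 3 2.376084 0.4942736      ok

feats <- percentile_features(metrics)
feats[, c("nrCBV_mean", "nrCBV_p75", "PSR_mean", "PSR_p70")]
#>   nrCBV_mean nrCBV_p75  PSR_mean   PSR_p70
#> 1   3.495459  4.060426 0.4249672 0.4749852
```

All 360 tumor voxels passed QC. This tumor drew a high blood volume from
the oligodendroglioma population (true tumor-mean nrCBV 3.38, PSR 0.43);
the pipeline's estimates (3.50, 0.42) recover those truths through the
full detection → conversion → leakage-correction → normalization chain.
`nrcbv` is dimensionless (ratio to NAWM); `psr` is a fraction.

A full cohort run — extraction for every patient, the 44-row statistics
table, candidate filtering, RFE and the classifier report — is one call:

```r
simulate_cohort(n_astro = 28, n_oligo = 24, seed = 1, out_dir = "cohort/")
res <- run_all(run_config(cohort_dir = "cohort/", out_dir = "out/", seed = 1))
```

which writes `features.csv` (one row per patient, columns `nrCBV_mean`,
`nrCBV_min`, `nrCBV_max`, `nrCBV_p5` … `nrCBV_p95`, `PSR_mean`, …,
`PSR_p95`, plus `class`), `stats.csv`, `whisker.csv` (per-feature,
per-class box-plot statistics) and `report.json` (candidates, the five
selected features, importances, per-fold AUCs, mean ± SD and CI). New
cases are scored with `predict_case()`, which returns the class
probability plus the case-vs-cohort overlay data.

The same stages are scriptable from a shell via
`inst/cli/perfquant.R simulate|extract|stats|classify|run-all`.

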