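# dmnpredict

Seed-based intrinsic functional connectivity of the default mode network
(DMN) as a biomarker of antidepressant treatment remission — a tested,
reusable R pipeline from motion-censored task-residual BOLD series to
cluster-level group prediction and cross-validated classification.

## The scientific problem

Only a fraction of patients with major depressive disorder remit on a
first-line antidepressant, and no clinical variable reliably predicts who
will. A candidate imaging biomarker is the intrinsic (spontaneous)
functional coupling between the posterior cingulate cortex (PCC) and the
anterior cingulate / medial prefrontal cortex (ACC/mPFC), the posterior and
anterior hubs of the DMN: patients who later remit tend to show intact
PCC–ACC/mPFC connectivity, indistinguishable from healthy controls, while
eventual non-remitters show hypo-connectivity.

`dmnpredict` implements the full analysis chain needed to evaluate such a
biomarker:

1. **QC / censoring** — framewise displacement
   FD_t = Σᵢ |dᵢ(t) − dᵢ(t−1)| (rotations as arc length at 50 mm) and a
   DVARS-like scaled signal-change trace; volumes with FD ≥ 0.3 mm or
   scaled change > 10 are spikes; each spike censors frames t−1…t+2
   (4 volumes); subjects with > 200 of 600 volumes censored are excluded.
2. **Intrinsic residuals** — per-run GLM with HRF-convolved task
   regressors, the 24-parameter Volterra motion expansion
   (R_t, R_t², R_{t−1}, R_{t−1}²), white-matter/ventricle signals and
   per-censored-frame indicators; residuals band-passed to
   0.009 < f < 0.08 Hz and concatenated across runs.
3. **Seed connectivity** — mean series over two bilateral 5 mm PCC spheres
   (MNI −11,−52,37 / 12,−52,35); voxel-wise Pearson r over retained
   frames; Fisher z = atanh(r).
4. **Group inference** — voxel-wise z ~ outcome + age + illness duration +
   baseline severity; cluster-extent family-wise error control by
   Freedman–Lane permutation of the maximum cluster extent
   (p_FWE = (1 + #{perm max ≥ extent}) / (n_perm + 1)); planned
   comparisons vs controls with Cohen's d = t·√(1/n₁+1/n₂); paired
   pre/post tests; a remission × drug interaction model.
5. **Classification** — remission (week-8 HRSD₁₇ ≤ 7) predicted by
   hierarchical logistic regression (covariates ± standardized ROI
   connectivity), likelihood-ratio and Wald tests, ROC/AUC, and
   leave-one-out cross-validation with fold-wise standardization.
6. **Synthetic cohort** — a seeded generator producing BOLD runs (or,
   scaled down, connectivity maps directly) with planted group effects
   (d ≈ 1.2), motion spikes, task responses and nuisance signals, so every
   stage is testable without clinical data.

## Worked example

```r
library(dmnpredict)

# a desk-scale BOLD cohort: 10 remitters, 10 non-remitters, 6 controls,
# two 120-volume runs per session, compact synthetic geometry
root <- tempfile("cohort")
cfg <- pipeline_config(
  root = root,
  cohort = toy_cohort_spec(n_remit = 10, n_nonremit = 10, n_control = 6,
                           n_runs = 2, rng_seed = 2, noise_sd = 0.3),
  perm = permutation_config(n_permutations = 499, cluster_forming_p = 0.01,
                            fwe_alpha = 0.05, rng_seed = 7),
  roi_radius_mm = 8)
out <- run_pipeline(cfg)   # ~1.5 min: simulate, qc, connectivity, group, classify

head(read.table(file.path(cfg$out_dir, "cluster_table.tsv"), header = TRUE), 2)
#>   p_fwe extent peak_x peak_y peak_z peak_stat retained
#> 1 0.004     30   -1.5   19.5   -4.5  5.001754     TRUE
#> 2 0.818      2    1.5   10.5  -19.5  2.800159    FALSE

jsonlite::read_json(file.path(cfg$out_dir, "group_results.json"))
#> planned remitter vs control:      d =  0.08, p = 0.874
#> planned non-remitter vs control:  d = -1.43, p = 0.016
#> non-remitter paired pre/post:     mean change = +0.29, p < 1e-4

jsonlite::read_json(file.path(cfg$out_dir, "classification.json"))
#> roi_voxels 32, lr_chisq 12.4, wald_fc 2.21, auc_apparent 0.96,
#> auc_cv 0.72, accuracy_cv 0.85, sensitivity_cv 0.9, specificity_cv 0.8
```

Reading the output: the Step-1 permutation analysis retains exactly one
cluster (30 voxels, family-wise p = 0.004), whose peak (−1.5, 19.5, −4.5)
sits inside the planted anterior target region. The Step-2 planned
comparisons reproduce the planted clinical pattern — remitters are
indistinguishable from controls while non-remitters are hypo-connected
(d = −1.43), and non-remitter connectivity partially normalizes at the
follow-up session (+0.29 z, p < 1e-4). Adding the region's connectivity to
the covariate-only logistic model improves remission classification by a
likelihood-ratio χ² of 12.4 (1 df), with 85 % leave-one-out accuracy. At
this small n the realized cohort effect varies noticeably between seeds;
the acceptance suite quantifies retention rates at the full emulated
sample size. Outputs land under `<root>/derivatives/`: a QC censoring
table, a z-map manifest, the cluster table, ROC coordinates, and a JSON
manifest recording every stage's parameters and seeds.

A command-line driver wraps the same stages:

```sh
Rscript -e 'dmnpredict::pipeline_cli()' all --root ds --seed 5
```

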