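---
title: "Methods: intrinsic DMN connectivity as a remission biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic DMN connectivity as a remission biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmnpredict)
```

`dmnpredict` implements a complete seed-based intrinsic-connectivity
biomarker analysis: from raw task-fMRI runs with realignment traces to a
cluster-level group prediction of antidepressant remission and a
cross-validated classifier. This vignette documents the model at each
stage, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## 1. The measurement model

Intrinsic functional connectivity is estimated from *task residuals*: the
BOLD signal that remains after modeled task responses and nuisance
confounds have been regressed out, band-pass filtered into the slow
fluctuation band, and concatenated across the session's runs. The
biomarker of interest is the Fisher-z transformed Pearson correlation
between the posterior cingulate (PCC) seed — the union of two bilateral
5 mm spheres at MNI (−11, −52, 37) and (12, −52, 35) — and every other
voxel; the anterior cingulate / medial prefrontal (ACC/mPFC) region around
(−2, 50, −6) carries the prediction.

### Volume censoring

Head motion corrupts connectivity estimates in a way nuisance regression
alone cannot repair, so high-motion volumes are censored:

* **Framewise displacement.** FD_t = Σᵢ |dᵢ(t) − dᵢ(t−1)| over the six
  rigid-body parameters, rotations converted to arc length on a 50 mm
  sphere (`rotation_radius_mm`, the standard head-radius convention). The
  first volume has FD = 0 — it has no predecessor, and assigning the
  first difference there would spuriously censor every run start.
* **Scaled signal change.** The whole-volume mean squared intensity
  difference between consecutive volumes divided by the grand mean
  intensity of the series (a DVARS-like index). This is the literal
  reading of the defining sentence; the reference toolbox's exact
  normalization is not printed anywhere, so alternative scalings (×100)
  would change the threshold's meaning — the threshold default (10)
  belongs to *this* normalization.
* **Thresholds.** FD ≥ 0.3 mm (inclusive) or scaled change > 10 (strict)
  marks a spike; each spike censors the window t−1 … t+2, i.e. exactly
  four volumes per isolated interior spike, clipped at run boundaries
  (runs are modeled independently, so censoring never crosses them).
  The original protocol describes the window both as "each censored volume plus the
  subsequent volume" and as "four temporal masks (one before, two after)";
  the four-volume rule is adopted because it is stated with explicit
  counts.
* **Exclusion.** A subject with strictly more than `max_censored_volumes`
  (200, one third of the 600-volume session) censored volumes is removed
  from group analyses but remains in the QC report.

### Nuisance model and residuals

Each run's design matrix contains: HRF-convolved condition regressors
(canonical double-gamma HRF, peak 6 s, undershoot 16 s, ratio 6 — the
modeling software's conventional kernel, since no parameters are printed);
the 24-column Volterra motion expansion R_t, R_t², R_{t−1}, R_{t−1}²
(lagged columns take 0 at the first frame rather than discarding it); the
white-matter and ventricle mean signals (supplied as column series — mask
erosion is the data provider's concern); one indicator per censored
volume; and an intercept + linear drift block, which is harmless given
the later band-pass but stabilizes the fit. Residuals are ordinary least
squares with an SVD pseudoinverse (rank-deficiency tolerant) and one
iterative-refinement pass, which brings residual–design orthogonality to
machine precision; censored-frame residuals are exactly zero by
construction and are additionally zeroed against round-off. Prewhitening
(the original software's AR model) is deliberately not reproduced.

### Band-pass filter

The retained band is 0.009–0.08 Hz. The filter is zero-phase and applied
in the frequency domain with a 4th-order Butterworth *magnitude* response
(product of low-pass and high-pass half-responses); this deviates from
the "recursive filter" wording of the original design note because a
zero-phase FFT filter satisfies the same transfer-function contract
(≥ 99 % retention at 0.04 Hz, ≈ 8 % at 0.15 Hz, 0 at DC), is exactly
linear, and has no warm-up transient. Filtering is per run, before
concatenation: applying one filter across run boundaries would smear edge
artifacts between runs. Whether the original applied it per run or to the
concatenated series is ambiguous; per-run is the default here.

### Seed maps

The seed series is the unweighted mean over the union of the two seed
spheres (not a mean of per-hemisphere means). Voxel membership is by
voxel-center distance under the affine — deterministic and
partial-volume-free. Correlations use pairwise-complete retained frames;
omitting censored frames is, for a correlation, equivalent to the
original's spike-regressor absorption in a first-level model and much
simpler. |r| is clipped at 1 − 10⁻⁷ before atanh; zero-variance voxels
(possible in synthetic backgrounds) return z = 0 with a QC flag rather
than an error.

## 2. Group inference

Step 1 fits, at every voxel, z ~ outcome + age + illness duration +
baseline severity (covariates chosen because remitters and non-remitters
differ on them), with the remitter−non-remitter contrast tested one-sided
at a cluster-forming threshold of p < 0.001 (the conventional default —
the original protocol states only the cluster-level α, not the forming threshold;
both are exposed in `permutation_config()`). Clusters are contiguous
supra-threshold voxels under 26-connectivity (configurable to 18 or 6).

Family-wise error control is by permutation of the maximum cluster
extent — not random-field theory — because it is self-contained and
assumption-light: the Freedman–Lane scheme permutes the rows of the
reduced-model (covariates-only) residuals, adds them back to the reduced
fit, recomputes the statistic map, and records the maximum extent; the
cluster p is (1 + #{permuted maxima ≥ extent}) / (n_perm + 1). At the
default α = 0.001, at least 999 permutations are required for the minimum
attainable p to reach the threshold. The differential (drug-interaction)
model adds antidepressant main effects and outcome×drug columns and tests
the interaction block with a partial F statistic under the same
permutation scheme. Peak tie-breaks go to the smallest linear index.

Two numerical notes. First, max-extent permutation p-values are mildly
conservative because extents are small integers with heavy ties; the
calibration test uses a liberal forming threshold and face-adjacency so
the Monte-Carlo check is informative. Second, under a strong true effect
the permuted datasets inherit effect-sized variance (the reduced-model
residuals contain the outcome effect), so null maxima are larger than
under a pure null — an inherent property of Freedman–Lane, relevant when
interpreting borderline retention.

Step 2 extracts each subject's mean z over a retained cluster, compares
each patient group to controls by dummy-coded regression with age as
covariate (an ANOVA would obscure the hypothesis that one subgroup
resembles controls), reports Cohen's d = t·√(1/n₁+1/n₂) from the adjusted
contrast, and runs paired pre/post t tests per group. Summary-statistic
pooled t tests audit printed descriptive tables.

## 3. Classification

Remission is week-8 HRSD₁₇ ≤ 7 (eligibility requires baseline ≥ 16). The
classification ROI is the intersection of a supplied binary map with a
10 mm sphere at the anterior peak — the meta-analytic map retrieval
itself is out of scope, and the synthetic pipeline supplies the planted
target region as the map. Connectivity is mean-centered, scaled by its
SD, and added to a covariate-only logistic model; the added value is the
deviance-difference likelihood-ratio χ² with df = number of added
parameters (by convention even when the added column is degenerate), and
the Wald statistic is coefficient/SE, treated as a z. Complete separation
is detected and flagged, never silently returned.

ROC curves sweep all score thresholds; AUC is the trapezoid rule (equal
to pairwise concordance). The operating point is Youden-optimal by
default, with a fixed-0.5 alternative; the original reports its
accuracy/sensitivity/specificity triplet without stating a rule, so both
are available. Leave-one-out cross-validation refits everything —
including the centering/scaling parameters — on each training fold.

One correction deserves emphasis: pooled leave-one-out *probability*
scores are sharply pessimistic for AUC, because each fold's intercept
tracks the training fold's class balance, which is anti-correlated with
the held-out label; on null data the pooled-score AUC averages far below
0.5. The cross-validated ROC therefore uses prior-corrected scores — the
held-out linear predictor minus the training fold's base-rate logit —
which removes exactly that fold artifact while leaving genuine signal
intact. Raw held-out probabilities are kept for the fixed-0.5 accuracy
figures, which are unaffected by the issue in the same way and match the
convention of not optimizing a threshold on test scores.

Specificity analyses regress connectivity on each baseline characteristic
(anxiety score, comorbid-anxiety flag, early-life stressors, body-mass
index, cognitive score) and test, per characteristic, whether
connectivity still adds predictive power when entered after it.

## 4. The synthetic cohort: what a green test establishes

The generator plants the statistical structure the analysis assumes, with
defaults stating the emulated study: 38 non-remitters / 37 remitters / 31
controls; five 120-volume runs at TR 2.5 s per session; seed and target
coordinates as above; planted seed–target correlation ρ = 0.6 for
controls and remitters versus 0.15 for non-remitters; at follow-up the
non-remitter ρ rises by 0.2 without reaching remitter levels (the
"hypo-connectivity attenuates" pattern as a testable planted effect).

**Effect-size bookkeeping.** Between-subject variability of true
connectivity on the Fisher-z scale is `subject_sd_z` = 0.45 in total per
voxel, split into a region-shared component (≈ 0.335) and a voxel-level
component (`voxel_sd_z` = 0.3): individual connectivity maps differ voxel
by voxel, not only regionally, and a generator without voxel-level
heterogeneity creates a degenerate permutation null in which any null
draw that fires the region ties the observed extent exactly, making
FWE p ≤ 0.001 unattainable by construction. With the chosen split, the
planted gap atanh(0.6) − atanh(0.15) ≈ 0.54 is a **voxel-level d of
≈ 1.2** — the scale on which the voxel-wise Step-1 analysis operates —
while region-averaged (cluster-extracted) values show d ≈ 1.6, inside the
recovery band the planned-comparison tests assert. `planted_cohens_d()`
exposes both.

**BOLD construction.** Per run, a unit-variance band-limited (0.01–0.08
Hz) latent s(t) drives the seed; target voxels receive ρᵥ·s +
√(1−ρᵥ²)·u with u orthonormalized to s *in sample*, so with zero noise
the realized seed–target correlation equals ρ exactly (band-limited
series have only ~200 effective degrees of freedom per session, so
without this the sampling wobble alone would exceed the generator's
stated recovery tolerance). Task responses (20 s blocks, canonical HRF,
default amplitude 2 % of the fluctuation scale — large enough to matter,
small enough not to trip the intensity censoring), two global tissue
signals, voxel noise (`noise_sd`, in latent-SD units; note voxel noise
*attenuates* measured correlations relative to planted ρ — that
attenuation is part of the stated world, and the zero-noise contract is
what pins the generator), a baseline intensity of 1000 units, and motion
traces with thinned-Bernoulli spikes (rate λ/volumes per frame, 0.5 mm
steps, drift far below the FD threshold) complete the runs.

**Geometry.** The default grid is 24×42×24 voxels at 3 mm. A smaller
grid cannot hold the real coordinates: the world span from the left seed
sphere's lower edge (y = −57) to the ROI sphere's upper edge (y = 60) is
117 mm, which requires at least 40 voxels in y. `toy_cohort_spec()`
provides a compact self-consistent world (14×16×14, synthetic nearby
centers) for fast end-to-end tests.

**Scaled-down group world.** BOLD-level simulation of the full cohort is
deliberately out of reach on a desk (terabytes); `simulate_zmap_cohort()`
draws each subject's z-map directly from the same planted model (target
voxels: true z + estimation noise 1/√(n−3); background: estimation noise
only), and is the world in which the permutation-retention and
classification acceptance criteria run at full sample size.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: spatial autocorrelation and smoothness of real
fMRI, physiological noise, scanner drift structure beyond linear,
image-intensity artifacts coupled to motion spikes (censoring recovery is
tested through FD only), multi-site effects, and any real anatomy. The
acceptance suite shows the *machinery* is correct and calibrated, not
that the clinical effect would replicate.

## 5. Known limitations and degenerate inputs

* Real-data headline numbers (cluster extent 2880, peak Z 4.52, the
  ROC triplets, Δχ² = 16.55, the 498-voxel meta-analytic mask) are not
  reproducible without the non-public clinical data and the exact
  retrieved map; they are excluded as numeric targets by design.
* Permutation inference will not numerically match parametric
  random-field results even on identical data.
* The retention rate of criterion-level power simulations sits within a
  few percent of its bound at the stated world; realized-cohort
  variability at n = 75 is the binding factor.
* Degenerate inputs: constant voxel series → flagged z = 0; constant
  classifier scores → AUC 0.5 with a degenerate-curve flag; single-class
  training folds → flagged, subject score missing; perfectly separating
  predictors → separation flag; empty cluster sets at the forming
  threshold → empty list, not an error.
* Configuration is serialized as JSON (no YAML parser is assumed in the
  runtime environment); the manifest captures every stage's parameters
  and seeds and suffices to re-execute any stage.
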