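---
title: "Methods: individualized quantitative-MRI lesion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized quantitative-MRI lesion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`qmlm` implements single-subject quantitative-MRI postprocessing for
MRI-negative focal epilepsy: each patient's quantitative maps are compared
voxelwise against a healthy control cohort, suprathreshold voxels are
grouped into clusters, non-parenchymal findings are discarded, and the
surviving clusters are scored for lobe-level agreement with the
electroclinical hypothesis of the epileptogenic zone. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic phantom does and does not establish about behaviour on
real data.

# Quantitative maps

## T2 relaxometry

The multi-echo signal is modelled as a voxelwise mono-exponential,
`S(TE) = S0 exp(-TE/T2)`, fitted by unweighted ordinary least squares of
`ln S` on `TE`. The log-linear estimator is exact on noiseless data and is
the standard fast estimator for clinical echo trains; a weighted or
nonlinear fit would change variance properties but not the interface, and
is deliberately not the default.

Fit validity is explicit rather than silent: a voxel is dropped from the
valid mask (and set to the sentinel value -1) when any echo signal is
nonpositive, when the fitted slope is nonnegative (non-decaying), or when
the fitted T2 exceeds `t2_max` (default 1000 ms). The ceiling reflects an
estimability limit, not a prior belief about tissue: with echoes at
20-100 ms, a CSF-like T2 of ~2000 ms leaves the regression slope within
noise of zero, and the reciprocal transform turns that noise into unbounded
outliers which would otherwise dominate smoothed maps and z-denominators.
Because the cohort test mask is the intersection of all subjects' valid
masks, the ceiling effectively restricts T2 testing to parenchyma, which is
where the method looks for lesions anyway.

## MTR

`MTR = (MToff - MTon)/MToff * 100`, in percent. Voxels with `MToff <= 0`
are undefined and excluded from testing rather than divided through.

## Gray-white junction signal (WGJS)

Five steps: (1) tissue probability maps are taken as input; (2) binary GM
and WM masks keep voxels with probability above 0.9; (3) the junction mask
is every brain voxel whose T1-weighted intensity lies in
`[mean_GM - SD_GM, mean_WM + SD_WM]`, with means and SDs estimated from
this subject's own masks — per-subject statistics make the rule invariant
to global intensity scaling, which is why the raw (non-normalized) T1
volume is used; (4) the binary mask is convolved with a unitary 5x5x5
kernel, so each voxel carries the count (0-125) of junction voxels in its
neighborhood; (5) the convolved map enters the shared z-score engine.
Convolution uses zero padding; the junction mask does not touch the grid
border on any realistic brain volume, so the border convention is
documentation rather than behaviour.

# Detection engine

All measures share one chain: Gaussian smoothing, voxelwise z-scores
against the control cohort, significance thresholding, cluster-extent
filtering, parenchyma filtering.

* **Smoothing** uses a separable discrete Gaussian with
  `sigma = FWHM/(2 sqrt(2 ln 2))` per axis, converted to voxels by the
  voxel size. Within a mask the convolution is renormalized by the
  smoothed mask, so zeros outside the brain do not dilute edge voxels and
  a constant map stays constant inside the mask.
* **z-scores** are plain `(x - mean)/sd` with the cohort's voxelwise
  sample SD. With small cohorts this statistic is anticonservative
  relative to a proper single-subject t (the Crawford-Howell style
  `sd * sqrt(1 + 1/n)` inflation is available via `n_adjusted = TRUE`);
  the package keeps plain z as the default because the false-positive
  calibration step, not the nominal p-value, is what controls the
  operating point. Voxels with zero cohort SD are undefined and never
  counted as tests.
* **Thresholding** converts z to standard-normal p-values (two-sided by
  default, since lesions can raise or lower any of the measures) and
  applies one of: uncorrected `p <= alpha`; Benjamini-Hochberg FDR at
  level `q` (step-up cutoff over the tested voxels); or Bonferroni
  `p <= alpha/m`. Bonferroni stands in for random-field FWE deliberately:
  it is reproducible without random-field machinery and conservative,
  and the calibration layer compensates for threshold severity by
  adjusting the cluster extent.
* **Clustering** uses 26-connectivity by default (6 and 18 are options and
  are recorded with every result); the extent minimum `k` discards small
  clusters. Surviving-cluster computation commutes with the extent filter,
  which the calibration code exploits by thresholding once per p-setting
  and re-filtering sizes per `k`.
* **Parenchyma filter**: clusters whose peak voxel lies on an excluded
  atlas label (background, CSF, ventricle, brainstem, cerebellum — any
  label with lobe `"none"`), or whose peak is farther than
  `cortex_distance_mm` (default 5 mm) from the nearest GM voxel, are
  removed. No distance for "distant from the cortex" is standard in the
  literature; 5 mm keeps face-adjacent and most diagonal WM neighbours of
  the ribbon at 3 mm voxels while excluding deep white matter, and is
  configurable.

# False-positive calibration

Every control is compared against the remainder of the cohort
(leave-one-out; the excluded subject's mean/SD are recomputed from sums, so
the cost is linear in cohort size). A control is a false positive when at
least one cluster survives the full chain. The parameter grid crosses the
three p-modes (uncorrected 0.001, FWE 0.05, FDR 0.05) with a ladder of
extent minima; among grid points achieving the target rate (default 10%),
the smallest cluster extent wins — the lowest cluster threshold that still
controls false positives — tie-broken by the less restrictive p-setting
(uncorrected, then FDR, then FWE, then larger p), then grid order. The
tie-break beyond the extent rule is a determinism device, not a scientific
claim. The default extent ladder extends to 600 voxels so that the search
space always contains admissible points even for anticonservative
statistics; the chosen extent is reported, never assumed.

# Concordance scoring

Clusters are assigned the (lobe, side) of their peak voxel — peak-based
localization matches how neuroimaging findings are reported — with a
majority-vote fallback over cluster voxels when the peak sits on excluded
tissue. A cluster is concordant when its (lobe, side) matches any region of
the EZ hypothesis; a region with side `"unlateralized"` matches either
hemisphere (chosen because video-EEG frequently regionalizes without
lateralizing; the rule is explicit and logged). Patients without a
suspected focus location (NSLF) receive `NA` verdicts — concordance is
undefined, not negative. Subject-level calls are `concordant`,
`discordant_only`, `no_findings`, or `NA_NSLF`; cohort tables report
positives and concordant counts per measure with measure-specific
denominators, so postprocessing failures leave the denominator.

# The synthetic phantom

The generator emulates exactly the statistical structure the analysis
assumes, and no more:

* geometry: concentric smoothed ellipsoids — ventricular CSF core, WM
  interior, GM ribbon, CSF rim — on a 48x56x48 grid at 3 mm isotropic
  (~46k brain voxels); lobes are octants (frontal/temporal/parietal/
  occipital x left/right) of the parenchyma;
* signals: per-tissue means and between-subject SDs for T2, S0, MT
  saturation fraction, proton density, MD, T1 intensity and cortical
  thickness; echoes follow `S0 exp(-TE/T2)` and the MT pair follows
  `MTon = MToff (1 - f)` before noise. Defaults are literature-typical 3T
  values (e.g. GM T2 100 +/- 5 ms, WM 80 +/- 4 ms, WM MT saturation 0.45,
  MD in units of 1e-3 mm^2/s), chosen once as a realistic operating point;
  the acquisition parameters of the emulated protocol fix the TE ladder at
  20-100 ms;
* between-subject variability: one unit-variance Gaussian random field per
  channel per subject, smoothed to 12 mm FWHM and scaled by the tissue SD —
  the simplest structure giving a spatially smooth, nonzero cohort SD;
* noise: additive Gaussian per channel (Rician available as an option for
  the magnitude channels; at the default SNR of ~100 the difference is
  negligible);
* lesions: spheres that offset one latent channel by `delta` local
  between-subject SDs; observed volumes are re-derived from the frozen
  noise realization, so untargeted channels and out-of-sphere voxels are
  bit-identical — which is what makes channel-isolation and
  effect-size-recovery properties testable exactly.

What the phantom does **not** contain: cortical folding, partial-volume
structure beyond smoothed tissue boundaries, registration error, bias
fields, motion, or realistic lesion morphology. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline* under its own
statistical assumptions — they do not certify sensitivity or specificity on
clinical data, where registration and segmentation quality dominate.

Determinism is per subject: subject *i* of a cohort is drawn from RNG seed
`seed + i`, so cohorts are reproducible and extensible without
regenerating earlier subjects.

# Numerical choices and degenerate inputs

* T2 sentinel -1 with an explicit valid mask, never clamping.
* Zero cohort SD yields undefined z (excluded from testing); a fully
  degenerate cohort flags nobody.
* The FDR cutoff is 0 when nothing passes; only exact-zero p-values are
  then rejected.
* Smoothing normalizes the interior variance of generated random fields
  analytically; edge voxels of the field are slightly under-dispersed,
  which slightly lowers edge z-variance symmetrically in patient and
  cohort.
* Cluster ordering is by size descending; ties keep discovery order, and
  selection among calibration grid points is fully deterministic.

# Problem sizes

The shipped tests exercise: unit oracles on 12-16 voxel grids (bit-exact
brute-force comparison, 100 random instances per operation); calibration on
ten independent 30-control cohorts at full 48x56x48 resolution; and lesion
recovery (5-SD, ~170-voxel spheres against 20 controls, uncorrected
p <= 0.001, k = 30) over 20 seeds. These sizes were chosen to make the
whole suite comfortably runnable on a laptop while keeping the cohort sizes
of the emulated study design.

# Known limitations

* Random-field FWE is not implemented; Bonferroni plus extent calibration
  replaces it by design.
* Covariate adjustment (age, sex) in the control model is out of scope.
* Thickness is treated as a voxelwise scalar on the GM ribbon; surface
  (vertex-wise) statistics are a non-goal, so thickness findings inherit
  the volumetric engine's smoothing behaviour.
* The lobe atlas of the phantom is geometric, not anatomical; concordance
  logic is exercised fully, but lobe boundary placement is synthetic.
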