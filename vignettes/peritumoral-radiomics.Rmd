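---
title: "Peritumoral radiomics for distant-metastasis risk: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral radiomics for distant-metastasis risk: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

periomics studies a specific clinical question: does the CT appearance of
the *normal-looking lung tissue around* a tumor carry prognostic
information about distant metastasis (DM), beyond what the visible tumor
itself shows? Pathology gives this question teeth — lung adenocarcinoma
spreads through vasculature, lymphatics and airspaces of the surrounding
parenchyma, so microscopic disease often sits just outside the delineated
gross tumor volume. The package implements the full analysis chain needed
to ask that question quantitatively, and a synthetic phantom cohort
generator so the chain can be validated end to end without patient data.

## The analysis chain

1. **Region construction** (`make_rim()`, `make_exterior()`,
   `region_set()`). From a tumor mask and a lung mask, two peritumoral
   regions are built in physical units: the *rim* (3 mm inside to 3 mm
   outside the tumor boundary; the extratumoral part restricted to lung
   tissue, the intratumoral part kept unconditionally) and the *exterior*
   (lung tissue 3–9 mm outside the tumor). Morphology is implemented by
   thresholding the exact Euclidean distance transform between voxel
   centres rather than by voxel-count structuring elements, because planning
   CT grids are anisotropic (typically ~1 × 1 × 2.5 mm) and the band widths
   are specified in millimetres. Distances exactly equal to a threshold are
   included; a voxel survives erosion iff its centre is more than the inner
   width from the nearest background voxel centre. Regions are built on the
   native grid; resampling happens afterwards, at feature-computation time.

2. **Image preparation** (`resample_isotropic()`, `discretize()`,
   `log_filter()`, `wavelet_subbands()`). Images are resampled to an
   isotropic 3 mm grid (trilinear for intensities, nearest-neighbour for
   masks) and discretized with a 25 HU bin width. Bins are anchored at
   absolute multiples of the bin width, not at the region minimum: that
   makes gray levels comparable between test and retest replicates, which
   the stability stage requires. Derived images are Laplacian-of-Gaussian
   responses at 0.5/1.5/2.5/3.0 mm (scale-normalized, separable, mirror
   padding, exactly zero response to constants) and the 8 sub-bands of a
   one-level undecimated Coiflet-1 wavelet decomposition, labelled by
   per-axis L/H letters in (x, y, z) array order. Filters run on the
   resampled grid so a physical sigma is isotropic in voxels.

3. **Feature extraction** (`extract_features()`). Per region and filter:
   8 first-order statistics (median, minimum, range, Pearson kurtosis,
   mean, population SD, energy, histogram entropy in bits), GLCM
   difference entropy, GLRLM run entropy, and the five NGTDM features
   (complexity, strength, coarseness, busyness, contrast). Texture
   matrices use the merged-matrix convention: co-occurrence and run counts
   are summed over the 13 unique 3D directions before normalization; the
   co-occurrence distance is 1 voxel; NGTDM uses the full 26-neighbourhood
   with partial neighbourhoods at mask borders included. All entropies are
   base-2 with the 0·log 0 = 0 convention and no epsilon constants.
   Regions with fewer than 2 voxels yield missing values, never errors.

4. **Feature selection** (`stability_filter()`, `mrmr_rank()`). Features
   must first survive a test–retest stability filter: ICC(2,1) (two-way
   random effects, absolute agreement, single measurement) computed on
   replicate scans, with threshold 0.85. The survivors are reduced to 15
   per region by greedy minimum-redundancy-maximum-relevance ranking using
   plug-in mutual information against the binary DM event status, with the
   additive (difference) criterion and equal-frequency quartile
   discretization of continuous features. Exact score ties break
   lexicographically so the ranking is deterministic.

5. **Modelling and inference** (`concordance_index()`, `fit_cox()`,
   `build_signature()`, `compare_cindex()`, `stratify()`). Univariable
   prognostic value is measured by Harrell's concordance index with a
   Noether-type test against CI = 0.5 and Benjamini–Hochberg FDR control.
   Signatures are built by forward selection in mRMR order: each prefix is
   scored by repeated stratified 70:30 subset validation on the training
   split (Cox fit on 70 %, concordance on the held-out 30 %, event
   fraction balanced between parts), and growth stops at the first prefix
   whose mean CV concordance does not exceed its predecessor's — equal
   means prefer the smaller model. The chosen signature is refitted on the
   full training split. Models are combined by fitting a Cox model on the
   component models' linear predictors. Validation statistics (concordance,
   paired model comparisons, median-split Kaplan–Meier with log-rank test
   and hazard ratio) are computed exclusively on the held-out split, with
   the risk cutoff fixed at the training median.

## Statistical conventions worth knowing

* **Comparable pairs.** A patient pair enters the concordance only if the
  earlier time is an event. An event tied in time with a censored
  observation counts as earlier; two events at the same time are not
  comparable. Tied risk scores score 0.5.
* **Noether-type inference.** The variance of the concordance U-statistic
  is estimated by the leave-one-subject-out jackknife of per-subject pair
  contributions. The same per-subject contributions give the paired
  one-sided test used by `compare_cindex()`; its type-I error is verified
  by simulation in the test suite rather than assumed.
* **Cox fitting.** `fit_cox()` uses Breslow tie handling (Efron behind a
  flag) via the survival package; the single-covariate solution is checked
  in the tests against a grid search over the directly evaluated partial
  likelihood. Singular or unconverged fits are flagged, not raised, so
  cross-validation loops can redraw degenerate splits.
* **Risk orientation.** Higher linear predictor means higher hazard and
  shorter expected time to DM, so CI > 0.5 is predictive. The univariable
  screen reports the raw CI, the folded `ci_oriented = max(CI, 1 - CI)`,
  and the direction flag ("Prop."/"Inv."), because inversely proportional
  features are as interesting as proportional ones.

## The phantom generator

`phantom_spec()` / `generate_cohort()` produce a seeded cohort of 200
synthetic thoracic CT patches split half/half into a training and a
validation half: a soft-tissue body cylinder (~30 HU), two lung
ellipsoids (~-800 HU), and one ellipsoidal tumor (~0 HU, radius 5–11 mm)
abutting the lateral lung wall so that the extratumoral rim genuinely
mixes parenchyma with non-lung tissue and the lung-mask restriction does
real work.

The prognostic mechanism is a per-patient latent aggressiveness score
`z ~ N(0,1)`:

* **Texture.** Spatially correlated Gaussian fields (2 mm correlation
  length) are added inside three disjoint shells — the true 6 mm rim
  shell, the tumor core, and the 3–9 mm exterior band — with amplitude
  `60 HU × exp(effect × z)`. The default effect sizes are 1.0 (rim),
  0.4 (tumor core) and 0 (exterior): heterogeneity around the invasive
  front carries most of the signal, the tumor core some, the exterior none
  beyond partial-volume bleed-over, which mirrors the empirically weak
  exterior signal such studies report. With an effect of 0 the amplitude
  is exactly independent of `z` by construction.
* **Outcomes.** Time to DM is exponential with hazard
  `0.05/month × exp(0.7 z + β'·clinical)` (clinical covariates centred),
  censored by an independent uniform time on (0, 72) months; this yields
  roughly two-thirds observed events and a median time to DM near one
  year, matching the cohort profile the package is designed around.
  Clinical covariates (age, gender, overall/T/N stage, performance
  status, tumor size) are sampled with realistic marginals for a locally
  advanced adenocarcinoma cohort and carry deliberately weak log-hazards,
  so the clinical model hovers just above chance — the regime in which the
  incremental value of imaging is actually interesting.
* **Acquisition realism.** The noiseless anatomy is blurred by a 1 mm
  scanner PSF before noise is added. This matters more than it looks:
  with an infinitely sharp -800 → 0 HU tumor edge, edge-adjacent features
  become pathologically sensitive to sub-voxel repositioning, and the
  stability filter then removes exactly the informative features — the
  opposite of what is observed with real scanners, where signature
  features are test–retest stable. The 60 HU texture amplitude is in the
  range of visible peritumoral ground-glass/spiculation changes and was
  chosen so the best region features reach univariable concordances
  around 0.6–0.65, the magnitude typically reported for CT radiomics DM
  signatures.
* **Test–retest replicates.** `generate_retest_pair()` rebuilds both
  scans from the stored noiseless template: fresh 10 HU white noise each,
  plus a rigid 1.25 mm shift of the second scan (masks shifted
  consistently). With zero noise and zero shift the replicates are
  bit-identical and every ICC is exactly 1 — a useful degenerate check.

What the phantom does *not* emulate: respiratory motion, contrast
enhancement, airway/vessel trees, multi-lesion disease, non-exponential
hazards, informative censoring, and inter-scanner protocol variation.
Passing the end-to-end tests therefore shows the *pipeline* recovers a
known peritumoral signal under controlled conditions; it says nothing
about effect sizes in any real cohort.

## Numerical choices and degenerate inputs

* Distance-transform morphology is exact (Felzenszwalb-style separable
  lower envelope) and tested for voxel-set equality against brute-force
  distance computation on anisotropic grids.
* Mirror padding for every convolution, so volume borders do not leak step
  artifacts into rim features.
* The wavelet family defaults to Coiflet-1; only the sub-band labels, not
  the family, are fixed by the feature-name schema, and the letter order is
  documented as (x, y, z) with H = high-pass.
* Empty regions, all-censored outcome sets, constant covariates, collinear
  model combinations and degenerate stratifications (all validation
  patients on one side of the cutoff) are all explicit, tested error or
  fallback paths.
* One root seed drives every stage through a documented derivation
  (`seed × 7919 + stage × 1009 mod 2^31-1`), so a study is reproducible
  bit-for-bit including its 70:30 resampling streams.

## Problem sizes used by the validation studies

The multi-seed end-to-end checks in the test suite run 200-patient
cohorts (100 training / 100 validation) with a reduced filter bank
(original, LoG 1.5 mm, LoG 3 mm, wavelet LHL) and 100–200 cross-validation
repetitions per prefix, ten seeds per scenario; the acceptance script runs
the full default filter bank with 200 repetitions. These sizes keep a full
multi-seed validation campaign in the tens of minutes on a single core
while leaving every stage of the method exercised; the forward-selection
behaviour at 1000 repetitions is identical in expectation, only the Monte
Carlo error of the mean CV concordance changes.

## Known limitations

* The feature catalogue is the named subset above, not a full radiomics
  platform; size-zone and dependence matrices (GLSZM/GLDM/GLDZM) are out
  of scope.
* 2D (slice-wise) texture modes, multi-level wavelets and voxel-wise
  feature maps are not implemented.
* The mRMR relevance target is the binary event indicator; with ~100
  training patients the mutual-information estimates are noisy, and the
  ranking of weakly informative features is correspondingly unstable —
  visible in the phantom studies as seed-to-seed variability of the
  selected signatures, and a faithful property of the method rather than a
  defect of the implementation.
* `compare_cindex()` uses jackknife inference; alternative variance
  estimators exist and give slightly different p-values in small samples.
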