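# periomics

Peritumoral radiomics modelling of distant-metastasis risk in lung cancer.

## The problem

In locally advanced non-small-cell lung cancer, the parenchyma immediately
around the tumor often harbours microscopic disease — spread through
vessels, lymphatics and airspaces — that the delineated gross tumor volume
does not capture. periomics asks whether the CT *texture* of that
normal-appearing peritumoral tissue predicts time to distant metastasis
(DM), and whether it adds prognostic value over tumor-only radiomics and
clinical covariates. It is written for imaging scientists and
biostatisticians who want the whole chain — region geometry, filtered
texture features, stability/relevance selection, survival modelling — as
tested, reusable R functions rather than a monolithic pipeline script.

Two tissue shells are analysed alongside the tumor itself:

* **rim** — 3 mm inside to 3 mm outside the tumor boundary (the invasive
  front), extratumoral part restricted to lung tissue;
* **exterior** — lung tissue 3–9 mm outside the tumor contour.

## The method

For each region *r* and patient *i*, a feature vector is extracted from
the 3 mm-resampled, 25 HU-discretized CT (first-order statistics, GLCM
difference entropy, GLRLM run entropy, NGTDM complexity/strength/…, over
the original, Laplacian-of-Gaussian and wavelet-filtered images). Features
are kept if test–retest stable (ICC(2,1) > 0.85), reduced to 15 by
mutual-information mRMR against DM status, and screened univariably with
Harrell's concordance index

C = Pr(risk_i > risk_j | patient with the earlier event among a comparable
pair), tested against C = 0.5 by a Noether-type jackknife test with
Benjamini–Hochberg FDR control.

A region *signature* is built by forward selection in mRMR order: each
prefix is scored by the mean validation concordance over repeated
stratified 70:30 splits of the training half (Cox proportional hazards,
Breslow ties), stopping at the first non-increase. Signatures and the
clinical Cox model are combined through their linear predictors, compared
pairwise with a paired jackknife concordance test, and assessed by
median-risk Kaplan–Meier stratification (log-rank test, hazard ratio) on
the held-out validation half.

Because no patient data ship with the package, a seeded phantom module
generates synthetic thoracic CT cohorts in which a latent aggressiveness
score drives both the rim texture heterogeneity and the DM hazard — so
every stage, and the headline claim (rim > tumor > exterior prognostic
ordering), can be validated end to end. See the methods vignette
(`vignettes/peritumoral-radiomics.Rmd`) for the model and every numerical
convention.

## Worked example

```r
library(periomics)

study <- run_study(study_config(
  phantom = phantom_spec(),        # 200 patients, 100 train / 100 validation
  cv_reps = 200, seed = 1
))
study
```

```
<periomics_study>
Validation concordance (split B):
               model        ci         se          p   n
               tumor 0.5625879 0.03509324 0.07450904 100
                 rim 0.5909517 0.03678427 0.01341451 100
            exterior 0.5203938 0.03672929 0.57872602 100
            clinical 0.5084388 0.03280332 0.79698191 100
      clinical+tumor 0.5243788 0.03488738 0.48468590 100
        clinical+rim 0.5473511 0.03524817 0.17915394 100
   clinical+exterior 0.5196906 0.03495835 0.57325908 100
 composite_radiomics 0.5832161 0.03624545 0.02168128 100
```

The rim signature is the only single-region model significantly better
than chance on the held-out half (CI 0.59, p = 0.013), the tumor model is
weaker (0.56), and the exterior band carries little signal (0.52) — the
phantom's ground truth, recovered by the pipeline. The paired comparison
confirms the ordering:

```r
dplyr::filter(study$comparisons, model_a == "rim", model_b == "exterior")
#>   model_a  model_b    ci_a    ci_b   delta p_a_greater
#>       rim exterior   0.591   0.520  0.0706      0.0456
```

Individual stages are ordinary functions on tables and arrays:

```r
co   <- generate_cohort(phantom_spec(n_patients = 4, seed = 7))
p    <- co$patients[[1]]
regs <- region_set(p$tumor_mask, p$lung_mask)   # rim + exterior geometry
regs
#> <region_set> tumor 639 | rim 1193 | exterior 2960 voxels
feats <- extract_region_features(p$image, regs)  # 3 regions x 195 features
glance(fit_cox(co$table["latent_score"], co$table[c("time", "event")]))
```

`autoplot()` methods draw the validation-CI panel and Kaplan–Meier
stratification curves; `tidy()`/`glance()` turn fitted models into tibbles.

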