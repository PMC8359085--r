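---
title: "AEF texture analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AEF texture analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeftex)
```

## The problem and the quantity at the core

Hepatocellular carcinoma (HCC) progressively shifts its blood supply from
the portal vein to newly formed arteries ("arterialization"). Because
transarterial chemoembolization (TACE) works by embolizing exactly those
feeding arteries, the spatial pattern of arterialization inside a lesion is
a plausible predictor of treatment response. Three-phase contrast-enhanced
CT lets one estimate that pattern voxel by voxel through the **arterial
enhancement fraction**

$$\mathrm{AEF} = \frac{\mathrm{CT_a} - \mathrm{CT_u}}{\mathrm{CT_p} - \mathrm{CT_u}},$$

the arterial share of the portal-phase enhancement (CT~u~, CT~a~, CT~p~:
unenhanced, arterial and portal attenuation in HU). The package computes
AEF maps, extracts a fixed catalogue of 32 texture features from the lesion
region of interest (ROI), and carries them through the complete radiomics
signature workflow: univariate group comparisons, redundancy filtering,
LASSO selection, multivariate logistic modeling, scoring with two published
fixed-coefficient models, and ROC / calibration / decision-curve
evaluation.

## The AEF stage

`compute_aef_map()` evaluates the ratio pixelwise. Two numerical guards are
needed because the denominator is a noisy difference:

* **epsilon** (default 1 HU): a voxel is *valid* only when its portal
  enhancement CT~p~ − CT~u~ exceeds epsilon. 1 HU rejects division by pure
  noise while keeping genuinely portal-enhancing tissue. Invalid voxels are
  carried as `NA` and **excluded** from every downstream statistic —
  zero-filling would fabricate gray levels.
* **clip_range** (default `[0, 4]`): negative ratios (arterial
  de-enhancement) clip to 0; 4 is a generous physical ceiling, several
  times the lesion means seen in practice (≈ 0.85–1.55).

AEF is invariant to adding a constant to all three phases and to scaling
both enhancements by a common positive factor; both invariances are tested
to 10⁻¹².

`align_phases()` provides a deliberately simple rigid alignment: an
exhaustive search over integer shifts (± `max_shift` voxels per axis)
minimizing the mean squared difference against the unenhanced grid on the
overlap. Deformable registration is out of scope; for phantom work integer
translation is the only misalignment mode worth modelling, and the
exhaustive search is its own oracle.

## The 32-feature catalogue

Features are computed in 2D on the ROI's **largest axial plane** (ties go
to the lower plane index), matching the single-plane ROI convention, with
tumor area = pixel count × pixel size.

* **11 intensity statistics** on the raw AEF values: order statistics,
  moments (standard deviation with the *n* − 1 denominator), pixel count,
  value sum, range, mean absolute deviation and the coefficient of
  variation.
* **5 histogram features**: skewness and excess kurtosis
  (population-moment form; both defined as 0 for a constant or
  single-pixel ROI), Uniformity = Σp², Entropy = −Σp log₂p over a 256-bin
  histogram, and Energy = Σp² over the 64-level quantization.
* **6 co-occurrence (GLCM) features** and **10 run-length (GLRLM)
  features** in the classical Haralick and Galloway(-extended)
  conventions: four directions {(0,1), (1,0), (1,1), (1,−1)} at distance
  1, symmetric co-occurrence counts, features averaged over directions.
  Out-of-ROI and invalid pixels contribute no pairs and break runs.

### Discretization choices

The commercial tool behind the original feature values does not publish
its discretization, so three knobs are fixed here and exposed in
`texture_config()`:

* `n_gray_levels = 64` for the matrices and Energy, with equal-width bins
  over the ROI's own min–max (the reported high-gray-level run emphases of
  order 10³ ≈ Ng² are consistent with about this many levels). A constant
  ROI maps wholly to level 1.
* `n_hist_bins = 256` for Uniformity/Entropy (reported entropies of 6–7
  bits need more than 2⁷ bins).
* `hist_range = c(0, 4)`: the 256-bin histogram is binned over the fixed
  default AEF clip range rather than each ROI's min–max. This was a
  genuinely open design point and the fixed range is the deliberate
  choice: with per-ROI min–max binning the histogram entropy becomes
  scale-free — acquisition noise alone spreads a *homogeneous* lesion over
  the full bin range — which blunts, and can even invert, Entropy's
  sensitivity to real arterialization heterogeneity. A fixed range makes
  Uniformity and Entropy comparable across subjects and monotone in
  heterogeneity. Setting `hist_range = NULL` restores min–max binning.

### Degenerate conventions

Constant ROIs would make several features 0/0. The package fixes:
dispersion features 0, Skewness = Kurtosis = 0, Uniformity = 1,
Entropy = 0, Correlation = HaralickCorrelation = 1 (all mass on the
diagonal at one level). These are contracts, not accidents, and are
tested.

HaralickCorrelation is computed as
$(\sum_{ij} i\,j\,p(i,j) - \mu_t^2)/\sigma_t^2$ with $\mu_t,\sigma_t^2$
the level-weighted marginal mean and variance. For a symmetric matrix this
coincides with the normalized Correlation; the published table prints
values near 10⁶ for this feature, which no level-weighted convention on
64 levels can reach, so the upstream tool evidently used a different
(unpublished) internal form — a known limitation when comparing absolute
magnitudes of this one feature.

All 16 matrix features and both matrix builders are verified against an
independent brute-force enumeration (direct loops over pixel pairs and
runs) on hundreds of random small planes to 10⁻¹⁰.

## The synthetic cohort generator

The patient data behind the original analysis are restricted, so the
package ships a generator whose defaults *are* the study conditions the
pipeline is exercised under:

* Grid 64 × 64 × 16 voxels at 0.8 × 0.8 × 3 mm — desk-scale but with the
  realistic in-plane/through-plane anisotropy of an abdominal CT.
* Background HU triple (55, 70, 105) for unenhanced/arterial/portal
  parenchyma; additive Gaussian noise (default 5 HU), independent across
  phases, which also exercises the AEF epsilon guard.
* Lesions are physically isotropic spheres (radius in in-plane voxels;
  default base radius 21 ≈ 8.9 cm² largest-plane area, inside the reported
  1.25–73 cm² range and near its mean). Patchy arterialization is realized
  by thresholding a Gaussian-smoothed random field at the within-lesion
  quantile, so `arterialized_fraction` is matched exactly and
  `cluster_scale` (the field's correlation length, physically isotropic)
  is a single interpretable granularity knob. With the default gains the
  strongly arterialized patches sit at AEF 90/60 = 1.5 and the rest at
  30/60 = 0.5, spanning the ~0.1–2 range seen on real maps.
* Cohorts: 22 vs 23 subjects for the Improved/Un-improved scheme, 31
  vs 14 for Un-worsened/Worsened. Responders receive
  `arterialized_fraction` +0.3 (0.2 → 0.5) and `cluster_scale` −1.5
  (3 → 1.5): more, finer-grained arterialized patches, i.e. more
  heterogeneous AEF. Per-subject jitter (fraction sd 0.06, log-scale
  cluster sd 0.15, radius sd 1 voxel, gain sd 5 HU) creates overlap
  between groups. These effect sizes were chosen once to reproduce the
  *qualitative* reported directions — lower Energy, higher Entropy, lower
  InverseDifferenceMoment in responders — since no quantitative
  description of lesion-level AEF spatial structure is available.
* All randomness flows from one master seed; subject *i* uses
  `seed + i`, so any subject regenerates in isolation and cohorts are
  bit-identical under a fixed seed. The generator restores the caller's
  RNG state.

What the generator does **not** emulate: liver anatomy, vessels, lipiodol
deposits, breathing motion, scanner spectra. Passing tests therefore
demonstrate correctness of the computational pipeline and the *direction*
of the heterogeneity effect under a controlled model — not clinical
performance on real patients.

## Statistical machinery

* Normality screening: plain one-sample Kolmogorov–Smirnov against a
  normal with the sample mean/sd (no Lilliefors correction — the simplest
  reading of the screening step); gate at α = 0.05 per group, overridable
  with `force_test`.
* Continuous comparisons: t test when both groups pass the gate, otherwise
  Mann–Whitney — exact when the smaller group has ≤ 10 observations and
  the pooled sample is tie-free, else the tie-corrected normal
  approximation. Mid-ranks are used for ties and rank means are always
  reported. All p two-tailed; no multiplicity correction in the
  univariate table.
* Categorical comparisons: chi-squared without continuity correction when
  all expected counts ≥ 5, Fisher's exact test otherwise (2 × 2 only).
* Redundancy filter: greedy elimination among pairs with Spearman
  |ρ| ≥ 0.9, dropping the feature with the weaker univariate association
  (larger Mann–Whitney p); alphabetical tie-break. The keep rule is this
  package's construction — the source analysis states only that redundant
  features were excluded.
* LASSO: `glmnet` over its descending penalty grid; penalty by minimum
  mean cross-validated binomial deviance (the most common default; a
  1-SE rule was the other candidate) over stratified 5-fold splits whose
  fold ids are built deterministically from the seed.
* Logistic refit: ordinary ML glm with Wald z / two-tailed p. Perfect
  separation is flagged (directly from fitted probabilities within 10⁻⁸
  of 0/1, since glm can converge before warning) and reported as a
  warning, not an error — notably, the published Improved-outcome model's
  own intercept shows z ≈ 0, p = 1.000, the signature of near-separation
  at n = 45, and the synthetic cohorts reproduce exactly this behaviour.
* Standardization: (x − mean)/sd with the sample (n − 1) sd, recorded per
  feature for scoring new subjects; applied before the (rank-based, hence
  unaffected) redundancy filter.

## Published models

The two fixed-coefficient logistic models ship as JSON resources
transcribed from the published coefficient table: Model A (9 terms,
"Improved" outcome, intercept −7.1555) and Model B (4 terms,
"Un-worsened" outcome, intercept 3.1287), both applied to standardized
features. Where the in-text formula and the table disagree in the fourth
decimal of one Model A coefficient (−12.0606 vs −12.0604), the table value
is used; two obvious misspellings in the in-text formula are normalized to
the catalogue names (Kurtosis, HighGreyLevelRunEmphasis).

## Evaluation conventions

* ROC: thresholds at all distinct scores, predicted-positive means
  score ≥ threshold, AUC by the trapezoidal rule (equal to the
  Mann–Whitney U/(n₀n₁) identity, which is tested). The reported
  operating point maximizes Youden's J; J ties break to the **lower**
  cutoff. The cutoff rule is recorded in the report metadata because the
  original report does not name its rule.
* Calibration: 10 equal-frequency bins (degenerate duplicate quantiles
  collapse), plus a logistic recalibration slope/intercept of the labels
  on logit(p).
* Decision curves: net benefit TP/n − (FP/n)·pt/(1 − pt) on the grid
  0.01–0.99 (step 0.01), with treat-all and treat-none references;
  probability ≥ pt is treatment-positive, closed on the left, making the
  curves bit-reproducible.

## Problem sizes used by the test suite

The suite verifies exact identities at tiny n (hand-enumerable
Mann–Whitney and Fisher cases, 2 × 2 co-occurrence examples), oracle
equivalence on 200 random 6 × 6 planes, type-I error on 1000 null
replicates (n = 20 + 20), LASSO recovery on 100 replicates (n = 200, 10
features), logistic parameter recovery at n = 2000, and the
direction-of-effect property on replicate synthetic cohorts of n = 30 + 30
at a 32 × 32 × 10 grid (radius-7 lesions). Monte-Carlo module tests use
20–25 replicates with acceptance bands set at ~3 binomial standard errors
of their nominal rates; these sizes are the package's own balance between
resolution and runtime.

## Known limitations

* Texture is 2D-on-one-plane by design; no 3D, wavelet or filtered
  feature families.
* Absolute magnitudes of HaralickCorrelation (and, to a lesser degree,
  Entropy) depend on unpublished upstream conventions and are not
  comparable to the printed table values; directions and all internal
  identities are.
* The cohort-level performance figures obtainable here are apparent
  (resubstitution) estimates on synthetic data; the original patient-level
  AUCs are not reproducible without the restricted data.
* Alignment is integer-rigid; real breathing deformation is out of scope.
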