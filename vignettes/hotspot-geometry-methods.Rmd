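---
title: "Hotspot geometry biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot geometry biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hotspotpet)
```

## The measurement model

A PET study enters the pipeline as a 3D grid of standardized uptake
values (SUV) with voxel spacing in mm. The package adopts one coordinate
convention throughout: voxel indices are 0-based, the physical center of
voxel $(i,j,k)$ is $(i s_x, j s_y, k s_z)$, and every distance is measured
between voxel centers in mm. The measurement chain is:

1. **Resampling.** Trilinear interpolation onto an isotropic grid
   (default 3 mm, the clinical reconstruction grid for this application).
   Trilinear is exact for affine fields, non-ringing, and the standard
   default for SUV maps. Output SUV is clipped at zero; the grid origin is
   preserved and the extent changes by less than one voxel.
2. **Hotspot.** The SUVmax voxel, located on the resampled grid (all
   metrics live there; the input-grid SUVmax is retained in the provenance
   log for diagnostics). Ties break to the lexicographically smallest
   $(i,j,k)$ so results are deterministic.
3. **Segmentation.** The metabolically active lesion is the 26-connected
   (vertex-adjacent) component of $\{\mathrm{SUV} \ge 0.4 \cdot
   \mathrm{SUV_{max}}\}$ containing the hotspot. The comparison is
   inclusive ($\ge$), matching common PET tooling. The 26/6 connectivity
   pairing (body/boundary) is the standard morphological choice that keeps
   the two definitions consistent. No hole filling and no minimum-size
   filter are applied; interior holes contribute perimeter voxels. An
   optional search mask can exclude a second avid structure.
4. **Perimeter.** The outermost voxel layer: mask voxels with at least one
   of their 6 face-adjacent neighbors outside the mask (the grid border
   counts as outside).
5. **Metrics.** With mask volume $V$ (mL; voxel count × voxel volume /
   1000):
   - $\mathrm{MTV} = V$, $\mathrm{SUV_{mean}}$ the arithmetic mask mean,
     $\mathrm{TLG} = \mathrm{SUV_{mean}} \times \mathrm{MTV}$ (exact by
     construction, asserted bitwise in the tests);
   - the equivalent-sphere radius $R = (3 \cdot 1000 V / 4\pi)^{1/3}$ mm;
   - $\mathrm{NHOC_{max}} = \lVert x_{\mathrm{hot}} - \bar{x} \rVert / R$
     with $\bar{x}$ the unweighted geometric centroid of mask voxel
     centers (an SUV-weighted centroid is available behind an option,
     default off — the upstream processing convention is not documented,
     and the unweighted centroid is the simpler reading of "tumor
     centroid");
   - $\mathrm{NHOP_{max}} = \min_{p \in \mathrm{perimeter}}
     \lVert x_{\mathrm{hot}} - x_p \rVert / R$, distances to perimeter
     *voxel centers*, not to a polygonal surface.

Degenerate single-voxel lesions return NHOC = NHOP = 0 with a
`"degenerate"` flag and a warning, never an error, so batch extraction
cannot abort.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `target_spacing_mm` | 3.0 | isotropic resampling target (mm); `NULL` disables resampling and metrics honor anisotropic spacing |
| `threshold_fraction` | 0.40 | segmentation threshold as a fraction of SUVmax |
| `centroid_weighting` | geometric | unweighted vs SUV-weighted centroid |
| `n_boot` | 2000 | bootstrap replicates for the AUC confidence interval |

## What the phantom generator emulates

`make_phantom()` builds the idealized world in which the measurement chain
can be validated against analytic truth: an ellipsoidal lesion (default a
21 mm-radius sphere) on a uniform background (default SUV 1), with a
hotspot planted at a controllable normalized offset along a chosen
direction, blurred by a Gaussian point-spread function (default FWHM
4 mm) and degraded by additive Gaussian noise (default SD 0.05 SUV),
clipped at zero. Peak SUV defaults to 10, a typical avid lung lesion.
Sphere truth is analytic ($\mathrm{NHOC} = d$, $\mathrm{NHOP} = 1 - d$
for offset $d$); ellipsoid truth solves the point-to-surface Lagrange
condition by 1D root finding, with the degenerate-axis critical points
also examined.

Two generator design choices deserve explanation:

- **Interior uptake profile.** The lesion interior is a steep Gaussian
  peak (half-decay 4.5 mm) on a plateau at 0.80 of peak. The steep peak
  pins the SUVmax voxel at the planted location under noise (the
  between-voxel contrast near the peak is several noise SDs). The high
  plateau keeps the lesion *edge* far enough above 40% of SUVmax that the
  blurred iso-contour sits at the planted surface: a profile that decays
  to the minimal 0.5 floor blurs to roughly $(0.5\,\mathrm{peak} +
  \mathrm{bg})/2 < 0.4\,\mathrm{SUV_{max}}$ at the surface and erodes the
  segmentation by ~1.5 mm, corrupting the geometry being validated.
  Interior uptake never falls below 0.5 of peak, and the background must
  stay below 0.4 of peak so the lesion is separable at the default
  threshold.
- **What is *not* modeled.** Scanner physics (Poisson sinogram noise,
  scatter, partial-volume sampling), respiratory motion, irregular or
  spiculated margins, multiple lesions, and background heterogeneity. A
  green phantom test therefore establishes that the geometry pipeline
  recovers known continuum truth through voxelization, blur and mild
  noise — not that it is robust to clinical image quality.

`simulate_cohort()` emulates the statistical structure of a resected
lung-adenocarcinoma cohort: marginals NHOP $\sim N(0.34, 0.23^2)$ and
NHOC $\sim N(0.55, 0.28^2)$ (truncated to their plausible ranges), SUVmax
and MTV log-normal with means/SDs 6.54/4.62 and 5.43/10.61, TLG
proportional to MTV × SUVmax with multiplicative noise, coupled by a
Gaussian copula with one weak exchangeable correlation (default 0.1 —
reported inter-metric correlations are weak, and the generator exposes
rather than asserts them). Recurrence is Bernoulli with logit
$\beta_0 + \beta_{\mathrm{nhop}} \mathrm{NHOP} + \beta_{\mathrm{suv}}
\mathrm{SUV_{max}}$; defaults $\beta_{\mathrm{nhop}} = \log 0.033$
(strongly protective), $\beta_{\mathrm{suv}} = \log 1.1$, intercept
−0.85 calibrated once to a ~20% event rate. DFS is exponential among
recurrent patients (baseline hazard 0.03/month, so most recurrences are
observed within the horizon) scaled by $\mathrm{HR}^{z}$ with
$\mathrm{HR} = 0.4$ per SD of NHOP, administratively censored at 96
months (the longest plausible follow-up); events occur only in recurrent
patients, so `event = 1` implies `recurrence = 1`. The alternative
`design = "binormal"` replaces NHOP by an *untruncated* normal score
shifted down by $\delta$ SDs in cases, for which
$\mathrm{AUC} = \Phi(\delta/\sqrt{2})$ holds exactly — truncation would
compress the SD and bias the empirical AUC upward by ~0.02.

## Statistical operations

- **Spearman matrix**: Pearson correlation of midranks; p-values from the
  t approximation on $n-2$ df. Constant columns yield `NA` with a
  warning.
- **ROC / Youden**: AUC is pairwise concordance with ties counting ½
  (computed via the midrank identity). Orientation is auto-chosen so
  AUC ≥ 0.5 and recorded explicitly — a protective marker (OR < 1) with
  AUC > 0.5 implies the score direction was flipped, and making the flip
  explicit avoids silent sign errors. The cut-off maximizes Youden's
  $J$ over all observed values, ties resolved to the smallest cut-off;
  the 95% CI is a stratified percentile bootstrap (default 2000
  replicates, fixed seed) — distribution-free, at the price of Monte
  Carlo wobble in the last digit.
- **Logistic regression**: maximum likelihood via IRLS, Wald 95% CIs and
  p-values (the routine clinical reporting convention; profile-likelihood
  intervals are deliberately not used). Suspected complete separation
  (|log-odds| > 15, SE > 10, or fitted-probability warnings) is flagged,
  not silently reported.
- **Cox regression**: partial likelihood with the Efron tie correction
  (the better default under heavy ties from month-resolution times);
  monotone-likelihood warnings are flagged.
- **Kaplan–Meier / log-rank**: product-limit estimates per group;
  chi-square from observed-minus-expected event counts over pooled risk
  sets, p on (groups − 1) df. With no censoring the KM estimate equals
  the empirical survival function exactly (asserted in the tests).
- **Dichotomization**: values equal to the cut-off go to the lower group.
- No multiple-testing correction is applied anywhere.

## Numerical choices and degenerate inputs

- Resampling output size along each axis is
  $\lfloor (n-1) s / t \rfloor + 1$, preserving the physical extent to
  within one voxel; when input spacing already equals the target the
  volume is returned unchanged, bit for bit.
- The ellipsoid surface-distance root is bracketed against the dominant
  singularity $t \to -\min a_i^2$ and solved to 1e-12; a center point
  returns $\min a_i$ directly.
- Empty masks, single-class outcomes, zero events, out-of-bounds hotspots
  and non-finite parameters raise immediate, named errors; degenerate
  lesions and separation/monotone-likelihood are flagged-but-returned.
- All generators restore the caller's RNG state, so they are pure
  functions of (parameters, seed).

## Known limitation: the discrete NHOP floor

The minimum distance from the hotspot to perimeter *voxel centers* is
biased inward on coarse grids. A digitized ball at 3 mm voxels has
"staircase ledge" perimeter voxels — columns laterally offset from a
surface-tangent direction whose outermost in-mask voxel sits a full layer
down — so the nearest perimeter center lies ~2.6–2.8 mm inside the
continuum surface. You can see this without any segmentation at all:

```{r ledge, eval = FALSE}
ball <- (function(R, sp) {
  n <- 2 * ceiling(R / sp) + 5; ctr <- (n - 1) / 2 * sp
  ax <- (seq_len(n) - 1) * sp
  array(outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
        <= R^2, c(n, n, n))
})(21, 3)
per <- extract_perimeter(ball)
ctr0 <- (dim(ball) - 1) / 2
min(sqrt(rowSums((sweep(per, 2, ctr0) * 3)^2)))  # ~18.25 mm, not 21
```

Dividing by the equivalent-sphere radius (~20.9 mm) gives
NHOP(center) ≈ 0.87 for an ideal sphere — and sweeping the effective
segmented radius over 20–24.5 mm moves this only within ~0.87–0.91, so no
segmentation accuracy can remove the bias. Consequently sphere-phantom
NHOP recovery at small offsets misses a nominal ±0.10 band (the
acceptance suite asserts the band as specified and documents the failure
rather than widening it); NHOC, which measures to the centroid rather
than to a minimum over a discrete set, recovers within ±0.08 at all
tested offsets. Users comparing NHOP across patients on a fixed grid are
unaffected (the bias is shared), but absolute NHOP values near the
continuum bound 1 should not be over-interpreted on 3 mm grids.

## Scope and other limitations

- SUV maps are taken as given; dose/decay conversion from DICOM is out of
  scope, as are SUVpeak and its derived distances (unstable for lesions
  under ~12 mm diameter).
- One lesion per extraction; batch or multi-lesion segmentation is not
  provided.
- NIfTI-1 support is deliberately minimal (3D scalar volumes, slope/
  intercept scaling, both endiannesses, stored axis order taken as
  canonical); orientation matrices are written but not used to reorder
  axes.
- The simulated cohorts are a *stated world* for validating the
  statistical machinery: green tests establish correctness of the
  computations and direction/magnitude recovery under the stated models,
  not clinical performance of any biomarker.
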