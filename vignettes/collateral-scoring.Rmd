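---
title: "Downstream-area collateral scoring: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream-area collateral scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odacs)
```

## The measurement model

Collateral status is quantified as a vessel-volume ratio between
homologous regions of the two hemispheres. The package implements two
instances of that model:

* **Downstream-area score**: the region is the patient-specific
  occlusion-downstream area, proxied by hypoperfused tissue on the CTP
  Tmax map (`Tmax > 6 s`), refined by morphological closing, and
  mirrored across the midline plane for the contralateral reference.
* **Territory score**: the region is a fixed MCA-territory mask
  (atlas-derived or synthetic), again mirrored for the reference side.

Both assume: (i) the CTA vessel segmentation and the Tmax map live on
one voxel grid (the package applies a *given* affine co-registration
via `resample_to_grid()` but never estimates one); (ii) the brain
midline is approximately planar and supplied externally (vendor-style
sidecar) or approximated by the grid-centre plane; (iii) contralateral
anatomy is a meaningful reference, i.e. the mirrored region is not
itself hypoperfused or pathological.

The central structural fact the package exposes: when the vessel
deficit is confined to the downstream region and that region is a
strict subset of the territory, the territory ratio is the downstream
ratio diluted toward 1 by the symmetric vessel volume outside the
lesion — for ipsilateral deficit `I ≤ C` and shared volume `S`,
`(I + S) / (C + S) ≥ I / C`. Distal occlusions (small downstream
regions inside a large territory) therefore earn systematically higher
territory scores, which is the bias the downstream-area score removes.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tmax_threshold_s` | 6.0 | s | standard hypoperfusion criterion across CTP software; strict `>` comparison |
| `closing_semi_axes` | (10, 10, 1) | voxels | ellipsoidal element sized to bridge vessel-calibre holes in-plane on thick-slice (≈5 mm) CTP grids |
| `low_relax` | 0.05 | ratio | category 0 relaxed from "no filling" to < 5 % so tiny false-positive vessel voxels cannot promote a patient out of category 0 |
| `high_relax` | 0.95 | ratio | category 3 relaxed from exactly 100 % to > 95 % for the symmetric reason |
| `overlap_warning_fraction` | 0.05 | fraction | mirror self-overlap beyond this suggests a midline-straddling lesion, flagged not fatal |

The closing element is specified in voxel units, exactly as the method
defines it, so its physical shape follows the grid anisotropy (on a
2 × 2 × 5 mm grid the default element spans 20 mm in-plane and one
slice out-of-plane). A deliberately 3D reading is used: the ellipsoid
inequality `(dx/a)² + (dy/b)² + (dz/c)² ≤ 1` is inclusive, so semi-axis
1 along z admits offsets (0, 0, ±1) — the element is not a stack of
independent 2D discs. Inclusivity also makes semi-axis 0 collapse an
axis cleanly (only the zero offset survives).

## Numerical and boundary conventions

* **Category boundaries.** The relaxations are stated as strict
  ("less than 5 %", "more than 95 %") without fixing where the equality
  points go; the package assigns boundary points to the *inner*
  categories (0.05 → 1, 0.50 → 1, 0.95 → 2), preserving the original
  Tan pattern of inclusive upper bounds ("> 0 % but ≤ 50 %"). The
  extended scale refines only the interior: 1a spans [0.05, 0.25],
  2b spans (0.75, 0.95]. Ratios above 1 satisfy `r > 0.95` and map to
  category 3; they arise when the contralateral side carries less
  vessel volume than the ipsilateral one.
* **Undefined ratios.** A zero contralateral vessel volume yields an
  undefined (`NA`) ratio and category with a recorded reason, never a
  silent 0 and never an exception at cohort level — cohort statistics
  drop such patients pairwise with reported counts.
* **Mirroring.** Reflections are computed in physical millimetres
  (anisotropic voxels handled correctly) and voxelized by
  nearest-voxel-centre assignment; exact half-voxel ties round toward
  the lower index so results are deterministic. For grid-symmetric
  planes this makes mirroring an exact involution that preserves voxel
  counts; for arbitrary planes, off-grid reflections are dropped and
  their fraction recorded as a warning.
* **Closing at the image border.** The volume is padded with
  background by the element extent before dilation and cropped after
  erosion, so the border never closes gaps spuriously; with this
  convention closing is extensive, idempotent and monotone (all three
  are tested against a set-arithmetic oracle). Internally the
  dilation/erosion counts are computed by FFT convolution; counts are
  integers, so the 0.5 decision thresholds are insensitive to FFT
  round-off by nine orders of magnitude.
* **Hypoperfusion components.** The thresholded mask is used as-is: no
  connected-component or size filtering, since the method defines none.
* **Alignment.** `align_to_midplane()` applies the minimal rotation
  taking the supplied plane normal onto the left-right axis and
  translates the plane point to the grid centre; masks are resampled
  nearest-neighbour, scalars trilinearly. Planes more than 45° from
  the left-right axis are rejected as degenerate.
* **Medians and IQRs** use linear interpolation between order
  statistics (`stats::quantile` type 7). The signed-rank test is exact
  (full sign-assignment distribution) for n ≤ 25 without ties in the
  absolute differences, and a tie-corrected normal approximation
  otherwise; zero differences are dropped with reported counts. The
  weighted kappa uses a *fixed* category set (0–3, or the six extended
  levels) so the quadratic weights do not drift across cohort subsets
  in which some categories are unobserved.

## What the phantom generator emulates

`generate_phantom()` builds the geometry the scoring pipeline assumes:

* an ellipsoidal one-sided Tmax lesion above the 6 s criterion on a
  strongly anisotropic grid (default 64 × 64 × 16 voxels at
  2 × 2 × 5 mm, echoing thick-slice CTP reconstructions);
* tubular vessels (capsules rasterized in physical coordinates) placed
  inside the lesion, with the contralateral set the exact mirror of the
  full base set and the ipsilateral set truncated so the brute-force
  voxel-count ratio inside the refined region hits `target_ratio`
  within one voxel (for ratios above 1 the roles swap). Calibration
  counts voxels directly instead of trusting analytic capsule volumes,
  so the recorded truth absorbs all rasterization error;
* mirror-symmetric background vessels outside the lesion but inside
  the hemispheric territory, which is what separates the territory
  score from the downstream score;
* optional **vessel carving**: lesion-interior vessel voxels are reset
  to background Tmax, reproducing the vendor-software artifact that the
  closing refinement exists to undo. Carving is asymmetric whenever the
  ipsilateral vessel set differs from the contralateral one, so
  disabling the closing step demonstrably corrupts the ratio — the
  regression the test suite pins;
* a grid-centre midline plane and a margin-trimmed hemispheric slab as
  the synthetic territory.

One feasibility rule is the generator's own: the lesion centre is
shifted laterally so the ellipsoid clears the midplane by three
in-plane voxels (clipping at the outer grid border is permitted). At
desk-scale grids, study-scale proximal lesions would otherwise straddle
the midline and a one-sided ground truth could not exist.

What the phantoms do **not** model: CT noise and beam hardening,
vascular tree branching, non-planar midlines, imperfect co-registration,
and contralateral pathology. Passing the phantom suite therefore
validates the geometry, morphology and arithmetic of the pipeline — not
the clinical performance of any vessel segmentation; real CTA
segmentation is a pluggable input (`fallback_segment()` is a simple
threshold-plus-component-cleaning stand-in for phantoms only).

`generate_cohort()` draws occlusion locations at the study-like
prevalence (52 / 32 / 16 % for proximal M1 / distal M1 / M2), target
ratios uniform on [0.1, 1.1], and lesion sizes decreasing with more
distal locations, so the cohort reproduces the qualitative gradient of
interest: the territory-minus-downstream difference grows as lesions
shrink. Two synthetic raters grade a noise-perturbed truth ratio
(Gaussian, SD 0.12) on the Tan scale to exercise the agreement
statistics.

## Problem sizes

Default phantoms are 64 × 64 × 16 voxels; a full generate-and-score
cycle takes well under a second, so the test suite runs a 24-phantom
recovery sweep and a 50-patient cohort in a few minutes on one core.
The morphology oracle comparisons use twenty random 32³ masks with the
full (10, 10, 1) element.

## Known limitations

* No registration estimation: inputs must already share a grid or come
  with an explicit affine; no skull stripping, no automatic midline
  detection (symmetry-based midline estimation is out of scope).
* The territory mask is accepted as given; mapping an atlas into
  patient space is the caller's responsibility.
* The hypoperfusion proxy inherits Tmax's vendor variability; the API
  supports re-scoring with any alternative downstream mask, which is
  the hook a sensitivity analysis would use.
* Categorical agreement statistics are reported without confidence
  intervals, and no multiple-testing correction is applied to the
  per-location p values.
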