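# odacs — occlusion-downstream area collateral scoring

Cerebral collaterals keep brain tissue alive while a large artery is
occluded, and collateral status guides treatment decisions in acute
ischemic stroke. Conventional automated collateral scores compare vessel
volumes over the whole middle cerebral artery (MCA) territory, which
dilutes the signal when the occlusion is distal and only a small part of
the territory is actually at risk. `odacs` scores collaterals **only in
the territory downstream of the occlusion**, using the hypoperfused
region of a CT perfusion (CTP) Tmax map as a patient-specific proxy for
that territory.

The package is for imaging researchers who have a CTA vessel
segmentation and a vendor CTP Tmax map on a common grid and want a
reproducible, scriptable collateral score — plus everything needed to
validate the pipeline without patient data (a synthetic phantom
generator with exact ground truth) and to compare scoring methods across
a cohort (agreement and shift statistics).

## The score

Given a binary vessel mask V, a Tmax map, and a midline plane:

1. **Hypoperfusion mask** — `H = { x : Tmax(x) > 6 s }` (strict
   inequality; threshold configurable).
2. **Refinement** — vendor CTP software removes vessels from its
   analysis, so vessels traversing H appear as tubular holes. Morphological
   closing with a 3D ellipsoidal structuring element (semi-axes 10, 10, 1
   voxels along x, y, z) fills them: `D = close(H)`, the
   occlusion-downstream area. Always `D ⊇ H`.
3. **Mirroring** — `D′ = mirror(D)` across the midline plane gives the
   homologous contralateral region.
4. **Quantitative score** — `ODACS = vol(V ∩ D) / vol(V ∩ D′)`,
   the ipsilateral-to-contralateral vessel-volume ratio (not capped at 1;
   undefined when the contralateral volume is zero).
5. **Categorized score** — Tan-style ordinal grading with relaxed
   boundary criteria guarding against small segmentation errors:

   | category | ratio r            | meaning   |
   |----------|--------------------|-----------|
   | 0        | r < 0.05           | absent    |
   | 1        | 0.05 ≤ r ≤ 0.50    | poor      |
   | 2        | 0.50 < r ≤ 0.95    | moderate  |
   | 3        | r > 0.95           | good      |

   An extended six-level scale splits 1 into 1a (≤ 0.25) / 1b and 2 into
   2a (≤ 0.75) / 2b; the dichotomy is poor (0–1) vs good (2–3).

The reference method, `compute_mca_cs()`, computes the same ratio over
an MCA-territory mask (any NIfTI atlas mask you supply, or a synthetic
hemispheric territory). The cohort module quantifies how the two methods
disagree: Bland–Altman limits of agreement, one-sided Wilcoxon
signed-rank tests, quadratically weighted Cohen's kappa, confusion
matrices, and the proportion of patients shifting from good to poor.

## Worked example

Phantoms are generated with a known truth ratio, so you can see the whole
pipeline work end to end:

```r
library(odacs)

ph <- generate_phantom(phantom_spec(target_ratio = 0.4, seed = 42))
ph
#> <odacs_phantom> 64x64x16 grid, side left, truth ratio 0.4022 (ipsi 0.74 mL / contra 1.84 mL)

sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane)
sc
#> <ODACS> ipsi 0.74 mL, contra 1.84 mL -> ratio 0.4022, category 1 (1b, poor)
#> <odacs_region_pair> side: left, ipsi 54.4 mL, contra 54.4 mL, overlap 0, slices 8

mc <- compute_mca_cs(ph$vessel_mask, ph$territory_ipsi, ph$plane)
mc$result
#> <MCA_CS> ipsi 1.64 mL, contra 2.74 mL -> ratio 0.5985, category 2 (2a, good)
```

The phantom's vessel deficit is confined to the downstream area, so the
territory-wide score (0.60, "good") is diluted upward relative to the
downstream score (0.40, "poor") — exactly the disagreement the
downstream-area score is designed to expose. Despite the vessels having
been carved out of the Tmax lesion (as vendor software does), the closing
step returned them to the region: the recovered ratio matches the truth
ratio of 0.4022.

On a cohort the same comparison becomes a table:

```r
co <- generate_cohort(12, seed = 7, grid_shape = c(48, 48, 12))
an <- cohort_analysis(co$table)
glance(an)[, c("location", "n", "odacs_median", "mca_median",
               "wilcoxon_p", "shift_good_to_poor")]
#>   location  n odacs_median mca_median wilcoxon_p shift_good_to_poor
#> 1  overall 12        0.596      0.714     0.0134              0.167
```

`tidy(an)` gives the per-location rows, `autoplot(an)` the Bland–Altman
panels, and `plot_confusion(an$confusion$overall)` the category
cross-table.

## Command line

A thin wrapper lives in `inst/cli/odacs` (installed under the package's
`cli/` directory):

```sh
odacs score --vessels seg.nii.gz --tmax tmax.nii.gz \
      [--midplane plane.json] [--territory mca.nii.gz] \
      [--config cfg.yaml] [--save-masks dir/] --out report.json
odacs cohort  --table cohort.csv --out analysis_dir/
odacs phantom --spec spec.yaml --out phantom_dir/
```

Reports are versioned JSON with undefined values as explicit `null` and
the full parameter set plus input content hashes in `provenance`. The
affine sidecar format is a plain-text file of 12 numbers (row-major 3×3
matrix, then the translation in mm) mapping moving-image physical
coordinates into the reference space.

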