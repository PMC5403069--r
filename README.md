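# octaquant

Quantification of diabetic macular ischemia from en-face OCT-angiography
(OCTA) images, for retinal imaging researchers who need reproducible,
testable implementations of the standard 3 × 3 mm macular measurements and
of the cohort statistics built on them.

Diabetic macular ischemia shows on an en-face angiogram as enlargement of
the foveal avascular zone (FAZ) and perifoveal capillary dropout. The
package measures, per eye:

* **FAZ morphometry** from a manually traced contour: surface
  `A = (mm/px)² · ½|Σᵢ (xᵢ·yᵢ₊₁ − xᵢ₊₁·yᵢ)|` (shoelace), perimeter as the
  sum of edge lengths, and an ordinal 0–4 contour grade (0 = normal
  border, 2 = less than half disrupted, 3 = half or more, 4 = completely
  altered) from the fraction of the border lacking the capillary arcade;
* the **nonperfusion index** on the superficial plexus,
  `NPI = #{pixels with brightness < 45} / #{all pixels}`, which captures
  FAZ enlargement and capillary dropout in one standardized number;
* the **central nonperfused area** on the deep plexus: the seeded
  4-connected below-threshold component, in mm².

Cohort-level analysis follows the nonparametric workflow used for such
measurements: Kruskal–Wallis across NPDR stages, Fisher exact for
qualitative factors, Spearman / Mann–Whitney univariate screens, and
ordinary least-squares covariance models with entry at p < 0.20 and
backward elimination to p < 0.05, with optional log transformation.

Because no patient images are distributed, the package ships a synthetic
angiogram and cohort generator with complete ground truth (FAZ polygon,
disruption fraction, dropout fraction, stage effects), so the entire
pipeline is exercised and verified without any download. See the vignette
`vignettes/quantifying-macular-ischemia.Rmd` for the model and its
assumptions.

## Worked example

```r
library(octaquant)

# a synthetic eye: enlarged FAZ, 30% border disruption, 20% dropout
sc <- generate_angiogram(vascular_scene_params(
  faz_area_mm2 = 0.45, arcade_disruption_fraction = 0.3,
  dropout_fraction = 0.2, seed = 7))

compute_npi(sc$image)
#> NPI = 0.4277 (39530 / 92416 pixels < 45)

scale <- sc$image$scale
contour_area(sc$truth$polygon, scale)       # 0.450 mm^2  (truth: 0.45)
contour_perimeter(sc$truth$polygon, scale)  # 2.384 mm

fr <- measure_disruption(sc$image$pixels >= 45, sc$truth$polygon)
grade_faz(fr)                               # grade 2 (fr = 0.211, truth 0.30)

# stage comparison on a simulated 58-eye cohort
co <- generate_cohort(cohort_params(seed = 1))
compare_groups(co, "npi")
#> npi: Kruskal-Wallis H = 14.17 (df = 2), p = 0.0008381
#>     group  n      mean         sd
#>      mild 20 0.2467759 0.09125676
#>  moderate 24 0.2809504 0.06104222
#>    severe 14 0.3418945 0.04989175
```

The NPI of 0.43 reflects the dark FAZ interior plus the dropout patches
and intercapillary background; the Kruskal–Wallis p below 0.001 shows the
simulated stage gradient in NPI (means rising 0.25 → 0.28 → 0.34) is
detected at the default cohort size.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

1. `01_simulate_scenes.R` — nine severity-graded angiogram pairs + ground truth
2. `02_image_metrics.R` — FAZ/NPI/deep-plexus measurements, recovery check
3. `03_simulate_cohort.R` — the default 35-patient cohort and descriptives
4. `04_group_comparisons.R` — stage comparisons, full JSON/CSV report
5. `05_models.R` — univariate screens and backward-elimination models

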