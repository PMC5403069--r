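---
title: "Quantifying diabetic macular ischemia from en-face OCT-angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diabetic macular ischemia from en-face OCT-angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement problem

Diabetic macular ischemia (DMI) is the progressive closure of the capillary
network around the fovea. On an en-face OCT-angiography (OCTA) image —
a 3 × 3 mm frontal projection of a retinal capillary slab, centred on the
fovea — it shows up in two ways: the physiologic foveal avascular zone
(FAZ) enlarges and its bounding capillary arcade breaks up, and patches of
perifoveal capillaries drop out and appear dark. `octaquant` implements the
quantification of both phenomena and the cohort statistics that relate them
to nonproliferative diabetic retinopathy (NPDR) stage.

Three measurements are made per eye:

* **FAZ morphometry.** The FAZ border is traced manually as a closed
  polygon in pixel space. After calibrating the scale (`calibrate()`:
  mm/px = field width / raster side), the surface is the absolute shoelace
  area of the polygon and the perimeter the sum of its Euclidean edge
  lengths, closing edge included. An ordinal contour grade 0–4 summarizes
  arcade disruption: 0 a normal contour, 1 questionable disruption, 2 less
  than half the circumference disrupted, 3 half or more, 4 a completely
  altered contour.
* **Nonperfusion index (NPI).** On the superficial-plexus image, the
  fraction of pixels whose 8-bit brightness is beneath a fixed threshold
  (default 45), computed over the *whole* frame. Because the FAZ interior
  is itself below threshold, one number captures FAZ enlargement and
  perifoveal dropout together.
* **Deep-plexus central nonperfused area.** On the deep-plexus image, the
  4-connected component of below-threshold pixels containing a central
  seed, converted to mm².

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `field_mm` | 3.0 | mm | standard macular OCTA field |
| `image_size_px` | 304 | px | typical export raster for this field |
| `npi_threshold` | 45 | 8-bit brightness | the decision boundary between perfused signal and nonperfusion |
| inequality | strict (`<`) | — | literal reading of "beneath"; `inclusive = TRUE` gives the `<=` sensitivity variant |
| `questionable_epsilon` | 0.05 | fraction of border | upper edge of the "questionable" grade-1 band |
| `entry_p` / `stay_p` | 0.20 / 0.05 | p-value | univariate entry and multivariate retention thresholds |

The brightness threshold is only meaningful on an 8-bit scale, so colour or
deeper inputs are converted to 8-bit luminance on read and the conversion
is reported.

## The synthetic scene generator

No public OCTA image set with traced FAZ ground truth exists at the scale
needed for testing, so the package generates its own scenes
(`generate_angiogram()`), with every construction parameter recorded as
ground truth:

* The FAZ boundary is a low-order Fourier perturbation of a circle
  (harmonics 2–5, amplitude proportional to `faz_irregularity`), rescaled
  so the polygon's shoelace area hits `faz_area_mm2` exactly. The boundary
  stays star-shaped, hence simple.
* The capillary bed is a jittered square lattice rasterized with a ~2 px
  stroke — about 900 edges/mm² by default, which leaves an intercapillary
  background fraction that puts baseline NPI near 0.3 at the default
  brightness settings.
* A double arcade ring hugs the FAZ border; a contiguous arc covering
  `arcade_disruption_fraction` of the circumference is left bare, and
  capillaries are cleared from a 10 px band outside the border there, so
  an automated grader looking outward from the contour finds nothing.
* Dropout is a union of random disks confined to the perifoveal annulus
  (12 px beyond the border to half the field); disks are added until the
  union covers `dropout_fraction` of the annulus, and the achieved
  fraction — measured on the union mask, so overlap is handled — is stored
  as truth.
* Brightness is bimodal (background 20, vessels 180 by default) with
  additive Gaussian speckle clipped to [0, 255] applied last. Same
  parameters and seed give a bit-identical image.

What the generator does *not* emulate: OCT speckle statistics and
decorrelation noise, projection artifacts from the superficial onto the
deep slab, motion artifacts, vessel-calibre variation, and the foveal
brightness gradient of real angiograms. Passing tests therefore show that
the measurement pipeline is correct *given* imagery with known truth — not
that the fixed threshold 45 is clinically optimal on any particular
device's export.

The automated disruption measure (`measure_disruption()`) samples the
contour at arc-length-uniform points and declares a sample disrupted when
a window reaching 6 px along the outward normal (±2 px tangentially)
contains no vessel pixel. On noise-free scenes it recovers the generated
disruption fraction within 0.05. It is a grading aid and a test surrogate
for the human grader, not a segmenter; with speckle on, the thresholded
vessel mask is noisy and the measure degrades gracefully.

## The synthetic cohort

`generate_cohort()` draws an eye-level table with the structure the
statistics assume: 35 patients contributing a second eye with probability
23/35 (so 58 eyes in expectation), stage sampled per eye with weights
19/24/15, and covariates from stage-dependent normals. The defaults were
chosen once to make the overall moments realistic for an NPDR cohort —
age 61.8 (SD 12.1), overall HbA1c near 7.6%, BCVA near 81 ETDRS letters,
diabetes duration near 18 years, 63% men, 83% insulin-treated — with
stage effects on the image metrics (e.g. NPI means 0.24/0.29/0.35,
SD 0.06; FAZ area 0.32/0.42/0.56 mm², SD 0.12) large enough that a ~58-eye
study is well powered for the stage trend, as the corresponding clinical
observation was. Patient-level covariates are shared by fellow eyes and
drawn from the distributions of the patient's worse-stage eye. Setting the
per-stage means equal produces a null cohort for calibration checks.

## Statistical workflow and numerical choices

Eyes are treated as independent observations throughout (no
intraclass-correlation correction) — deliberately mirroring the
exploratory design this pipeline reproduces.

* **Stage comparisons:** Kruskal–Wallis with midrank tie correction;
  the p-value is the chi-square tail on k − 1 df. With two groups the
  statistic equals the squared Mann–Whitney normal deviate. All-tied input
  returns H = 0, p = 1 with a warning rather than an error.
* **Qualitative factors:** Fisher exact on the stage contingency table;
  all-zero rows/columns are dropped with a warning; a single observed
  level returns p = 1.
* **Univariate screens:** Spearman rank correlation for quantitative
  covariates, two-sided Mann–Whitney for binary ones; constant covariates
  are skipped with a warning. Exact p-values are used where the underlying
  base-R routines provide them (small n, no ties).
* **Multivariate models:** ordinary least-squares analysis of covariance.
  Candidates enter at univariate p < 0.20; backward elimination removes
  the covariate with the largest p ≥ 0.05 and refits until all retained
  are significant. Ties in exit p-values are broken by removing the
  *later* covariate in the declared candidate order, which makes the
  elimination trace reproducible; collinear covariates are dropped first,
  by name, with a warning. "Log transformation if necessary" is
  operationalized as: transform when the full-model residuals fail
  Shapiro–Wilk at p < 0.05 and the outcome is strictly positive; the
  decision is recorded in the fit and can be forced either way.
* The ordinal FAZ grade is analysed by rank-based tests; it is never used
  as a linear-model outcome unless explicitly requested.
* Missing data: complete cases per model, with the case count reported.

Coordinate convention everywhere: pixel centres at integer coordinates,
x rightward, y downward, 0-based. Polygon area defaults to the traced
polygon (shoelace), not a filled pixel mask; the two differ at sub-pixel
order and the polygon is the reproducible choice. Reports serialize floats
at 6 significant digits with sorted keys so identical inputs hash
identically.

## Verification strategy and problem sizes

Each implementation is checked against an independent oracle: NPI against
a brute-force double-loop pixel count (integer equality on 100 random
scenes), the seeded component against a breadth-first flood fill, the
shoelace area against Monte-Carlo rejection sampling, and the rank tests
against exhaustive permutation / hypergeometric enumeration at n ≤ 10.
Morphometry recovery runs over a 10-point grid of FAZ areas
(0.1–1.2 mm², speckle off): measured-vs-true area has slope 1 ± 0.02 and
|intercept| < 0.01 mm². Calibration simulations use 2000 null replicates
(type-I error of the stage test at α = 0.05) and 200 replicates each for
the stage-ordering power check and the backward-elimination recovery
check at 58 eyes; those sizes give Monte-Carlo standard errors well below
the margins being asserted. Image-level property tests run on 64–160 px
rasters, which preserve every geometric property of the 304 px default at
a fraction of the cost.

## Known limitations

* The synthetic capillary mesh is statistically stationary; real plexuses
  have radial vessel orientation and density gradients, so absolute NPI
  values here are not comparable to device measurements.
* The disruption grader assumes a star-shaped contour (outward = away from
  the centroid); strongly non-convex manual traces would need true normal
  estimation.
* The deep-plexus "central nonperfused area" depends on the seed pixel
  being inside the dark region; on an eye whose centre is perfused the
  seeded variant returns 0 with a warning and a manual polygon should be
  routed through the FAZ morphometry path instead.
* No mixed-effects option: inter-eye correlation is knowingly ignored, as
  in the design being reproduced; a cluster-robust variance would be the
  natural extension.
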