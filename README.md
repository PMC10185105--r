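# legcomp

Semiautomated segmentation and body-composition analysis of the lower
extremities from chemical-shift-encoded (CSE / Dixon) MRI.

Lipedema is a chronic adipose-tissue disease with disproportionate,
symmetric subcutaneous fat deposition in the legs that is frequently
mistaken for obesity. Dixon MRI separates fat- and water-dominated signal
and so can quantify where that fat sits — but whole-leg acquisitions are
hundreds of slices, and manual outlining does not scale. `legcomp`
implements a multislice pipeline, built entirely from classical image
processing, that partitions every axial slice into subcutaneous adipose
tissue (SAT) and skeletal muscle, aggregates per-slice volumes along the
leg, and compares patient groups with rank-based statistics. It is aimed at
quantitative-imaging researchers working on adipose-tissue disease who need
reproducible whole-leg composition metrics without training data.

## The algorithm

Each axial slice is processed in five steps:

1. **Leg boundary** — two-phase Chan–Vese active contour on the in-phase
   image (bright over the whole leg), initialized from the global Otsu
   foreground dilated by 3 px.
2. **Fat/water classification** — locally adaptive thresholding of the
   masked fat- and water-weighted images. Each pixel is compared with the
   local mean in an `s × s` window, where the kernel side adapts to the
   anterior–posterior extent of the legs:

   `s = 2 ⌊ HBOX · (3/4) / 2 ⌋ + 1`

   with `HBOX` the height of the tightest box enclosing both legs. Local
   thresholding is what keeps the dim, off-isocenter regions of an
   extremity acquisition from being dropped, where any single global
   threshold fails.
3. **Muscle** — erode the leg mask by a 2×2 kernel (skin rim), intersect
   with the water mask, subtract the fat mask, remove objects < 10 px, fill
   holes < 18 px, close with a radius-2 (calf) or radius-4 (thigh) disc,
   and flood-fill the enclosed bone holes → filled muscle mask.
4. **SAT** — fat mask minus filled muscle, opening with a radius-2 disc,
   exclusion of components with circularity `4πA/P² > 0.80` (round fatty
   marrow), removal of components < 10 px.
5. **Final muscle** — subtract the remaining fat-weighted components
   (intermuscular fat, marrow) from the filled muscle mask.

Per-slice SAT and muscle volumes (mL, both legs summed) are averaged over
**decades** — ten contiguous groups of 10% of the analyzed slices, decade 1
at the ankle — to compare anatomy across subjects of different heights.
Segmentation accuracy is validated with the Dice similarity coefficient
`DSC(A, G) = 2|A∩G| / (|A|+|G|)`, and group differences are tested with the
Mann–Whitney U test (exact below per-group n = 8, tie-corrected normal
approximation otherwise) with effect size `r = |Z|/√N`.

Because no public CSE-MRI dataset of this kind exists, the package includes
a parametric phantom generator (`phantom_spec()`, `generate_phantom()`,
`generate_cohort()`) producing two-leg multi-contrast volumes with known
tissue labels, a multiplicative bias field, and noise — every stage of the
pipeline is testable end to end against ground truth.

## Worked example

```r
library(legcomp)

ph    <- generate_phantom(phantom_spec(seed = 1))   # 60 slices, 96 x 192
masks <- segment_volume(ph$volume)                  # five-step pipeline
met   <- volume_metrics(masks, ph$volume$voxel_spacing, circumference_side = "left")
dec   <- decade_summaries(met)
dec[c(3, 7), c("decade", "mean_sat_volume_ml", "mean_muscle_volume_ml",
               "mean_sat_muscle_ratio", "mean_circumference_cm")]
#>  decade mean_sat_volume_ml mean_muscle_volume_ml mean_sat_muscle_ratio mean_circumference_cm
#>       3             10.491                 5.026                 2.097                22.132
#>       7             13.286                 6.293                 2.116                24.810

rep <- phantom_dsc_report(masks, ph$truth)          # Dice vs ground truth
rep$dsc <- round(rep$dsc, 4)
rep
#>  region tissue slice dsc
#>    calf    sat    15   1
#>    calf muscle    15   1
#>   thigh    sat    39   1
#>  thigh muscle    39   1

mann_whitney(c(0.72, 0.42, 0.61, 1.29, 0.55), c(1.26, 0.62, 2.25, 1.05, 1.4))
#> Mann-Whitney U = 4.0 (n1 = 5, n2 = 5), p = 0.09524, r = 0.561 [exact permutation enumeration]
```

Decade 3 sits in the superior calf and decade 7 at the midthigh; the decade
means are per-slice averages of the bilateral SAT and muscle volumes (mL)
and their ratio, and the circumference is the left leg's outer-contour
perimeter in cm. On this phantom the representative slices are recovered
essentially perfectly (Dice rounds to 1.0); over ten phantoms the benchmark
mean is slightly below 1 (see below).

A cohort study mirroring the group analysis (per-decade Mann–Whitney tests
and effect sizes for SAT volume, muscle volume and SAT-to-muscle ratio)
runs as:

```r
cohort <- generate_cohort(13, 15, sat_multiplier = 1.75, seed = 29)
study  <- run_study(cohort)
study$best_decade     # largest effect-size decade per metric
```

The same operations are scriptable from a shell via
`inst/cli/legcomp.R` (`phantom-generate`, `phantom-cohort`, `segment`,
`study`), which reads and writes NIfTI volumes, CSV tables and JSON
configuration.

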