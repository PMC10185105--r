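---
title: "Methods: lower-extremity fat-water segmentation and composition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lower-extremity fat-water segmentation and composition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Chemical-shift-encoded (Dixon) MRI reconstructs fat-weighted,
water-weighted and in-phase images from one acquisition. In the lower
extremities this gives near-complementary contrast between subcutaneous
adipose tissue (SAT, fat-bright) and skeletal muscle (water-bright), with
the in-phase image bright over the whole limb. `legcomp` segments each
axial slice of such an acquisition into SAT and muscle with classical
image-processing operations only — no training data — and aggregates
per-slice composition metrics along the leg. The intended application is
quantifying the disproportionate SAT deposition of lipedema against
BMI-matched controls, where the discriminating quantity turns out to be an
internal metric (SAT-to-muscle volume ratio) rather than anything visible
from the outside such as limb circumference.

The pipeline is deliberately semiautomated: the analyzed slice range
(inferior ankle to superior thigh) is chosen by the operator from
anatomical landmarks, overlapping acquisition stacks are stitched by
physical slice position (duplicates resolved in favour of the more superior
stack, which sits nearer the isocenter in a head-first acquisition), and a
per-slice override hook accepts manually drawn masks for anatomy the
automated steps do not model (the knee joint).

## The five per-slice steps and their tunables

All tunables live in `segmentation_config()`; defaults are the protocol
values and all areas/radii are in **pixels**, bound to the 2.07 × 1.35 mm
in-plane protocol resolution (a warning fires when input spacing deviates
by more than 25%, because printed pixel thresholds do not transfer across
resolutions unscaled).

1. **Leg boundary** (`segment_leg_boundary`). Two-phase Chan–Vese active
   contour on the in-phase slice, run in its morphological form: pixels are
   reassigned to the nearer of the inside/outside class means, then the
   binary level set is regularized by a 3×3 majority vote; iterations stop
   at `ac_iterations` (default 100) or as soon as the contour is stable.
   The initialization — global Otsu foreground dilated by 3 px — is
   deterministic and anatomy-agnostic; with it, phantom slices converge in
   well under the iteration cap. An all-background slice returns an empty
   mask with a warning rather than an error, so a volume with empty
   end-slices still processes.
2. **Fat/water classification** (`classify_fat_water`). Both contrasts are
   masked by the leg boundary and binarized against a per-pixel threshold
   `local_mean × 2(1 − sensitivity)` (default sensitivity 0.5, i.e. the
   local mean itself). The window side adapts to the anterior–posterior leg
   extent: `s = 2⌊HBOX·kernel_scalar/2⌋ + 1` with `kernel_scalar = 3/4`,
   guaranteeing an odd, positive kernel. Local means use an exact
   integral-image computation with replicate padding — replicate padding
   avoids dark-border artifacts, and exactness lets tests compare against a
   brute-force oracle to machine precision. The local threshold is what
   preserves fat in signal-attenuated regions (off-isocenter drop-off)
   where one global threshold for the slice discards it; the test suite
   demonstrates this on a two-leg toy in which one leg retains 15% of
   nominal intensity.
3. **Muscle** (`segment_muscle`). In printed order: erode the leg mask by a
   2×2 square (`skin_erosion`) and intersect with the water mask; subtract
   the fat mask; remove objects `< min_object_area` (10 px); fill enclosed
   holes `< max_hole_fill_area` (18 px) while preserving the larger bone
   holes; close with a disc of radius `closing_radius_lower` (2 px) in the
   lower region or `closing_radius_upper` (4 px) in the upper region;
   flood-fill the remaining enclosed holes (bones). The original
   lower/upper distinction referred to acquisition stacks, which stitching
   erases, so the boundary is expressed as a slice fraction
   (`upper_region_fraction`, default 0.5). A 2×2 kernel has no centre
   pixel; the erosion is anchored at the kernel's top-left pixel, fixed and
   documented for reproducibility (it trims one pixel from two sides of
   the limb).
4. **SAT** (`segment_sat`). Fat mask minus filled muscle, opening with a
   radius-2 disc (`sat_opening_radius`) to sever SAT–marrow bridges,
   exclusion of components with circularity above `circularity_cutoff`
   (0.80), then removal of components below `min_object_area`.
5. **Final muscle** (`finalize_muscle`). Fat-weighted components not
   assigned to SAT (intermuscular fat, marrow) are subtracted from the
   filled muscle mask, so SAT and final muscle are disjoint by
   construction.

### Numerical choices

- **Circularity** is `4πA/P²` with `P` the total boundary length —
  exterior plus hole contours (the scikit-image/ImageJ region-property
  convention). An alternative is the exterior contour alone, but that
  definition breaks on exactly the population this tool targets: a thick
  subcutaneous annulus whose inner hole falls below ~45% of the leg radius
  has exterior-only circularity `1 − (r_in/r)² > 0.8` and would be deleted
  as "marrow-like" wholesale. With hole-inclusive perimeter an annulus
  scores `(r − r_in)/(r + r_in) ≤ 1/3` however thick it grows, while solid
  marrow discs still score near 1 and are removed.
- **Boundary lengths** (circularity and limb circumference) are measured on
  the marching-squares contour polygon smoothed by a circular moving
  average of window 5. The raw 8-connected chain length overestimates
  smooth boundaries by ~5% on average (up to 8% at 22.5°), which would
  break a ±2% circumference tolerance; the smoothed polygon is within 0.3%
  of the analytic perimeter for a radius-50 disc and within 0.3% of the
  quadrature value for the anisotropic-spacing ellipse.
- **Connected components** are 8-connected (diagonal-touching pixels merge),
  so 1–2-px oblique fat streaks behave as single objects for the area and
  circularity filters.
- **Hole filling "< 18 px"** fills any background component fully enclosed
  by foreground whose area is below the cutoff; larger enclosed holes
  (bones) survive until the dedicated flood-fill at the end of step 3.
- **Empty-vs-empty Dice** is defined as 1.0 (both raters agree there is no
  tissue) and logged via a message.
- **Ties and exactness in the Mann–Whitney test**: midranks throughout; the
  two-sided p-value is computed by exhaustive enumeration of all
  `choose(N, n1)` group assignments when either group has fewer than 8
  values, and by the tie-corrected normal approximation otherwise. No
  continuity correction is applied: the standardized statistic Z also
  defines the effect size `r = |Z|/√N`, and at the cohort sizes of interest
  (13 vs 15) the exact size of the α = 0.05 decision is 0.0464 with or
  without the correction, so the simpler rule is used and documented.
- **No multiplicity adjustment** is applied across decades; per-decade
  p-values are reported as such.

## The phantom: what it emulates and what it does not

The generator (`phantom_spec()` defaults) is the package's study
environment. Each slice holds two elliptical legs (96 × 192 grid at
2.07 × 1.35 × 3.0 mm, 60 slices ankle→thigh) with per-slice eccentricity
jitter around 0.85 — deliberately non-circular so the SAT annulus is not a
trivial target for the circularity filter. Each leg has, outside-in: a 2-px
skin rim; a SAT annulus tapering 6→8 px; muscle; two 2-px marrow bones in
the calf-like half and one 4-px bone in the thigh-like half; and two 2-px
intramuscular fat arcs. Intensities are complementary (fat-bright
SAT/marrow/IMAT at 1.0 against 0.08 tissue background; water-bright muscle
at 1.0 with SAT at 0.25 and skin at 0.08; in-phase bright across the leg),
a multiplicative bias field — an in-plane Gaussian drop-off away from the
image centre plus a linear attenuation ramp along the slice axis, total
amplitude 0.3 — and additive Gaussian noise (σ = 0.05 of tissue intensity,
clamped at zero as in magnitude images) perturb all three contrasts. With
noise and bias switched off, thresholding each contrast at half the tissue
intensity recovers its truth foreground exactly; that oracle pins the
contrast synthesis.

Design notes a maintainer should know:

- **Skin contrast.** The skin rim is dim in *both* fat and water contrasts
  (bright only in-phase). A water-bright rim ≥ 1 px would survive the 2×2
  one-sided erosion as a near-closed loop that the flood-fill would fill,
  destroying the muscle mask — in vivo skin at this resolution is sub-voxel
  and partial-volume dim, which the phantom reproduces by construction.
  The SAT water intensity of 0.25 keeps the local mean at the limb edge
  above the skin intensity, which is what actually excludes the rim from
  the water mask; edge SAT pixels that do cross into the water mask are
  removed by the fat-mask subtraction.
- **Cohort jitter** (`generate_cohort`): per-subject leg-radius scale
  ~ N(1, 0.12) and SAT-thickness scale ~ N(1, 0.15), both truncated to
  [0.8, 1.2], chosen to match the printed between-subject dispersions of
  the target population (circumference CV ~11–15%, ratio CV ~30%). The
  lipedema-like group's SAT thickness is multiplied by `sat_multiplier`
  (default 1.75), and SAT growth beyond the subject's base thickness
  expands the leg radius outward — the disease enlarges the limb — so the
  muscle compartment is identical in distribution between groups, matching
  the observation that muscle volume does not differ.
- **Problem sizes.** The default 60-slice, 96 × 192 phantom segments in
  ~1.5 s; the test suite uses 12–20-slice phantoms per case and the
  benchmark (10 volumes, 600 slices) completes in ~20 s, so the whole
  suite runs in under two minutes.

What the phantom does **not** model — and hence what passing tests do not
establish about real data: Rician noise statistics (noise is Gaussian; the
pipeline thresholds magnitudes far from the noise floor, where the
distinction is immaterial, but low-SNR behaviour is untested); chemical
shift, relaxation and partial-volume mixing at tissue boundaries (edges are
hard, so real boundary voxels will be harder than phantom ones); the knee
joint (mapped to the manual-override input, as in the intended workflow);
subcutaneous edema, which inverts fat/water contrast locally; and the
nodular SAT texture described clinically in lipedema — the phantom models
only thickness differences, because no quantitative texture description
was available to emulate.

## Decades, circumference and orientation conventions

`decade_partition(n)` cuts the analyzed range into ten contiguous groups
with boundaries `⌊d·n/10⌋`; decade 1 is the ankle end (decade 3 ≈ superior
calf, decade 7 ≈ midthigh fix the orientation). Decade means are
unweighted per-slice means; slices whose muscle mask is empty get an
*undefined* ratio and are excluded from (not zero-filled into) the ratio
mean, since zero-filling would bias the ankle decades where muscle can
vanish. Representative region slices (circumference, Dice validation) are
the middle slice of decades 3 and 7. The subject-left leg is the component
whose centroid lies on the image-right half (radiological convention),
exposed as a flag; a single merged component is measured with a warning
and flagged as NA by the per-slice metrics.

## Known limitations

- Pixel-denominated thresholds tie the defaults to the protocol
  resolution; other resolutions need a rescaled configuration.
- Decade normalization assumes leg proportions are comparable across
  subjects.
- The adaptive threshold classifies every leg pixel as fat or water; mixed
  voxels (fascia, vessels) land on whichever side of the local mean they
  fall, and no fat-fraction map is produced (that requires multi-echo
  inputs).
- The Chan–Vese step assumes the in-phase image separates limb from
  background bimodally; severe coil-shading that inverts this ordering
  would need a different initialization.
- Validation is phantom-based end to end; accuracy numbers quantify
  recovery of the phantom's geometry under its noise model, not clinical
  performance.
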