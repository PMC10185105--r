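# Five-step per-slice segmentation partitioning each axial slice into
# subcutaneous adipose tissue (SAT) and final skeletal-muscle masks:
#   1. leg boundary from the in-phase contrast (Chan-Vese active contour),
#   2. fat/water voxel classification by locally adaptive mean thresholding
#      with a kernel size adapted to the anterior-posterior leg extent,
#   3. muscle identification (skin erosion, Boolean subtraction, object/hole
#      size filters, region-dependent closing, flood fill),
#   4. SAT compartmentalization (muscle subtraction, opening, circularity and
#      size exclusion),
#   5. subtraction of intramuscular fat and marrow from the muscle mask.

#' Segmentation tuning parameters
#'
#' All defaults are the printed protocol values; area and radius parameters
#' are in pixels and are resolution-bound (a warning is emitted when the
#' in-plane spacing deviates more than 25% from the 2.07 x 1.35 mm protocol).
#'
#' @param ac_iterations Maximum Chan-Vese iterations for the leg boundary.
#' @param kernel_scalar Numerator factor of the adaptive kernel-size rule
#'   `s = 2 * floor(HBOX * kernel_scalar / 2) + 1`.
#' @param threshold_sensitivity Adaptive-threshold sensitivity in `[0, 1]`;
#'   the per-pixel threshold is `local_mean * 2 * (1 - sensitivity)`, so 0.5
#'   thresholds at the local mean.
#' @param skin_erosion Side (px) of the square kernel eroding the leg mask
#'   before water masking (anchored at its top-left pixel).
#' @param min_object_area Connected components smaller than this (px) are
#'   removed.
#' @param max_hole_fill_area Enclosed holes smaller than this (px) are filled
#'   while larger holes (bones) are preserved.
#' @param closing_radius_lower,closing_radius_upper Radius (px) of the
#'   circular closing kernel in the lower (ankle-to-knee) and upper (thigh)
#'   regions.
#' @param upper_region_fraction Fraction of the most superior slices treated
#'   as the upper region for the closing radius.
#' @param sat_opening_radius Radius (px) of the circular opening applied to
#'   the SAT candidate mask.
#' @param circularity_cutoff SAT candidate components with circularity
#'   `4*pi*A/P^2` above this are excluded (round marrow structures).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ac_iterations = 100L,
                                kernel_scalar = 3 / 4,
                                threshold_sensitivity = 0.5,
                                skin_erosion = 2L,
                                min_object_area = 10L,
                                max_hole_fill_area = 18L,
                                closing_radius_lower = 2L,
                                closing_radius_upper = 4L,
                                upper_region_fraction = 0.5,
                                sat_opening_radius = 2L,
                                circularity_cutoff = 0.80) {
  cfg <- structure(list(ac_iterations = as.integer(ac_iterations),
                        kernel_scalar = kernel_scalar,
                        threshold_sensitivity = threshold_sensitivity,
                        skin_erosion = as.integer(skin_erosion),
                        min_object_area = as.integer(min_object_area),
                        max_hole_fill_area = as.integer(max_hole_fill_area),
                        closing_radius_lower = as.integer(closing_radius_lower),
                        closing_radius_upper = as.integer(closing_radius_upper),
                        upper_region_fraction = upper_region_fraction,
                        sat_opening_radius = as.integer(sat_opening_radius),
                        circularity_cutoff = circularity_cutoff),
                   class = "segmentation_config")
  counts <- c("ac_iterations", "skin_erosion", "min_object_area",
              "max_hole_fill_area", "closing_radius_lower",
              "closing_radius_upper", "sat_opening_radius")
  for (nm in counts) if (cfg[[nm]] < 1L) stopf("'%s' must be a positive count", nm)
  for (nm in c("threshold_sensitivity", "upper_region_fraction",
               "circularity_cutoff", "kernel_scalar")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) stopf("'%s' must lie in (0, 1]", nm)
  }
  cfg
}

#' Leg boundary from the in-phase contrast (step 1)
#'
#' Two-phase Chan-Vese active contour in its morphological form: the level
#' set starts from the global-Otsu foreground dilated by 3 px, and each
#' iteration reassigns pixels to the nearer of the two region means followed
#' by a 3x3 majority smoothing of the contour. Iterations stop at
#' `config$ac_iterations` or earlier once the contour is stable; the scheme
#' is fully deterministic.
#'
#' @param in_phase_slice 2D in-phase intensity matrix.
#' @param config A [segmentation_config].
#' @return Logical leg mask (empty, with a warning, for an all-background
#'   slice).
#' @export
segment_leg_boundary <- function(in_phase_slice, config = segmentation_config()) {
  if (!is.matrix(in_phase_slice)) stopf("'in_phase_slice' must be a matrix")
  if (length(in_phase_slice) == 0L) stopf("empty slice")
  if (diff(range(in_phase_slice)) == 0) {
    warnf("all-background slice: returning an empty leg mask")
    return(matrix(FALSE, nrow(in_phase_slice), ncol(in_phase_slice)))
  }
  u <- in_phase_slice > otsu_threshold(in_phase_slice)
  u <- as_mask(EBImage::dilate(u + 0, disc_brush(3L)))
  img <- in_phase_slice
  for (i in seq_len(config$ac_iterations)) {
    n_in <- sum(u)
    if (n_in == 0L || n_in == length(u)) break
    c1 <- mean(img[u]); c2 <- mean(img[!u])
    reassigned <- (img - c1)^2 < (img - c2)^2
    smoothed <- box_sum3(reassigned + 0) >= 5
    if (identical(smoothed, u)) break
    u <- smoothed
  }
  if (!any(u)) warnf("leg boundary converged to an empty mask")
  u
}

#' Anatomy-adaptive threshold kernel size (step 2 kernel rule)
#'
#' `s = 2 * floor(hbox * kernel_scalar / 2) + 1`, where `hbox` is the height
#' in px of the tightest bounding box enclosing the leg masks; always an odd
#' positive integer.
#'
#' @param hbox Bounding-box height in px (>= 0).
#' @param kernel_scalar Numerator factor (default 3/4).
#' @return Odd positive integer kernel side.
#' @export
compute_adaptive_kernel_size <- function(hbox, kernel_scalar = 3 / 4) {
  if (!is.numeric(hbox) || length(hbox) != 1L || is.na(hbox) || hbox < 0)
    stopf("'hbox' must be a single non-negative number")
  as.integer(2 * floor(hbox * kernel_scalar / 2) + 1)
}

#' Adaptive fat/water voxel classification (step 2)
#'
#' Each contrast is masked by the leg boundary and binarized against a
#' per-pixel threshold equal to the local mean intensity in a
#' `kernel_size x kernel_size` neighbourhood (replicate-padded at the image
#' border) scaled by the sensitivity factor.
#'
#' @param fat_slice,water_slice 2D intensity matrices.
#' @param leg_mask Logical leg mask on the same grid.
#' @param kernel_size Odd positive kernel side (see
#'   [compute_adaptive_kernel_size()]).
#' @param config A [segmentation_config].
#' @return List with logical masks `fat` and `water`, both subsets of
#'   `leg_mask`.
#' @export
classify_fat_water <- function(fat_slice, water_slice, leg_mask, kernel_size,
                               config = segmentation_config()) {
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stopf("'kernel_size' must be a positive odd integer (got %s)", kernel_size)
  assert_same_dim(fat_slice, water_slice, "contrast slices")
  assert_same_dim(fat_slice, leg_mask, "slice and leg mask")
  leg_mask <- as_mask(leg_mask)
  factor <- 2 * (1 - config$threshold_sensitivity)
  binarize <- function(slice) {
    masked <- slice * leg_mask
    thr <- local_mean_box(masked, kernel_size) * factor
    (masked > thr) & leg_mask
  }
  list(fat = binarize(fat_slice), water = binarize(water_slice))
}

#' Muscle border segmentation (step 3)
#'
#' In printed order: erode the leg mask by the square skin kernel and
#' intersect with the water mask; subtract the fat mask; remove objects below
#' `min_object_area`; fill enclosed holes below `max_hole_fill_area`
#' (preserving the larger bone holes); morphological closing with the lower-
#' or upper-region radius; flood-fill all remaining enclosed holes (bones) to
#' produce the filled muscle mask.
#'
#' @param water_mask,fat_mask,leg_mask Logical masks on one grid.
#' @param slice_region `"lower"` (ankle-to-knee) or `"upper"` (thigh).
#' @param config A [segmentation_config].
#' @return Logical filled muscle mask.
#' @export
segment_muscle <- function(water_mask, fat_mask, leg_mask,
                           slice_region = c("lower", "upper"),
                           config = segmentation_config()) {
  slice_region <- match.arg(slice_region)
  assert_same_dim(water_mask, fat_mask, "masks")
  assert_same_dim(water_mask, leg_mask, "masks")
  m <- erode_square_topleft(as_mask(leg_mask), config$skin_erosion) & as_mask(water_mask)
  m <- m & !as_mask(fat_mask)
  m <- remove_small_objects(m, config$min_object_area)
  m <- fill_small_holes(m, config$max_hole_fill_area)
  radius <- if (slice_region == "upper") config$closing_radius_upper
            else config$closing_radius_lower
  m <- morph_close(m, radius)
  fill_all_holes(m)
}

#' SAT segmentation (step 4)
#'
#' Subtracts the filled muscle mask from the fat mask, opens with a circular
#' kernel to break connections between SAT and marrow, excludes components
#' with circularity above the cutoff (round fatty marrow), and removes
#' components below `min_object_area`.
#'
#' @param fat_mask Logical fat mask.
#' @param muscle_filled Logical filled muscle mask (from [segment_muscle()]).
#' @param config A [segmentation_config].
#' @return Logical SAT mask.
#' @export
segment_sat <- function(fat_mask, muscle_filled, config = segmentation_config()) {
  assert_same_dim(fat_mask, muscle_filled, "masks")
  s <- as_mask(fat_mask) & !as_mask(muscle_filled)
  s <- morph_open(s, config$sat_opening_radius)
  lab <- label_components(s)
  if (max(lab) > 0L) {
    circ <- component_circularity(lab)
    keep <- which(circ <= config$circularity_cutoff)
    s <- matrix(lab %in% keep, nrow(s), ncol(s))
  }
  remove_small_objects(s, config$min_object_area)
}

#' Final muscle mask (step 5)
#'
#' Subtracts intermuscular fat-weighted components not previously defined as
#' SAT (IMAT, marrow, cartilage) from the filled muscle mask.
#'
#' @param muscle_filled,fat_mask,sat_mask Logical masks on one grid.
#' @return Logical final muscle mask, disjoint from `sat_mask`.
#' @export
finalize_muscle <- function(muscle_filled, fat_mask, sat_mask) {
  assert_same_dim(muscle_filled, fat_mask, "masks")
  assert_same_dim(muscle_filled, sat_mask, "masks")
  as_mask(muscle_filled) & !(as_mask(fat_mask) & !as_mask(sat_mask))
}

segment_slice <- function(fat_slice, water_slice, in_phase_slice, slice_region,
                          config) {
  leg <- segment_leg_boundary(in_phase_slice, config)
  hbox <- bbox_height(leg)
  ks <- compute_adaptive_kernel_size(hbox, config$kernel_scalar)
  fw <- classify_fat_water(fat_slice, water_slice, leg, ks, config)
  muscle_filled <- segment_muscle(fw$water, fw$fat, leg, slice_region, config)
  sat <- segment_sat(fw$fat, muscle_filled, config)
  muscle_final <- finalize_muscle(muscle_filled, fw$fat, sat)
  structure(list(leg = leg, fat = fw$fat, water = fw$water,
                 muscle_filled = muscle_filled, sat = sat,
                 muscle_final = muscle_final,
                 hbox = hbox, kernel_size = ks),
            class = "slice_masks")
}

#' Segment a full lower-extremity volume (steps 1-5 per slice)
#'
#' Applies the five-step algorithm to every axial slice. Slices in the most
#' superior `upper_region_fraction` of the volume use the upper-region
#' closing radius. Manual override masks, when supplied, replace the
#' automated result verbatim for their slices (the hook for manually
#' segmented anatomy such as the knee joint).
#'
#' @param volume A [cse_volume] ordered ankle to thigh.
#' @param config A [segmentation_config].
#' @param overrides Optional named list of `slice_masks` objects; names are
#'   slice indices.
#' @return List of `slice_masks`, one per slice, each holding the logical
#'   masks `leg`, `fat`, `water`, `muscle_filled`, `sat`, `muscle_final` plus
#'   the recorded `hbox` and `kernel_size`.
#' @export
segment_volume <- function(volume, config = segmentation_config(), overrides = NULL) {
  if (!inherits(volume, "cse_volume")) stopf("'volume' must be a cse_volume")
  nz <- n_slices(volume)
  if (nz < 1L) stopf("empty volume")
  sp <- volume$voxel_spacing
  if (max(abs(sp[1:2] / c(2.07, 1.35) - 1)) > 0.25)
    warnf(paste("in-plane spacing %.2f x %.2f mm deviates >25%% from the",
                "2.07 x 1.35 mm protocol; pixel-based parameters may need rescaling"),
          sp[1], sp[2])
  if (!is.null(overrides)) {
    idx <- suppressWarnings(as.integer(names(overrides)))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nz))
      stopf("override slice indices must lie in 1..%d", nz)
  }
  lower_count <- floor(nz * (1 - config$upper_region_fraction))
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    ov <- overrides[[as.character(z)]]
    if (!is.null(ov)) {
      out[[z]] <- ov
      next
    }
    region <- if (z > lower_count) "upper" else "lower"
    out[[z]] <- segment_slice(volume$fat[, , z], volume$water[, , z],
                              volume$in_phase[, , z], region, config)
  }
  out
}
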