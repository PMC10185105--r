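# Per-slice composition metrics and decade-level aggregation along the leg.
# Quantification is bilateral: per-slice volumes sum both legs. Decade 1 is
# the most inferior (ankle) end.

#' Per-slice composition metrics
#'
#' SAT and muscle volumes in mL (voxel count times voxel volume, summed over
#' both legs) and their ratio. The ratio is undefined (NA, with
#' `ratio_undefined = TRUE`) when the slice contains no muscle.
#'
#' @param masks A `slice_masks` object (see [segment_volume()]).
#' @param voxel_spacing Numeric (row mm, col mm, slice mm), all positive.
#' @param circumference_side Optionally `"left"` or `"right"`: also measure
#'   the limb circumference of that leg (NA when the legs cannot be
#'   separated).
#' @param slice_index Optional slice index recorded in the output.
#' @return One-row data frame with `slice_index`, `sat_volume_ml`,
#'   `muscle_volume_ml`, `sat_muscle_ratio`, `ratio_undefined` and
#'   `circumference_cm`.
#' @export
slice_metrics <- function(masks, voxel_spacing, circumference_side = NULL,
                          slice_index = NA_integer_) {
  if (any(voxel_spacing <= 0)) stopf("voxel spacing must be strictly positive")
  vox_ml <- prod(voxel_spacing) / 1000
  sat_n <- sum(masks$sat)
  mus_n <- sum(masks$muscle_final)
  undef <- mus_n == 0L
  circ <- NA_real_
  if (!is.null(circumference_side)) {
    # merged legs (a single component) are flagged as NA for the slice
    circ <- tryCatch(
      withCallingHandlers(
        limb_circumference(masks$leg, voxel_spacing, side = circumference_side),
        warning = function(w) stop("merged")),
      error = function(e) NA_real_)
  }
  data.frame(slice_index = slice_index,
             sat_volume_ml = sat_n * vox_ml,
             muscle_volume_ml = mus_n * vox_ml,
             sat_muscle_ratio = if (undef) NA_real_ else sat_n / mus_n,
             ratio_undefined = undef,
             circumference_cm = circ)
}

#' Metrics for every slice of a segmented volume
#'
#' @param masks_list List of `slice_masks` from [segment_volume()].
#' @param voxel_spacing Numeric (row mm, col mm, slice mm).
#' @param circumference_side Optional side passed to [slice_metrics()].
#' @return Data frame with one row per slice, ordered ankle to thigh.
#' @export
volume_metrics <- function(masks_list, voxel_spacing, circumference_side = NULL) {
  do.call(rbind, lapply(seq_along(masks_list), function(z)
    slice_metrics(masks_list[[z]], voxel_spacing, circumference_side,
                  slice_index = z)))
}

#' Partition slices into ten decades
#'
#' Contiguous groups each containing 10% of the slices, with boundaries at
#' `floor(d * n / 10)`; decade 1 is the ankle end. Ranges are disjoint,
#' exhaustive, and their sizes differ by at most one.
#'
#' @param n_slices Total slice count (>= 10).
#' @return Data frame with columns `decade`, `start`, `end`, `n`.
#' @export
decade_partition <- function(n_slices) {
  if (n_slices < 10L) stopf("need at least 10 slices to form decades (got %d)", n_slices)
  bounds <- as.integer(floor((0:10) * n_slices / 10))
  data.frame(decade = 1:10,
             start = bounds[1:10] + 1L,
             end = bounds[2:11],
             n = diff(bounds))
}

#' Decade-level summary of per-slice metrics
#'
#' Unweighted means of SAT volume, muscle volume and SAT-to-muscle ratio over
#' each decade's slices. Slices with an undefined ratio are excluded from the
#' ratio mean and counted in `n_ratio_undefined`.
#'
#' @param metrics Data frame from [volume_metrics()] (rows ordered ankle to
#'   thigh).
#' @return Data frame with one row per decade.
#' @export
decade_summaries <- function(metrics) {
  part <- decade_partition(nrow(metrics))
  do.call(rbind, lapply(1:10, function(d) {
    rows <- metrics[part$start[d]:part$end[d], ]
    ratios <- rows$sat_muscle_ratio[!rows$ratio_undefined]
    data.frame(decade = d,
               start = part$start[d], end = part$end[d], n = part$n[d],
               mean_sat_volume_ml = mean(rows$sat_volume_ml),
               mean_muscle_volume_ml = mean(rows$muscle_volume_ml),
               mean_sat_muscle_ratio = if (length(ratios)) mean(ratios) else NA_real_,
               n_ratio_undefined = sum(rows$ratio_undefined),
               mean_circumference_cm = mean(rows$circumference_cm))
  }))
}

#' Middle slice of a decade
#'
#' The representative slice used for circumference and Dice validation in a
#' decade (e.g. decade 3 for the superior calf, decade 7 for the midthigh).
#'
#' @param n_slices Total slice count.
#' @param decade Decade number (1-10).
#' @return Slice index.
#' @export
decade_middle_slice <- function(n_slices, decade) {
  part <- decade_partition(n_slices)
  as.integer(floor((part$start[decade] + part$end[decade]) / 2))
}

#' Limb circumference of one leg
#'
#' Perimeter of the selected leg's outer contour, measured as the length of
#' the marching-squares boundary polygon in physical coordinates (anisotropic
#' spacing respected) after light smoothing, in cm. The subject-left leg is
#' the connected component whose centroid lies on the image-right half
#' (radiological convention).
#'
#' A mask holding a single connected component (one leg, or two merged legs)
#' is measured as-is with a warning; [slice_metrics()] treats that warning as
#' a merged-legs flag and records NA for the slice.
#'
#' @param leg_mask Logical mask containing both legs (or a single leg).
#' @param voxel_spacing Numeric (row mm, col mm, ...) spacing; only the
#'   in-plane entries are used.
#' @param side `"left"` or `"right"` (subject side).
#' @return Circumference in cm.
#' @export
limb_circumference <- function(leg_mask, voxel_spacing, side = c("left", "right")) {
  side <- match.arg(side)
  leg_mask <- as_mask(leg_mask)
  if (!any(leg_mask)) stopf("empty leg mask")
  lab <- label_components(leg_mask)
  n_comp <- max(lab)
  if (n_comp < 2L) {
    warnf("single connected component: legs may be merged; measuring it as-is")
    pick <- 1L
  } else {
    areas <- tabulate(lab[lab > 0], nbins = n_comp)
    two <- order(areas, decreasing = TRUE)[1:2]
    cent_col <- vapply(two, function(i) mean(col(lab)[lab == i]), numeric(1))
    # subject-left appears on image-right (larger column index)
    pick <- if (side == "left") two[which.max(cent_col)] else two[which.min(cent_col)]
  }
  comp <- lab == pick
  per_mm <- outer_perimeter(comp,
                            xs = seq_len(nrow(comp)) * voxel_spacing[1],
                            ys = seq_len(ncol(comp)) * voxel_spacing[2])
  per_mm / 10
}
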