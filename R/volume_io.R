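#' Multi-contrast chemical-shift-encoded MR volume
#'
#' Container for co-registered fat-weighted, water-weighted and in-phase
#' intensity volumes on a shared grid. Slices are ordered inferior (ankle) to
#' superior (thigh); in-plane rows run anterior-posterior and columns run
#' left-right with subject-left on image-right (radiological convention).
#'
#' @param fat,water,in_phase 3D non-negative numeric arrays `[row, col, slice]`
#'   sharing one shape.
#' @param voxel_spacing Numeric length-3: row, column and slice spacing in mm.
#' @return An object of class `cse_volume`.
#' @export
cse_volume <- function(fat, water, in_phase, voxel_spacing) {
  for (nm in c("fat", "water", "in_phase")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3L)
      stopf("'%s' must be a 3D array", nm)
    if (min(a) < 0) stopf("'%s' must be non-negative", nm)
  }
  assert_same_dim(fat, water, "contrasts")
  assert_same_dim(fat, in_phase, "contrasts")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stopf("'voxel_spacing' must be 3 strictly positive values (mm)")
  if (dim(fat)[3] < 1L) stopf("volume must contain at least one slice")
  structure(list(fat = fat, water = water, in_phase = in_phase,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "cse_volume")
}

#' @export
print.cse_volume <- function(x, ...) {
  d <- dim(x$fat)
  cat(sprintf("cse_volume: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_spacing[1], x$voxel_spacing[2],
              x$voxel_spacing[3]))
  invisible(x)
}

#' Number of axial slices in a volume
#' @param volume A [cse_volume].
#' @return Integer slice count.
#' @export
n_slices <- function(volume) dim(volume$fat)[3]

subset_slices <- function(volume, idx) {
  cse_volume(volume$fat[, , idx, drop = FALSE],
             volume$water[, , idx, drop = FALSE],
             volume$in_phase[, , idx, drop = FALSE],
             volume$voxel_spacing)
}

#' Read a multi-contrast volume from NIfTI files
#'
#' @param fat,water,in_phase Paths to NIfTI (`.nii`/`.nii.gz`) files holding
#'   the respective contrasts. All must share grid and voxel spacing.
#' @return A [cse_volume].
#' @export
read_cse_volume <- function(fat, water, in_phase) {
  paths <- c(fat = fat, water = water, in_phase = in_phase)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  imgs <- lapply(paths, RNifti::readNifti)
  sp <- RNifti::pixdim(imgs[[1]])[1:3]
  cse_volume(fat = array(as.numeric(imgs$fat), dim(imgs$fat)),
             water = array(as.numeric(imgs$water), dim(imgs$water)),
             in_phase = array(as.numeric(imgs$in_phase), dim(imgs$in_phase)),
             voxel_spacing = sp)
}

#' Write a multi-contrast volume as NIfTI files
#'
#' Writes `fat.nii.gz`, `water.nii.gz` and `inphase.nii.gz` (voxel spacing in
#' the header) into a directory.
#'
#' @param volume A [cse_volume].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cse_volume <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fat.nii.gz", "water.nii.gz", "inphase.nii.gz"))
  arrs <- list(volume$fat, volume$water, volume$in_phase)
  for (i in 1:3) {
    img <- RNifti::asNifti(arrs[[i]])
    RNifti::pixdim(img) <- volume$voxel_spacing
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Ordered set of overlapping acquisition stacks
#'
#' @param stacks List of [cse_volume] objects sharing in-plane grid and
#'   spacing.
#' @param offsets_mm Physical slice-axis offset (mm) of each stack's first
#'   slice; strictly increasing.
#' @return An object of class `stack_set`.
#' @export
stack_set <- function(stacks, offsets_mm) {
  if (length(stacks) < 1L) stopf("need at least one stack")
  if (length(offsets_mm) != length(stacks))
    stopf("one offset per stack required")
  if (length(offsets_mm) > 1 && any(diff(offsets_mm) <= 0))
    stopf("stack offsets must be strictly increasing")
  d1 <- dim(stacks[[1]]$fat)[1:2]; sp1 <- stacks[[1]]$voxel_spacing
  for (s in stacks) {
    if (!identical(dim(s$fat)[1:2], d1))
      stopf("stacks must share the in-plane grid")
    if (max(abs(s$voxel_spacing - sp1)) > 1e-6)
      stopf("stacks must share voxel spacing")
  }
  structure(list(stacks = stacks, offsets_mm = as.numeric(offsets_mm)),
            class = "stack_set")
}

#' Stitch overlapping acquisition stacks into one volume
#'
#' Slice positions are computed from each stack's offset and the slice
#' spacing. Where two stacks supply the same physical position (within half
#' the slice spacing) the duplicate slice is removed and the copy from the
#' more superior stack is kept. A gap between stacks larger than one slice
#' spacing is tolerated with a warning (volumes are concatenated).
#'
#' @param stacks A [stack_set].
#' @return A [cse_volume] with strictly increasing slice positions.
#' @export
stitch_stacks <- function(stacks) {
  if (!inherits(stacks, "stack_set")) stopf("'stacks' must be a stack_set")
  vols <- stacks$stacks
  if (length(vols) == 1L) return(vols[[1]])
  dz <- vols[[1]]$voxel_spacing[3]
  tol <- dz / 2

  tab <- do.call(rbind, lapply(seq_along(vols), function(i) {
    nz <- n_slices(vols[[i]])
    data.frame(pos = stacks$offsets_mm[i] + (seq_len(nz) - 1L) * dz,
               stack = i, slice = seq_len(nz))
  }))
  tab <- tab[order(tab$pos, tab$stack), ]

  # Cluster positions closer than tol; within a cluster keep the slice from
  # the most superior (largest-offset) stack.
  keep <- logical(nrow(tab))
  i <- 1L
  while (i <= nrow(tab)) {
    j <- i
    while (j < nrow(tab) && tab$pos[j + 1L] - tab$pos[i] < tol) j <- j + 1L
    grp <- i:j
    keep[grp[which.max(tab$stack[grp])]] <- TRUE
    i <- j + 1L
  }
  kept <- tab[keep, ]
  gaps <- diff(kept$pos)
  if (any(gaps > dz + tol))
    warnf("gap of %.1f mm between stacks exceeds one slice spacing; volumes concatenated",
          max(gaps))

  pick <- function(field) {
    arrs <- lapply(seq_len(nrow(kept)), function(r)
      vols[[kept$stack[r]]][[field]][, , kept$slice[r], drop = FALSE])
    do.call(function(...) abind3(...), arrs)
  }
  cse_volume(pick("fat"), pick("water"), pick("in_phase"),
             vols[[1]]$voxel_spacing)
}

# Minimal 3rd-axis bind (avoids an abind dependency).
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:2]
  nz <- sum(vapply(xs, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d, nz))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[3]
    out[, , (at + 1L):(at + k)] <- a
    at <- at + k
  }
  out
}

#' Select the analyzed lower-extremity slice range
#'
#' Extracts the inclusive sub-volume between two manually chosen landmark
#' slices (inferior ankle and superior thigh) in the inferior-to-superior
#' slice ordering.
#'
#' @param volume A [cse_volume].
#' @param lower_slice Index of the most inferior (ankle) slice.
#' @param upper_slice Index of the most superior (thigh) slice.
#' @return A [cse_volume] with `upper_slice - lower_slice + 1` slices.
#' @export
select_lower_extremity <- function(volume, lower_slice, upper_slice) {
  nz <- n_slices(volume)
  if (lower_slice < 1L || upper_slice > nz)
    stopf("slice range [%d, %d] out of bounds (1..%d)", lower_slice, upper_slice, nz)
  if (lower_slice > upper_slice)
    stopf("reversed range: lower_slice (%d) > upper_slice (%d)", lower_slice, upper_slice)
  subset_slices(volume, lower_slice:upper_slice)
}
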