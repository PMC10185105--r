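# Internal helpers shared across modules. All masks are logical matrices in
# [row, col] orientation; volumes are [row, col, slice] arrays.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_mask <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || !(is.logical(m) || all(m %in% c(0, 1))))
    stopf("'%s' must be a binary matrix", name)
  invisible(m)
}

as_mask <- function(m) {
  if (is.logical(m)) m else matrix(m > 0.5, nrow(m), ncol(m))
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopf("%s must share the same grid (got %s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
}

# Local box mean with replicate padding via integral images. Exact (no FFT);
# k must be odd. Matches a brute-force mean over the clamped k x k window.
local_mean_box <- function(m, k) {
  if (k == 1L) return(m)
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  cs <- apply(p, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  cs <- rbind(0, cbind(0, cs))
  nR <- nr + 2L * h + 1L; nC <- nc + 2L * h + 1L
  (cs[(1L + k):nR, (1L + k):nC, drop = FALSE] -
     cs[1:(nR - k), (1L + k):nC, drop = FALSE] -
     cs[(1L + k):nR, 1:(nC - k), drop = FALSE] +
     cs[1:(nR - k), 1:(nC - k), drop = FALSE]) / k^2
}

# 3x3 neighbour count (zero padding), used for majority smoothing of binary
# level sets in the active-contour iterations.
box_sum3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1:nr, 1:nc] + p[2:(nr + 1L), 1:nc] + p[3:(nr + 2L), 1:nc] +
    p[1:nr, 2:(nc + 1L)] + p[2:(nr + 1L), 2:(nc + 1L)] + p[3:(nr + 2L), 2:(nc + 1L)] +
    p[1:nr, 3:(nc + 2L)] + p[2:(nr + 1L), 3:(nc + 2L)] + p[3:(nr + 2L), 3:(nc + 2L)]
}

# Erosion by a k x k square structuring element anchored at its top-left
# pixel (even kernels have no centre; the anchor is fixed for
# reproducibility). Pixels outside the image count as background.
erode_square_topleft <- function(mask, k) {
  mask <- as_mask(mask)
  if (k <= 1L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(TRUE, nr, nc)
  p <- matrix(FALSE, nr + k - 1L, nc + k - 1L)
  p[1:nr, 1:nc] <- mask
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    out <- out & p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  out
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

morph_close <- function(mask, radius) {
  if (radius < 1L) return(as_mask(mask))
  as_mask(EBImage::closing(as_mask(mask) + 0, disc_brush(radius)))
}

morph_open <- function(mask, radius) {
  if (radius < 1L) return(as_mask(mask))
  as_mask(EBImage::opening(as_mask(mask) + 0, disc_brush(radius)))
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; labels
# touching diagonally are merged so thin oblique structures (fat streaks,
# contour arcs) stay single objects, matching the usual region-analysis
# convention.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(as_mask(mask) + 0)
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # "\" diagonal neighbours
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # "/" diagonal neighbours
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, numeric(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

remove_small_objects <- function(mask, min_area) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(as_mask(mask))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Fill every background component fully enclosed by foreground.
fill_all_holes <- function(mask) {
  as_mask(EBImage::fillHull(as_mask(mask) + 0))
}

# Fill only enclosed background components with area < max_area, preserving
# larger holes (e.g. bones).
fill_small_holes <- function(mask, max_area) {
  mask <- as_mask(mask)
  holes <- fill_all_holes(mask) & !mask
  if (!any(holes)) return(mask)
  lab <- label_components(holes)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < max_area)
  mask | matrix(lab %in% small, nrow(mask), ncol(mask))
}

# Closed-polygon moving average (circular window), used to de-staircase
# marching-squares contours before measuring their length.
smooth_closed_polygon <- function(x, y, window = 5L) {
  n <- length(x)
  if (n <= window) return(list(x = x, y = y))
  pad <- (window - 1L) %/% 2L
  sm <- function(v) {
    vv <- c(v[(n - pad + 1L):n], v, v[1:pad])
    as.numeric(stats::filter(vv, rep(1 / window, window), sides = 2L))[(pad + 1L):(pad + n)]
  }
  list(x = sm(x), y = sm(y))
}

closed_polygon_length <- function(x, y) {
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  sum(sqrt(dx^2 + dy^2))
}

# Outer boundary polygons of a binary mask by marching squares at level 0.5,
# in physical coordinates (xs = row positions, ys = column positions). The
# mask is zero-padded so boundaries touching the image edge stay closed.
outer_contours <- function(mask, xs = seq_len(nrow(mask)), ys = seq_len(ncol(mask))) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  dx <- if (nr > 1) diff(xs[1:2]) else 1
  dy <- if (nc > 1) diff(ys[1:2]) else 1
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask
  grDevices::contourLines(x = c(xs[1] - dx, xs, xs[nr] + dx),
                          y = c(ys[1] - dy, ys, ys[nc] + dy),
                          z = z, levels = 0.5)
}

# Smoothed outer-contour perimeter of a single-component mask (physical
# units). With several contours (component + holes) the longest one is the
# outer boundary.
outer_perimeter <- function(mask, xs = seq_len(nrow(mask)), ys = seq_len(ncol(mask)),
                            window = 5L) {
  cl <- outer_contours(mask, xs, ys)
  if (length(cl) == 0L) return(0)
  lens <- vapply(cl, function(ct) {
    p <- smooth_closed_polygon(ct$x, ct$y, window)
    closed_polygon_length(p$x, p$y)
  }, numeric(1))
  max(lens)
}

# Total boundary length of a mask: sum over all smoothed marching-squares
# contours, i.e. the exterior boundary plus any hole boundaries.
total_perimeter <- function(mask, xs = seq_len(nrow(mask)), ys = seq_len(ncol(mask)),
                            window = 5L) {
  cl <- outer_contours(mask, xs, ys)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(ct) {
    p <- smooth_closed_polygon(ct$x, ct$y, window)
    closed_polygon_length(p$x, p$y)
  }, numeric(1)))
}

# Circularity 4*pi*A/P^2 per labelled component. P is the full boundary
# length including hole boundaries (the scikit-image/ImageJ convention), so a
# solid marrow disc scores near 1 while a subcutaneous annulus -- however
# thick -- scores (r - r_in)/(r + r_in) and is never mistaken for a disc.
component_circularity <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  areas <- tabulate(lab[lab > 0], nbins = n)
  vapply(seq_len(n), function(i) {
    per <- total_perimeter(lab == i)
    if (per <= 0) return(1)
    min(4 * pi * areas[i] / per^2, 1)
  }, numeric(1))
}

# Global Otsu threshold (256-bin) on a non-negative intensity matrix.
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  x <- (m - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  rng[1] + t01 * diff(rng)
}

# Bounding-box height (row extent, px) of a mask; 0 when empty.
bbox_height <- function(mask) {
  rows <- which(rowSums(as_mask(mask)) > 0)
  if (length(rows) == 0L) return(0L)
  as.integer(max(rows) - min(rows) + 1L)
}
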