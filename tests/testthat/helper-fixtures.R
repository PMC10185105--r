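# Shared fixtures: small phantoms and toy masks, built in code at test time.

# A reduced phantom description for fast per-test segmentation.
small_spec <- function(n_slices = 12L, seed = 1L, ...) {
  phantom_spec(n_slices = n_slices, seed = seed, ...)
}

disc_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - center[1])^2 + (col(m) - center[2])^2 <= radius^2] <- TRUE
  m
}

annulus_mask <- function(n, r_outer, r_inner, center = c((n + 1) / 2, (n + 1) / 2)) {
  disc_mask(n, r_outer, center) & !disc_mask(n, r_inner, center)
}

# A crescent: a disc minus an offset disc, elongated and non-circular.
crescent_mask <- function(n = 40, radius = 12, offset = 7) {
  c0 <- c((n + 1) / 2, (n + 1) / 2)
  disc_mask(n, radius, c0) & !disc_mask(n, radius, c0 + c(0, offset))
}

# Tiny volume with constant value, for stitching arithmetic.
const_volume <- function(nz, value = 1, spacing = c(1, 1, 3), nr = 4, nc = 4) {
  a <- array(value, c(nr, nc, nz))
  cse_volume(a, a, a, spacing)
}

# Brute-force local-mean oracle (clamped window = replicate padding).
brute_local_mean <- function(m, k) {
  h <- (k - 1) / 2
  out <- m * 0
  for (r in seq_len(nrow(m))) for (cl in seq_len(ncol(m))) {
    rs <- pmin(pmax((r - h):(r + h), 1), nrow(m))
    cs <- pmin(pmax((cl - h):(cl + h), 1), ncol(m))
    out[r, cl] <- mean(m[rs, cs])
  }
  out
}

# Random binary mask for symmetry/property sweeps.
random_mask <- function(n, p = 0.3) matrix(stats::runif(n * n) < p, n, n)
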