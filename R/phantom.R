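# Synthetic multi-contrast lower-extremity phantoms with ground-truth labels.
#
# Each axial slice holds two roughly elliptical legs (mild per-slice
# eccentricity jitter so the subcutaneous ring is not trivially circular),
# each with a thin skin rim, a subcutaneous adipose (SAT) annulus, a muscle
# interior, one or two circular bones with fat-bright marrow inside a 1-px
# dark cortex, and optional thin intramuscular fat (IMAT) arcs. Contrasts are
# complementary: fat-weighted is bright on SAT/marrow/IMAT, water-weighted on
# muscle, and in-phase over the whole leg. A smooth multiplicative bias field
# (centred in-plane Gaussian drop-off plus a linear ramp along the slice
# axis) and additive Gaussian noise perturb all three contrasts; truth labels
# are returned unperturbed.

LABEL_INTENSITY <- list(
  fat      = c(bg = 0.02, skin = 0.08, sat = 1.00, muscle = 0.08,
               marrow = 1.00, imat = 1.00),
  water    = c(bg = 0.02, skin = 0.08, sat = 0.25, muscle = 1.00,
               marrow = 0.10, imat = 0.10),
  in_phase = c(bg = 0.02, skin = 0.80, sat = 1.00, muscle = 1.00,
               marrow = 1.00, imat = 1.00)
)

#' Parametric description of a two-leg phantom
#'
#' Defaults emulate a desk-scale lower-extremity acquisition: a 96 x 192
#' in-plane grid at 2.07 x 1.35 mm holding two legs side by side, 60 slices
#' at 3 mm ordered ankle to thigh, leg radius tapering 20 to 26 px, SAT
#' annulus 6 to 9 px, two bones in calf-like slices and one in thigh-like
#' slices, two 2-px IMAT arcs, 30% bias-field modulation and 5% additive
#' noise.
#'
#' @param n_slices Number of axial slices.
#' @param in_plane_shape Integer (rows, cols) of each slice.
#' @param voxel_spacing Numeric (row mm, col mm, slice mm).
#' @param leg_separation Distance in px between the two leg centres (columns).
#' @param leg_radius_profile Per-slice anterior-posterior leg semi-axis in px
#'   (tapering ankle to thigh); default linear 20 to 26.
#' @param sat_thickness_profile Per-slice SAT annulus thickness in px;
#'   default linear 6 to 8.
#' @param skin_thickness Skin rim thickness in px.
#' @param n_bones_profile Per-slice bone count; default 2 in the lower
#'   (calf-like) half, 1 in the upper (thigh-like) half.
#' @param bone_radius Marrow radius in px of the single thigh-like bone;
#'   calf-like slices carry two 2-px bones.
#' @param imat_streaks Number of thin IMAT arcs inside muscle (0-2).
#' @param imat_width Width of the IMAT arcs in px.
#' @param bias_field_amplitude Fractional intensity modulation in `[0, 1)`.
#' @param noise_sigma Additive Gaussian noise, as a fraction of the tissue
#'   intensity.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 60L,
                         in_plane_shape = c(96L, 192L),
                         voxel_spacing = c(2.07, 1.35, 3.0),
                         leg_separation = 96L,
                         leg_radius_profile = NULL,
                         sat_thickness_profile = NULL,
                         skin_thickness = 2,
                         n_bones_profile = NULL,
                         bone_radius = 4,
                         imat_streaks = 2L,
                         imat_width = 2,
                         bias_field_amplitude = 0.3,
                         noise_sigma = 0.05,
                         seed = 1L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stopf("'n_slices' must be >= 1")
  if (is.null(leg_radius_profile))
    leg_radius_profile <- seq(20, 26, length.out = n_slices)
  if (is.null(sat_thickness_profile))
    sat_thickness_profile <- seq(6, 8, length.out = n_slices)
  if (is.null(n_bones_profile))
    n_bones_profile <- ifelse(seq_len(n_slices) <= n_slices / 2, 2L, 1L)
  spec <- structure(list(
    n_slices = n_slices,
    in_plane_shape = as.integer(in_plane_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    leg_separation = leg_separation,
    leg_radius_profile = leg_radius_profile,
    sat_thickness_profile = sat_thickness_profile,
    skin_thickness = skin_thickness,
    n_bones_profile = as.integer(n_bones_profile),
    bone_radius = bone_radius,
    imat_streaks = as.integer(imat_streaks),
    imat_width = imat_width,
    bias_field_amplitude = bias_field_amplitude,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Worst-case eccentricity used both for validation and jitter bounds.
ECC_BASE <- 0.85
ECC_JITTER <- 0.04

validate_phantom_spec <- function(spec) {
  n <- spec$n_slices
  for (nm in c("leg_radius_profile", "sat_thickness_profile", "n_bones_profile"))
    if (length(spec[[nm]]) != n) stopf("'%s' must have length n_slices (%d)", nm, n)
  if (any(spec$leg_radius_profile <= 0)) stopf("leg radii must be positive")
  if (any(spec$sat_thickness_profile < 0)) stopf("SAT thickness must be >= 0")
  if (spec$skin_thickness < 0) stopf("skin thickness must be >= 0")
  if (spec$bias_field_amplitude < 0 || spec$bias_field_amplitude >= 1)
    stopf("bias_field_amplitude must lie in [0, 1)")
  if (spec$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (!spec$imat_streaks %in% 0:2) stopf("imat_streaks must be 0, 1 or 2")
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  for (z in seq_len(n)) {
    g <- slice_geometry(spec, z, ecc = ECC_BASE - ECC_JITTER)
    if (g$b_muscle <= 1)
      stopf("slice %d: skin + SAT leave no room for muscle (leg radius %.1f px)",
            z, spec$leg_radius_profile[z])
    for (bn in g$bones) {
      margin <- bn$radius + 2  # clearance from the muscle boundary
      if (g$a_muscle <= margin || g$b_muscle <= margin ||
          (bn$dr / (g$a_muscle - margin))^2 + (bn$dc / (g$b_muscle - margin))^2 > 1)
        stopf("slice %d: bone of radius %d px does not fit inside the muscle region",
              z, bn$radius)
    }
    if (g$c0[1] - g$b < 1 || g$c0[2] + g$b > nc || g$r0 - g$a < 1 || g$r0 + g$a > nr)
      stopf("slice %d: legs exceed the in-plane grid", z)
  }
  invisible(spec)
}

# Geometry of one slice: ellipse semi-axes, tissue offsets, bone placement.
slice_geometry <- function(spec, z, ecc) {
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  R <- spec$leg_radius_profile[z]
  a <- R                      # anterior-posterior semi-axis (rows)
  b <- R * ecc                # left-right semi-axis (cols)
  sat <- spec$sat_thickness_profile[z]
  skin <- spec$skin_thickness
  q <- min((skin + sat) / b, 1)
  a_m <- a * (1 - q); b_m <- b * (1 - q)
  # calf-like slices carry two small bones (tibia/fibula), thigh-like slices
  # one larger central bone (femur)
  bones <- if (spec$n_bones_profile[z] >= 2L) {
    list(list(dr = -0.12 * a_m, dc = -0.32 * b_m, radius = 2),
         list(dr = 0.12 * a_m, dc = 0.32 * b_m, radius = 2))
  } else if (spec$n_bones_profile[z] == 1L) {
    list(list(dr = 0, dc = 0, radius = spec$bone_radius))
  } else list()
  list(r0 = (nr + 1) / 2,
       c0 = (nc + 1) / 2 + c(-1, 1) * spec$leg_separation / 2,
       a = a, b = b, skin = skin, sat = sat,
       a_muscle = a_m, b_muscle = b_m, bones = bones)
}

# Integer tissue codes used in label volumes.
TISSUE_CODES <- c(bg = 0L, skin = 1L, sat = 2L, muscle = 3L, marrow = 4L,
                  imat = 5L)

draw_slice_labels <- function(spec, z, ecc_pair) {
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  lab <- matrix(TISSUE_CODES[["bg"]], nr, nc)
  rr <- row(lab); cc <- col(lab)
  for (leg in 1:2) {
    g <- slice_geometry(spec, z, ecc = ecc_pair[leg])
    r0 <- g$r0; c0 <- g$c0[leg]
    rho <- sqrt(((rr - r0) / g$a)^2 + ((cc - c0) / g$b)^2)
    inside <- rho <= 1
    depth <- (1 - rho) * g$b  # approx. distance to the boundary, px
    lab[inside & depth <= g$skin] <- TISSUE_CODES[["skin"]]
    lab[inside & depth > g$skin & depth <= g$skin + g$sat] <- TISSUE_CODES[["sat"]]
    musc <- inside & depth > g$skin + g$sat
    lab[musc] <- TISSUE_CODES[["muscle"]]
    for (bn in g$bones) {
      d2 <- (rr - (r0 + bn$dr))^2 + (cc - (c0 + bn$dc))^2
      lab[musc & d2 <= bn$radius^2] <- TISSUE_CODES[["marrow"]]
    }
    if (spec$imat_streaks > 0L && g$b_muscle > 4) {
      rho_m <- sqrt(((rr - r0) / g$a_muscle)^2 + ((cc - c0) / g$b_muscle)^2)
      theta <- atan2(cc - c0, rr - r0)
      band <- abs(rho_m - 0.55) <= spec$imat_width / (2 * g$b_muscle)
      arcs <- list(c(30, 90), c(200, 250))[seq_len(spec$imat_streaks)]
      in_arc <- Reduce(`|`, lapply(arcs, function(aw) {
        th <- theta * 180 / pi
        th >= aw[1] - 180 & th <= aw[2] - 180 | th >= aw[1] & th <= aw[2]
      }))
      sel <- band & in_arc & lab == TISSUE_CODES[["muscle"]]
      lab[sel] <- TISSUE_CODES[["imat"]]
    }
  }
  lab
}

bias_field <- function(spec) {
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  nz <- spec$n_slices; A <- spec$bias_field_amplitude
  if (A == 0) return(array(1, c(nr, nc, nz)))
  sigma <- 0.35 * max(nr, nc)
  d2 <- outer((seq_len(nr) - (nr + 1) / 2)^2, (seq_len(nc) - (nc + 1) / 2)^2, `+`)
  inplane <- 1 - A * (1 - exp(-d2 / (2 * sigma^2)))
  ramp <- if (nz > 1L) 1 - 0.5 * A * (seq_len(nz) - 1) / (nz - 1) else 1
  out <- array(0, c(nr, nc, nz))
  for (z in seq_len(nz)) out[, , z] <- inplane * ramp[z]
  out
}

#' Generate a synthetic multi-contrast leg phantom
#'
#' Builds ground-truth tissue labels from the parametric geometry in `spec`,
#' synthesizes the three contrasts from per-tissue intensities, then applies
#' the multiplicative bias field and additive Gaussian noise (clamped at
#' zero, as in magnitude images). Identical specs and seeds produce
#' bit-identical output.
#'
#' @param spec A [phantom_spec].
#' @param group_label Group label stored in the truth object
#'   (`"control-like"` or `"lipedema-like"`).
#' @return A list with elements `volume` (a [cse_volume]) and `truth` (a
#'   `phantom_truth`: logical label volumes `leg`, `skin`, `sat`, `muscle`,
#'   `marrow`, `imat`, plus `group_label`).
#' @export
generate_phantom <- function(spec, group_label = "control-like") {
  validate_phantom_spec(spec)
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]; nz <- spec$n_slices
  withr::with_seed(spec$seed, {
    labels <- array(0L, c(nr, nc, nz))
    for (z in seq_len(nz)) {
      ecc_pair <- ECC_BASE + stats::runif(2, -ECC_JITTER, ECC_JITTER)
      labels[, , z] <- draw_slice_labels(spec, z, ecc_pair)
    }
    field <- bias_field(spec)
    contrast <- function(name) {
      lut <- LABEL_INTENSITY[[name]]  # ordered by the 0..5 tissue codes
      v <- array(lut[labels + 1L], dim(labels))
      v <- v * field
      if (spec$noise_sigma > 0)
        v <- v + stats::rnorm(length(v), 0, spec$noise_sigma)
      pmax(v, 0)
    }
    vol <- cse_volume(contrast("fat"), contrast("water"), contrast("in_phase"),
                      spec$voxel_spacing)
  })
  truth <- structure(list(
    leg = labels > 0L,
    skin = labels == TISSUE_CODES[["skin"]],
    sat = labels == TISSUE_CODES[["sat"]],
    muscle = labels == TISSUE_CODES[["muscle"]],
    marrow = labels == TISSUE_CODES[["marrow"]],
    imat = labels == TISSUE_CODES[["imat"]],
    labels = labels,
    group_label = group_label), class = "phantom_truth")
  list(volume = vol, truth = truth, spec = spec)
}

#' Generate a two-group phantom cohort
#'
#' Applies per-subject random jitter to the leg radius and SAT thickness of a
#' base phantom description and scales the lipedema-like group's SAT
#' thickness by `sat_multiplier`. Any SAT thickness beyond the subject's base
#' value expands the leg radius outward (disproportionate subcutaneous
#' deposition enlarges the limb; the muscle compartment is unchanged).
#' Reproducible from `seed`.
#'
#' @param n_control,n_lipedema Subjects per group (>= 1).
#' @param base_spec A [phantom_spec] shared by all subjects.
#' @param sat_multiplier SAT-thickness factor for the lipedema-like group
#'   (> 0; 1 yields a null cohort differing only by jitter).
#' @param seed Integer seed controlling jitter and per-subject phantom seeds.
#' @return A list of per-subject lists (`volume`, `truth`, `spec`, `group`,
#'   `subject`), with a `manifest` attribute (data frame of subject, group,
#'   seed and jitter factors).
#' @export
generate_cohort <- function(n_control, n_lipedema, base_spec = phantom_spec(),
                            sat_multiplier = 1.75, seed = 1L) {
  if (n_control < 1L || n_lipedema < 1L)
    stopf("both groups need at least one subject")
  if (sat_multiplier <= 0) stopf("'sat_multiplier' must be positive")
  n <- n_control + n_lipedema
  groups <- c(rep("control-like", n_control), rep("lipedema-like", n_lipedema))
  jit <- withr::with_seed(seed, {
    data.frame(
      subject = seq_len(n),
      group = groups,
      seed = sample.int(2^30, n),
      radius_scale = pmin(pmax(stats::rnorm(n, 1, 0.12), 0.80), 1.20),
      sat_scale = pmin(pmax(stats::rnorm(n, 1, 0.15), 0.80), 1.20))
  })
  jit$sat_multiplier <- ifelse(jit$group == "lipedema-like", sat_multiplier, 1)
  out <- lapply(seq_len(n), function(i) {
    sp <- subject_spec(base_spec, jit[i, ])
    ph <- generate_phantom(sp, group_label = jit$group[i])
    ph$group <- jit$group[i]
    ph$subject <- i
    ph
  })
  attr(out, "manifest") <- jit
  out
}

# Per-subject spec from a manifest row (used by generate_cohort and the CLI
# when regenerating a cohort from its manifest CSV). SAT thickness beyond the
# subject's jittered base expands the leg radius so that the muscle
# compartment is preserved; the expansion is divided by the minimum column
# eccentricity so the lateral SAT gain is at least the nominal thickness.
subject_spec <- function(base_spec, row) {
  sp <- base_spec
  base_sat <- base_spec$sat_thickness_profile * row$radius_scale
  sat_t <- base_sat * row$sat_scale * row$sat_multiplier
  extra_r <- pmax(sat_t - base_sat, 0) / (ECC_BASE - ECC_JITTER)
  sp$leg_radius_profile <- base_spec$leg_radius_profile * row$radius_scale + extra_r
  sp$sat_thickness_profile <- sat_t
  sp$seed <- as.integer(row$seed)
  validate_phantom_spec(sp)
  sp
}

#' Write a phantom to disk as NIfTI + labels
#'
#' Writes the three contrasts via [write_cse_volume()] and the ground-truth
#' labels as one unsigned-integer NIfTI volume (`labels.nii.gz`, codes 0 =
#' background, 1 = skin, 2 = SAT, 3 = muscle, 4 = marrow, 5 = IMAT, 6 = bone
#' cortex).
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(phantom, dir) {
  paths <- write_cse_volume(phantom$volume, dir)
  lab <- RNifti::asNifti(phantom$truth$labels)
  RNifti::pixdim(lab) <- phantom$volume$voxel_spacing
  lp <- file.path(dir, "labels.nii.gz")
  RNifti::writeNifti(lab, lp)
  invisible(c(paths, lp))
}
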