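# Five-step segmentation: per-step oracles on toys and phantom slices,
# kernel-size rule, determinism and mask algebra.

test_that("kernel-size rule matches its printed hand evaluations", {
  expect_identical(compute_adaptive_kernel_size(0), 1L)
  expect_identical(compute_adaptive_kernel_size(8, 3 / 4), 7L)
  expect_identical(compute_adaptive_kernel_size(100, 3 / 4), 75L)
  expect_error(compute_adaptive_kernel_size(-1), "non-negative")
})

test_that("kernel-size rule agrees with brute force and is always odd", {
  for (hbox in seq(0, 300, by = 7)) {
    s <- compute_adaptive_kernel_size(hbox)
    expect_identical(s, as.integer(2 * floor(hbox * 0.75 / 2) + 1))
    expect_true(s %% 2L == 1L && s >= 1L)
  }
})

test_that("leg boundary covers the truth leg on a clean phantom slice", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, bias_field_amplitude = 0))
  z <- 6
  leg <- segment_leg_boundary(ph$volume$in_phase[, , z])
  truth <- ph$truth$leg[, , z]
  expect_gte(sum(leg & truth) / sum(truth), 0.99)          # coverage
  expect_lte(sum(leg & !truth) / sum(!truth), 0.01)        # background leak
  expect_equal(max(legcomp:::label_components(leg)), 2)    # two legs
})

test_that("an all-background slice yields an empty mask with a warning", {
  expect_warning(m <- segment_leg_boundary(matrix(0, 32, 32)), "all-background")
  expect_false(any(m))
})

test_that("a bright blob outside the legs joins the boundary mask as a third component", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, bias_field_amplitude = 0))
  z <- 6
  ip <- ph$volume$in_phase[, , z]
  blob <- matrix(FALSE, nrow(ip), ncol(ip))
  blob[(row(blob) - 10)^2 + (col(blob) - 96)^2 <= 36] <- TRUE  # arm-like blob
  expect_false(any(blob & ph$truth$leg[, , z]))
  ip[blob] <- 1
  m <- segment_leg_boundary(ip)
  expect_equal(max(legcomp:::label_components(m)), 3)
  expect_gte(sum(m & blob) / sum(blob), 0.8)
})

test_that("adaptive classification equals the brute-force local-mean oracle", {
  set.seed(21)
  img <- matrix(runif(400), 20, 20)
  water <- matrix(runif(400), 20, 20)
  leg <- disc_mask(20, 9)
  for (k in c(3L, 7L, 11L)) {
    got <- classify_fat_water(img, water, leg, k)
    thr <- brute_local_mean(img * leg, k)      # sensitivity 0.5 -> factor 1
    expect_identical(got$fat, (img * leg > thr) & leg)
    expect_true(all(leg[got$fat]))
    expect_true(all(leg[got$water]))
  }
  expect_error(classify_fat_water(img, water, leg, 4L), "odd")
})

test_that("windows straddling a bright/dark split separate the two sides", {
  img <- matrix(0.3, 20, 20)
  img[, 11:20] <- 1
  leg <- matrix(TRUE, 20, 20)
  got <- classify_fat_water(img, img, leg, 9L)$fat
  # adjacent to the split: bright side above its local mean, dark side below
  expect_true(all(got[, 11:12]))
  expect_false(any(got[, 9:10]))
})

test_that("an all-zero contrast slice produces an empty mask", {
  leg <- disc_mask(20, 8)
  got <- classify_fat_water(matrix(0, 20, 20), matrix(0, 20, 20), leg, 7L)
  expect_false(any(got$fat))
  expect_false(any(got$water))
})

test_that("adaptive thresholding recovers fat under the default bias field", {
  ph <- generate_phantom(small_spec(bias_field_amplitude = 0.3, seed = 3))
  z <- 11  # most superior slice: strongest ramp attenuation
  m <- legcomp:::segment_slice(ph$volume$fat[, , z], ph$volume$water[, , z],
                               ph$volume$in_phase[, , z], "upper",
                               segmentation_config())
  truth_fat <- ph$truth$sat[, , z] | ph$truth$marrow[, , z] | ph$truth$imat[, , z]
  expect_gte(dice(m$fat, truth_fat), 0.95)
})

test_that("global thresholding drops a signal-attenuated leg, the local mean does not", {
  # one leg sits in a strong signal drop-off zone (15% of nominal intensity);
  # a global threshold discards its fat while the local mean recovers it
  n <- 100
  mk_leg <- function(c0) list(leg = disc_mask(n, 20, c(50, c0)),
                              fat = annulus_mask(n, 20, 13, c(50, c0)))
  A <- mk_leg(27); B <- mk_leg(73)
  leg <- A$leg | B$leg
  truth_fat <- A$fat | B$fat
  img <- matrix(0, n, n)
  img[A$fat] <- 0.15; img[A$leg & !A$fat] <- 0.08 * 0.15
  img[B$fat] <- 1.00; img[B$leg & !B$fat] <- 0.08
  ks <- compute_adaptive_kernel_size(legcomp:::bbox_height(leg))
  adaptive <- classify_fat_water(img, img, leg, ks)$fat
  otsu <- (img * leg > legcomp:::otsu_threshold(img * leg)) & leg
  expect_gte(dice(adaptive, truth_fat), 0.95)
  expect_lt(dice(otsu, truth_fat), dice(adaptive, truth_fat))
  expect_lt(dice(otsu, truth_fat), 0.90)
})

test_that("muscle step fills small holes early, bone-sized holes at flood fill", {
  n <- 40
  leg <- disc_mask(n, 18)
  water <- annulus_mask(n, 15, 7)              # muscle annulus, hole r=7
  water[20:21, 20:21] <- TRUE                  # leave a small 2x2 island
  water[22, 22] <- TRUE
  fat <- matrix(FALSE, n, n)
  out <- segment_muscle(water, fat, leg, "lower")
  # the enclosed bone-sized hole is filled by the final flood fill
  expect_true(all(out[disc_mask(n, 6)]))
  # filled area ~ annulus + hole (the skin erosion trims ~1 px on two sides)
  full <- sum(annulus_mask(n, 15, 7)) + sum(disc_mask(n, 7))
  expect_gte(sum(out), 0.90 * full)
  expect_lte(sum(out), 1.05 * full)
  # a tiny enclosed hole (< 18 px) is filled even without flood fill
  water2 <- disc_mask(n, 12)
  water2[18:19, 18:19] <- FALSE                # 4-px hole
  holes_filled <- legcomp:::fill_small_holes(water2, 18L)
  expect_true(all(holes_filled[18:19, 18:19]))
})

test_that("empty water mask yields an empty muscle mask", {
  n <- 30
  out <- segment_muscle(matrix(FALSE, n, n), matrix(FALSE, n, n),
                        disc_mask(n, 10), "lower")
  expect_false(any(out))
  expect_error(segment_muscle(matrix(FALSE, n, n), matrix(FALSE, n, n),
                              disc_mask(n, 10), "sideways"))
})

test_that("skin erosion kernel is top-left anchored and removes the printed sides", {
  m <- matrix(FALSE, 10, 10)
  m[3:7, 3:7] <- TRUE
  e <- legcomp:::erode_square_topleft(m, 2L)
  expect_true(all(e[3:6, 3:6]))     # top-left block survives
  expect_false(any(e[7, ]))         # bottom row eroded
  expect_false(any(e[, 7]))         # right column eroded
  expect_equal(sum(e), 16)
})

test_that("SAT step keeps a crescent and discards a disc by circularity", {
  n <- 48
  crescent <- crescent_mask(n)
  disc <- disc_mask(n, 6, c(10, 38))
  fat <- crescent | disc
  empty <- matrix(FALSE, n, n)
  out <- segment_sat(fat, empty)
  expect_false(any(out & disc))
  expect_gt(sum(out & crescent) / sum(legcomp:::morph_open(crescent, 2L)), 0.99)
  # empty input stays empty
  expect_false(any(segment_sat(empty, empty)))
})

test_that("circularity removes perfect discs of radius >= 4 and never 1-px arcs", {
  for (r in 4:10) {
    lab <- legcomp:::label_components(disc_mask(40, r))
    expect_gt(legcomp:::component_circularity(lab), 0.80)
  }
  # quarter-circle arcs, 1 px thick, various radii
  for (r in c(6, 10, 14)) {
    n <- 40; c0 <- (n + 1) / 2
    d <- sqrt((row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2)
    ang <- atan2(col(matrix(0, n, n)) - c0, row(matrix(0, n, n)) - c0)
    arc <- abs(d - r) <= 0.5 & ang > 0 & ang < pi / 2
    lab <- legcomp:::label_components(arc)
    expect_lt(legcomp:::component_circularity(lab), 0.80)
  }
})

test_that("SAT Dice on a phantom thigh slice exceeds 0.95", {
  ph <- generate_phantom(small_spec())
  z <- 10
  m <- legcomp:::segment_slice(ph$volume$fat[, , z], ph$volume$water[, , z],
                               ph$volume$in_phase[, , z], "upper",
                               segmentation_config())
  expect_gte(dice(m$sat, ph$truth$sat[, , z]), 0.95)
})

test_that("final muscle subtracts fat streaks exactly", {
  n <- 30
  muscle_filled <- disc_mask(n, 12)
  streak <- matrix(FALSE, n, n); streak[14:15, 6:24] <- TRUE
  sat <- matrix(FALSE, n, n); sat[1:2, 1:4] <- TRUE
  fat <- streak | sat
  out <- finalize_muscle(muscle_filled, fat, sat)
  expect_false(any(out & streak))
  expect_equal(sum(muscle_filled) - sum(out), sum(streak & muscle_filled))
  # fat entirely inside SAT: nothing subtracted
  expect_identical(finalize_muscle(muscle_filled, sat, sat), muscle_filled)
})

test_that("phantom IMAT is excluded from the final muscle mask", {
  ph <- generate_phantom(small_spec())
  masks <- segment_volume(ph$volume)
  imat_in <- sum(vapply(seq_along(masks), function(z)
    sum(masks[[z]]$muscle_final & ph$truth$imat[, , z]), numeric(1)))
  expect_lte(imat_in / sum(ph$truth$imat), 0.10)
})

test_that("segment_volume keeps invariants on every slice and is deterministic", {
  ph <- generate_phantom(small_spec())
  m1 <- segment_volume(ph$volume)
  expect_length(m1, 12)
  for (m in m1) {
    expect_false(any(m$sat & m$muscle_final))
    expect_true(all(m$leg[m$sat | m$muscle_final]))
    expect_true(m$kernel_size %% 2L == 1L)
  }
  m2 <- segment_volume(ph$volume)
  expect_identical(m1, m2)
})

test_that("overrides replace automated slices verbatim", {
  ph <- generate_phantom(small_spec(n_slices = 6))
  fake <- legcomp:::segment_slice(ph$volume$fat[, , 1], ph$volume$water[, , 1],
                                  ph$volume$in_phase[, , 1], "lower",
                                  segmentation_config())
  out <- segment_volume(ph$volume, overrides = list("3" = fake))
  expect_identical(out[[3]], fake)
  expect_error(segment_volume(ph$volume, overrides = list("9" = fake)), "1..6")
})

test_that("noiseless bias-free phantoms reach near-perfect Dice", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, bias_field_amplitude = 0))
  masks <- segment_volume(ph$volume)
  for (z in seq_along(masks)) {
    expect_gte(dice(masks[[z]]$sat, ph$truth$sat[, , z]), 0.98)
    expect_gte(dice(masks[[z]]$muscle_final, ph$truth$muscle[, , z]), 0.98)
  }
})

test_that("off-protocol in-plane spacing triggers the resolution warning", {
  ph <- generate_phantom(small_spec(n_slices = 2, voxel_spacing = c(1, 1, 3)))
  expect_warning(segment_volume(ph$volume), "2.07")
})
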