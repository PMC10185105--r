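# Composition metrics: volumes, ratios, decades and circumference oracles.

fake_masks <- function(n = 64, sat_n = 0, muscle_n = 0) {
  sat <- matrix(FALSE, n, n); muscle <- matrix(FALSE, n, n)
  if (sat_n > 0) sat[seq_len(sat_n)] <- TRUE
  if (muscle_n > 0) muscle[n * n - seq_len(muscle_n) + 1] <- TRUE
  structure(list(leg = sat | muscle, sat = sat, muscle_final = muscle),
            class = "slice_masks")
}

test_that("voxel volumes convert to mL at the protocol spacing", {
  m <- fake_masks(sat_n = 1000, muscle_n = 500)
  met <- slice_metrics(m, c(2.07, 1.35, 3.0))
  expect_equal(met$sat_volume_ml, 8.38, tolerance = 0.01 / 8.38)
  expect_equal(met$muscle_volume_ml, 500 * 2.07 * 1.35 * 3 / 1000)
})

test_that("the SAT-to-muscle ratio handles equal and degenerate inputs", {
  eq <- slice_metrics(fake_masks(sat_n = 200, muscle_n = 200), c(1, 1, 1))
  expect_equal(eq$sat_muscle_ratio, 1.0)
  none <- slice_metrics(fake_masks(sat_n = 50, muscle_n = 0), c(1, 1, 1))
  expect_true(none$ratio_undefined)
  expect_true(is.na(none$sat_muscle_ratio))
})

test_that("volumes scale with slice spacing, ratios do not", {
  m <- fake_masks(sat_n = 300, muscle_n = 100)
  a <- slice_metrics(m, c(2, 1, 1.5))
  b <- slice_metrics(m, c(2, 1, 3.0))
  expect_equal(b$sat_volume_ml, 2 * a$sat_volume_ml)
  expect_equal(a$sat_muscle_ratio, b$sat_muscle_ratio)
})

test_that("decade partition covers printed cases and the general sweep", {
  p230 <- decade_partition(230)
  expect_true(all(p230$n == 23))
  p10 <- decade_partition(10)
  expect_true(all(p10$n == 1))
  p229 <- decade_partition(229)
  expect_true(all(p229$n %in% c(22, 23)))
  expect_equal(sum(p229$n), 229)
  expect_error(decade_partition(9), "at least 10")
  for (n in seq(10, 500, by = 13)) {
    p <- decade_partition(n)
    expect_equal(p$start, c(1L, head(p$end, 9) + 1L))  # disjoint + exhaustive
    expect_equal(sum(p$n), n)
    expect_lte(diff(range(p$n)), 1)
  }
})

test_that("decade means are exact for constants and ramps, and conserve totals", {
  n <- 57
  const <- data.frame(sat_volume_ml = rep(2.5, n), muscle_volume_ml = rep(4, n),
                      sat_muscle_ratio = rep(0.625, n),
                      ratio_undefined = rep(FALSE, n),
                      circumference_cm = rep(30, n))
  dc <- decade_summaries(const)
  expect_equal(dc$mean_sat_volume_ml, rep(2.5, 10))
  expect_equal(dc$mean_sat_muscle_ratio, rep(0.625, 10))
  ramp <- const
  ramp$sat_volume_ml <- seq_len(n)
  dr <- decade_summaries(ramp)
  expect_true(all(diff(dr$mean_sat_volume_ml) > 0))
  # weighted-mean conservation
  expect_equal(sum(dr$n * dr$mean_sat_volume_ml), sum(ramp$sat_volume_ml))
})

test_that("undefined ratios are excluded from decade means, not zero-filled", {
  n <- 20
  met <- data.frame(sat_volume_ml = rep(1, n), muscle_volume_ml = rep(1, n),
                    sat_muscle_ratio = rep(2, n), ratio_undefined = rep(FALSE, n),
                    circumference_cm = rep(NA_real_, n))
  met$sat_muscle_ratio[1] <- NA; met$ratio_undefined[1] <- TRUE
  dc <- decade_summaries(met)
  expect_equal(dc$mean_sat_muscle_ratio[1], 2)  # the NA slice is dropped
  expect_equal(dc$n_ratio_undefined[1], 1)
})

test_that("circumference matches analytic oracles within 2%", {
  disc <- disc_mask(128, 50)
  expect_warning(c1 <- limb_circumference(disc, c(1, 1, 1), "left"), "single")
  expect_equal(c1, 2 * pi * 50 / 10, tolerance = 0.02)

  rect <- matrix(FALSE, 128, 128); rect[11:110, 31:80] <- TRUE
  expect_warning(c2 <- limb_circumference(rect, c(1, 1, 1), "left"), "single")
  expect_equal(c2, 30.0, tolerance = 0.02)

  # same disc at anisotropic spacing vs Ramanujan ellipse perimeter
  a <- 50 * 2.07; b <- 50 * 1.35
  raman <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_warning(c3 <- limb_circumference(disc, c(2.07, 1.35, 3), "left"), "single")
  expect_equal(c3, raman / 10, tolerance = 0.02)
})

test_that("circumference is invariant to slice spacing and picks the right leg", {
  two <- disc_mask(96, 20, c(48, 28)) | disc_mask(96, 10, c(48, 70))
  left <- limb_circumference(two, c(1, 1, 3), "left")    # image-right, r = 10
  right <- limb_circumference(two, c(1, 1, 9), "right")  # image-left, r = 20
  expect_equal(left, 2 * pi * 10 / 10, tolerance = 0.02)
  expect_equal(right, 2 * pi * 20 / 10, tolerance = 0.02)
  expect_equal(limb_circumference(two, c(1, 1, 1), "left"), left)
  expect_error(limb_circumference(matrix(FALSE, 4, 4), c(1, 1, 1)), "empty")
})

test_that("slice metrics flag merged legs with an NA circumference", {
  m <- fake_masks(sat_n = 40, muscle_n = 40)
  m$leg <- disc_mask(64, 20)  # one blob only
  met <- slice_metrics(m, c(1, 1, 1), circumference_side = "left")
  expect_true(is.na(met$circumference_cm))
})
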