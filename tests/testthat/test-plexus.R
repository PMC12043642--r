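test_that("area filter boundary: 1199 px removed, 1201 px retained", {
  msk <- matrix(FALSE, 300, 300)
  msk <- stamp_blob(msk, 50, 20, 1199, 11)
  msk <- stamp_blob(msk, 150, 20, 1201, 11)
  out <- component_filter(msk, min_area_px = 1200, min_diameter_px = 8)
  st <- attr(out, "components")
  expect_equal(nrow(st), 1)
  expect_equal(st$area_px, 1201)
  expect_equal(sum(out), 1201)
})

test_that("thickness filter: 6-px ribbons removed, 12-px retained", {
  msk <- matrix(FALSE, 300, 300)
  msk[10:15, 50:249] <- TRUE                 # 200 x 6
  msk[100:111, 50:249] <- TRUE               # 200 x 12
  out <- component_filter(msk, min_area_px = 1000, min_diameter_px = 8)
  st <- attr(out, "components")
  expect_equal(nrow(st), 1)
  expect_equal(st$area_px, 2400)
  expect_equal(st$mean_thickness_px, 12, tolerance = 0.05)
})

test_that("disks pass or fail the filters by their analytic geometry", {
  rr <- matrix(seq_len(200), 200, 200)
  cc <- t(rr)
  big <- (rr - 100)^2 + (cc - 100)^2 <= 25^2    # area ~1963, thickness ~50
  small <- (rr - 100)^2 + (cc - 100)^2 <= 15^2  # area ~707: removed by area
  expect_equal(nrow(attr(component_filter(big), "components")), 1)
  expect_equal(nrow(attr(component_filter(small), "components")), 0)
})

test_that("8-connectivity joins diagonally touching strand pieces", {
  msk <- matrix(FALSE, 100, 100)
  msk[10:40, 10:20] <- TRUE
  msk[41:71, 21:31] <- TRUE                  # touches only diagonally
  out <- component_filter(msk, min_area_px = 500, min_diameter_px = 5)
  expect_equal(nrow(attr(out, "components")), 1)
  expect_equal(attr(out, "components")$area_px, 2 * 31 * 11)
})

test_that("plexus density is a pixel fraction", {
  expect_equal(plexus_density(matrix(0, 10, 10)), 0)
  m <- matrix(0, 1000, 1000); m[1:250, 1:1000] <- 1
  expect_equal(plexus_density(m), 0.25)
  sim <- simulate_plexus_image(n_strands = 6, seed = 9)
  expect_equal(plexus_density(sim$truth_mask),
               sum(sim$truth_mask != 0) / length(sim$truth_mask))
  expect_error(plexus_density(matrix(numeric(), 0, 0)), "empty")
})

test_that("an all-background image segments to density 0", {
  set.seed(2)
  img <- matrix(0.2, 200, 200)
  seg <- segment_plexus(img, segmentation_config(bg_window_px = 51))
  expect_equal(seg$density, 0)
  expect_equal(nrow(seg$components), 0)
})

test_that("density survives a +/-30% illumination gradient within 2 pp", {
  for (sd in 1:3) {
    sim <- simulate_plexus_image(n_strands = 12, background_gradient_amp = 0.3,
                                 noise_sd = 0.05, seed = sd)
    seg <- segment_plexus(sim$image)
    expect_lt(abs(100 * seg$density - 100 * sim$truth_density), 2)
  }
})

test_that("full pipeline keeps the 1201 px blob and drops the 1199 px one", {
  img <- matrix(0, 300, 300)
  img <- ifelse(stamp_blob(matrix(FALSE, 300, 300), 50, 20, 1199, 11) |
                  stamp_blob(matrix(FALSE, 300, 300), 150, 20, 1201, 11),
                1, 0)
  cfg <- segmentation_config(bg_window_px = 299, light_blur_px = 1,
                             threshold_method = 0.5,
                             border_clean_px = 1, close_radius_px = 0)
  seg <- segment_plexus(img, cfg)
  expect_equal(seg$components$area_px, 1201)
})

test_that("density never increases as the component filters tighten", {
  sim <- simulate_plexus_image(n_strands = 8, noise_sd = 0.05, seed = 13)
  dens_by_area <- vapply(c(200, 800, 1600, 3200), function(a)
    segment_plexus(sim$image,
                   segmentation_config(min_area_px = a))$density, numeric(1))
  expect_true(all(diff(dens_by_area) <= 0))
  dens_by_diam <- vapply(c(2, 8, 14), function(d)
    segment_plexus(sim$image,
                   segmentation_config(min_diameter_px = d))$density, numeric(1))
  expect_true(all(diff(dens_by_diam) <= 0))
})

test_that("images smaller than the background window are refused", {
  expect_error(segment_plexus(matrix(0, 50, 50)), "smaller")
})
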