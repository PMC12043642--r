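test_that("a contraction-free noiseless map is constant at baseline", {
  m <- simulate_stmap(n_rows = 40, n_cols = 100, baseline_diameter_mm = 2.5,
                      seed = 1)
  expect_equal(unclass(m), matrix(2.5, 40, 100), ignore_attr = TRUE)
})

test_that("planted contraction minima advance at the planted velocity", {
  v <- 1.0
  m <- fixture_stmap(velocity = v, span = 0.9, origin = 0.02)
  # per-row argmin oracle on rows well inside the span
  rows <- 20:100
  argmin_col <- apply(unclass(m)[rows, ], 1, which.min)
  fit <- stats::lm(argmin_col ~ rows)
  slope_expected <- mm_per_row(m) / (v * s_per_frame(m))
  expect_equal(unname(coef(fit)[2]), slope_expected, tolerance = 0.01)
})

test_that("identical seeds give bitwise-identical noisy maps", {
  a <- fixture_stmap(noise_sd = 0.1, seed = 7)
  b <- fixture_stmap(noise_sd = 0.1, seed = 7)
  expect_identical(unclass(a), unclass(b))
})

test_that("unflagged truncation and out-of-window origins are rejected", {
  late <- true_contraction(880, 0.02, 0.9, 1.0, 0.5)
  expect_error(simulate_stmap(contractions = list(late), seed = 1),
               "truncated")
  flagged <- true_contraction(880, 0.02, 0.9, 1.0, 0.5, truncated = TRUE)
  m <- simulate_stmap(contractions = list(flagged), seed = 1)
  expect_true(attr(m, "truth")[[1]]$truncated)
  distal <- true_contraction(100, 0.2, 0.5, 1.0, 0.5)
  expect_error(simulate_stmap(contractions = list(distal), seed = 1),
               "originates")
})

test_that("plexus truth mask density is an exact pixel count", {
  sim <- simulate_plexus_image(n_strands = 5, seed = 3)
  expect_equal(sim$truth_density, sum(sim$truth_mask) / length(sim$truth_mask))
  empty <- simulate_plexus_image(n_strands = 0, seed = 1)
  expect_equal(empty$truth_density, 0)
  expect_false(any(empty$truth_mask))
})

test_that("distractor blobs are planted with their exact area", {
  sim <- simulate_plexus_image(n_strands = 0,
                               distractor_blobs = list(c(1199, 20)), seed = 2)
  expect_equal(sim$distractors$area_px, 1199)
})

test_that("planted somata are disjoint and the SHANK3:PGP gain is exact", {
  sim <- simulate_ganglia_image(n_somata = 30, soma_radius_px = 8,
                                min_separation_px = 24, seed = 5)
  lab <- EBImage::bwlabel(matrix(as.numeric(sim$truth$hucd_mask),
                                 nrow(sim$truth$hucd_mask)))
  expect_equal(max(lab), 30)
  pgp <- sim$image[, , 2]
  sh <- sim$image[, , 3]
  on <- sim$truth$pgp_mask
  expect_equal(sh[on] / pgp[on], rep(sim$truth$shank3_pgp_ratio, sum(on)))
})

test_that("empty ganglion image carries truth count 0", {
  sim <- simulate_ganglia_image(n_somata = 0, seed = 1)
  expect_equal(sim$truth$n_somata, 0)
  expect_true(all(sim$image[, , 1] == 0))
})

test_that("noise-free plate readings invert to the planted concentrations", {
  sim <- simulate_plate_run(slope_au_per_ug_ml = 1000, intercept_au = 0,
                            sample_true_concs_ug_ml = 4,
                            replicate_noise_sd = 0, seed = 1)
  smp <- sim$plate[sim$plate$role == "sample", ]
  expect_equal(smp$reading_au, rep(4000, 3))
  expect_equal(sum(sim$plate$role == "sample"), 3)  # triplicate wells
  expect_equal((smp$reading_au - 0) / 1000, rep(4, 3))
})

test_that("group draws with zero SD equal their group means and reproduce", {
  d <- simulate_group_data(c(1, 2), c(0, 0), c(3, 3), seed = 1)
  expect_equal(d$value, c(1, 1, 1, 2, 2, 2))
  d1 <- simulate_group_data(c(0, 0), c(1, 1), c(5, 5), seed = 42)
  d2 <- simulate_group_data(c(0, 0), c(1, 1), c(5, 5), seed = 42)
  expect_identical(d1, d2)
  expect_warning(simulate_group_data(1, 1, 1, seed = 1), "SEM")
})

test_that("ANOVA p-values are roughly uniform under the null", {
  ps <- vapply(1:200, function(s) {
    d <- simulate_group_data(c(5, 5, 5), c(1, 1, 1), c(10, 10, 10), seed = s)
    one_way_anova_tukey(d, group = "group")$anova$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
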