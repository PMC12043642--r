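test_that("row normalization divides by the row mean and is exact", {
  m <- simulate_stmap(n_rows = 20, n_cols = 50, seed = 1)
  vals <- unclass(m)
  vals[1, ] <- 2; vals[2, ] <- c(rep(1, 25), rep(3, 25))
  m <- stmap(vals, mm_per_row(m), s_per_frame(m))
  nm <- normalize_rows(m)
  expect_equal(unclass(nm)[1, ], rep(1, 50), ignore_attr = TRUE)
  expect_equal(sort(unique(unclass(nm)[2, ])), c(0.5, 1.5))
  set.seed(4)
  r <- stmap(matrix(runif(10 * 100, 1, 3), 10 * 2, 50), 0.3, 1)
  expect_lt(max(abs(rowMeans(normalize_rows(r)) - 1)), 1e-12)
})

test_that("rows with non-positive mean are refused by name", {
  vals <- matrix(1, 20, 50); vals[3, ] <- 0
  expect_error(normalize_rows(stmap(vals, 0.25, 1)), "3")
})

test_that("the smoothing kernel sums to 1 and leaves constants unchanged", {
  k <- gaussian_kernel(8, 3)
  expect_equal(sum(k), 1)
  m <- stmap(matrix(2, 30, 60), 0.25, 1)
  expect_equal(unclass(smooth_stmap(m)), matrix(2, 30, 60),
               ignore_attr = TRUE)
})

test_that("smoothing equals direct 2-D convolution everywhere", {
  set.seed(8)
  m <- stmap(matrix(runif(32 * 64), 32, 64), 0.25, 1)
  sm <- smooth_stmap(m, smoothing_config(8, 3))
  oracle <- direct_filter2d(unclass(m), gaussian_kernel(8, 3))
  expect_lt(max(abs(unclass(sm) - oracle)), 1e-12)
})

test_that("smoothing twice equals one pass with the self-convolved kernel", {
  set.seed(9)
  m <- stmap(matrix(runif(40 * 80), 40, 80), 0.25, 1)
  twice <- smooth_stmap(smooth_stmap(m), smoothing_config(8, 3))
  k <- gaussian_kernel(8, 3)
  k2 <- matrix(0, 15, 15)           # full self-convolution of the 8x8 kernel
  for (u in 1:8) for (v in 1:8) k2[u:(u + 7), v:(v + 7)] <-
    k2[u:(u + 7), v:(v + 7)] + k[u, v] * k
  # the doubled kernel's effective center is offset 7, so embed it in a
  # 16 x 16 frame whose center index (8) lines up with it
  k16 <- matrix(0, 16, 16); k16[2:16, 2:16] <- k2
  interior <- 16:25
  oracle <- direct_filter2d(unclass(m), k16)
  expect_lt(max(abs(unclass(twice)[interior, 30:50] - oracle[interior, 30:50])),
            1e-10)
})

test_that("kernels larger than the map are refused", {
  m <- stmap(matrix(1, 20, 50), 0.25, 1)
  expect_error(smooth_stmap(m, smoothing_config(25, 3)), "exceeds")
})

test_that("bands tile the rows with a 5% initiation band", {
  m <- stmap(matrix(1, 100, 60), 0.3, 1)
  pr <- band_profiles(m)
  expect_length(pr, 11)
  expect_equal(pr[[1]]$rows, 1:5)            # proximal 5%
  expect_equal(pr[[2]]$rows, 1:10)
  expect_equal(pr[[11]]$rows, 91:100)        # ten contiguous 10% blocks
  expect_true(all(vapply(pr, function(p) all(p$deviation == 0), logical(1))))
})

test_that("peak detection finds two bumps at the right times and no more", {
  set.seed(3)
  t <- 0:899
  noise <- rnorm(900, sd = 0.002)
  trace <- 1 + 0.2 * exp(-(t - 100)^2 / 50) + 0.2 * exp(-(t - 300)^2 / 50) +
    noise
  prof <- list(band_id = 1L, trace = trace, deviation = abs(trace - 1))
  pk <- detect_peaks(prof, detection_config(), s_per_frame = 1)
  expect_equal(nrow(pk), 2)
  expect_lt(max(abs(pk$time_s - c(100, 300))), 1)
  flat <- list(band_id = 1L, trace = rep(1, 100), deviation = rep(0, 100))
  expect_equal(nrow(detect_peaks(flat, detection_config(), 1)), 0)
  # a bump below the prominence threshold is ignored
  weak <- 1 + 0.004 * exp(-(t - 400)^2 / 50) + noise
  prof_w <- list(band_id = 1L, trace = weak, deviation = abs(weak - 1))
  expect_equal(nrow(detect_peaks(prof_w, detection_config(), 1)), 0)
})

test_that("a constant map yields no contractions and an NA-flagged summary", {
  m <- stmap(matrix(1, 120, 900), 0.25, 1, normalized = TRUE)
  cc <- delineate_contractions(m)
  expect_equal(nrow(cc), 0)
  s <- summarize_motility(cc, m)
  expect_equal(s$n_initiated, 0L)
  expect_true(is.na(s$mean_velocity_mm_s))
  expect_true(is.na(s$mean_span_pct))
})

test_that("a planted contraction is recovered with its velocity and span", {
  m <- fixture_stmap(velocity = 1.0, span = 0.9, origin = 0.02)
  fit <- cmc_analysis(m)
  expect_equal(nrow(fit$contractions), 1)
  expect_equal(fit$contractions$velocity_mm_s, 1.0, tolerance = 0.05)
  expect_lt(abs(fit$contractions$span_pct - 90), 10)
  expect_true(fit$contractions$completed)
})

test_that("contractions still propagating at the recording end are discarded", {
  tc <- true_contraction(870, 0.02, 0.9, 1.0, 0.5, truncated = TRUE)
  m <- simulate_stmap(contractions = list(tc), seed = 1)
  fit <- cmc_analysis(m)
  expect_equal(nrow(fit$contractions), 0)
  expect_gte(attr(fit$contractions, "n_truncated"), 1)
})

test_that("summary metrics follow their definitions on a fixed table", {
  cc <- data.frame(onset_time_s = c(60, 180, 320),
                   onset_pos_mm = 0.75, end_pos_mm = c(27, 21, 27),
                   end_time_s = c(80, 200, 340),
                   span_pct = c(90, 70, 90), velocity_mm_s = c(1, 1, 1),
                   duration_s = c(20, 20, 20), n_band_peaks = 9,
                   completed = c(TRUE, FALSE, TRUE))
  m <- stmap(matrix(1, 120, 900), 0.25, 1)
  s <- summarize_motility(cc[1:2, ], m)
  expect_equal(s$pct_completed, 50)          # spans {90, 70} vs the 80% rule
  s3 <- summarize_motility(cc, m)
  expect_equal(s3$mean_interval_s, 130)      # onsets 60, 180, 320
  expect_equal(s3$n_initiated, 3L)
})

test_that("per-row gains leave the analysis unchanged (banding invariance)", {
  m <- fixture_stmap(velocity = 1.0, span = 0.9, onsets = c(100, 350, 600),
                     noise_sd = 0.1, seed = 21)
  set.seed(22)
  g <- runif(nrow(m), 0.7, 1.3)
  m_gained <- stmap(unclass(m) * g, mm_per_row(m), s_per_frame(m))
  a <- cmc_analysis(m)
  b <- cmc_analysis(m_gained)
  expect_equal(nrow(a$contractions), nrow(b$contractions))
  expect_lt(max(abs(a$contractions$onset_time_s - b$contractions$onset_time_s)),
            s_per_frame(m) + 1e-9)
  expect_lt(max(abs(a$contractions$end_time_s - b$contractions$end_time_s)),
            s_per_frame(m) + 1e-9)
})

test_that("raising the completion threshold never raises pct_completed", {
  m <- fixture_stmap(velocity = 1.0, span = 0.9, onsets = c(100, 300, 500))
  cc <- cmc_analysis(m)$contractions
  thresholds <- c(50, 70, 80, 90, 95)
  pc <- vapply(thresholds, function(th)
    summarize_motility(cc, m, detection_config(completion_threshold_pct = th))$pct_completed,
    numeric(1))
  expect_true(all(diff(pc) <= 0))
})

test_that("the analysis is a pure function of map and config", {
  m <- fixture_stmap(velocity = 1.3, span = 0.9, noise_sd = 0.12, seed = 5)
  a <- cmc_analysis(m)
  b <- cmc_analysis(m)
  expect_identical(a$contractions, b$contractions)
  expect_identical(unclass(summary(a)), unclass(summary(b)))
})
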