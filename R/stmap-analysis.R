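#' Detection and smoothing configuration for CMC analysis
#'
#' `smoothing_config()` parameterizes the 2-D Gaussian smoothing applied to
#' the row-normalized map; the defaults (an 8 x 8 kernel with sigma = 3
#' pixels, replicate-padded borders) follow the standard square-kernel
#' constructor convention of numerical image-processing environments.
#'
#' @param kernel_size_h side length h of the square kernel, in pixels (>= 1).
#' @param kernel_sigma Gaussian sigma in pixels (> 0).
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(kernel_size_h = 8, kernel_sigma = 3) {
  stopifnot(kernel_size_h >= 1, kernel_sigma > 0)
  structure(list(kernel_size_h = as.integer(kernel_size_h),
                 kernel_sigma = kernel_sigma,
                 boundary = "replicate"),
            class = "smoothing_config")
}

#' @rdname smoothing_config
#'
#' @details `detection_config()` parameterizes contraction detection and
#' tracking. The initiation band is the proximal 5% of rows; tracking bands
#' tile the map in ten 10% blocks. A peak in a band's deviation trace is a
#' local maximum whose topographic prominence exceeds `prominence_k` times
#' the robust SD (1.4826 x median absolute deviation) of the band trace.
#' Peaks are associated band-to-band, proximal to distal, by nearest time
#' within a window `delta_max = band length (mm) / v_min_mm_s`. A contraction
#' whose end time lies within `end_margin_s` of the end of the recording may
#' not have finished propagating and is discarded; `end_margin_s = NULL`
#' defaults to `delta_max`. A contraction "completes" when its span exceeds
#' `completion_threshold_pct` percent of colon length.
#'
#' @param initiation_band_frac fraction of proximal rows forming the
#'   initiation band (default 0.05).
#' @param band_frac row fraction per tracking band (default 0.10).
#' @param prominence_k peak prominence threshold in robust-SD multiples.
#' @param min_peak_separation_s minimum time between peaks in one band (s).
#' @param v_min_mm_s slowest trackable propagation velocity (mm/s).
#' @param min_rel_peak_height coverage gate: trailing associated band peaks
#'   whose deviation height falls below this fraction of the median
#'   associated-peak height are dropped before the endpoint metrics. A band
#'   only grazed by the end of a contraction (or reached only by smoothing
#'   smear) shows a strongly attenuated peak whose band-center position
#'   would otherwise bias span and velocity.
#' @param end_margin_s truncation margin (s); `NULL` = `delta_max`.
#' @param completion_threshold_pct span percentage above which a contraction
#'   counts as having completed propagation (default 80).
#' @param deviation_reference baseline the band deviation is measured from:
#'   `"median"` (default; the trace median, robust to the small positive
#'   offset row normalization leaves on quiescent segments whenever
#'   contractions occupy part of the recording) or `"baseline"` (the
#'   constant 1 of a row-normalized map).
#' @export
detection_config <- function(initiation_band_frac = 0.05, band_frac = 0.10,
                             prominence_k = 6.0, min_peak_separation_s = 5,
                             v_min_mm_s = 0.1, min_rel_peak_height = 0.5,
                             end_margin_s = NULL,
                             completion_threshold_pct = 80,
                             deviation_reference = c("median", "baseline")) {
  deviation_reference <- match.arg(deviation_reference)
  stopifnot(initiation_band_frac > 0, initiation_band_frac < 1,
            band_frac > 0, band_frac <= 0.5,
            prominence_k > 0, min_peak_separation_s > 0, v_min_mm_s > 0,
            min_rel_peak_height >= 0, min_rel_peak_height < 1,
            completion_threshold_pct > 0, completion_threshold_pct < 100)
  if (!is.null(end_margin_s)) stopifnot(end_margin_s >= 0)
  structure(list(initiation_band_frac = initiation_band_frac,
                 band_frac = band_frac,
                 prominence_k = prominence_k,
                 min_peak_separation_s = min_peak_separation_s,
                 v_min_mm_s = v_min_mm_s,
                 min_rel_peak_height = min_rel_peak_height,
                 end_margin_s = end_margin_s,
                 completion_threshold_pct = completion_threshold_pct,
                 deviation_reference = deviation_reference),
            class = "detection_config")
}

#' Row-normalize an STMap to remove banding artifacts
#'
#' Divides each row by its mean so that static baseline-diameter differences
#' along the colon (banding) cancel exactly; every output row has mean 1.
#'
#' @param map an [stmap].
#' @return A unitless normalized [stmap] (`normalized = TRUE`).
#' @export
normalize_rows <- function(map) {
  stopifnot(is.stmap(map))
  rm <- rowMeans(map)
  if (any(rm <= 0))
    stop("row(s) with non-positive mean cannot be normalized: ",
         paste(utils::head(which(rm <= 0), 5), collapse = ", "))
  stmap(unclass(map) / rm, mm_per_row(map), s_per_frame(map),
        normalized = TRUE)
}

#' Square Gaussian smoothing kernel
#'
#' Builds the h x h kernel with the given sigma, centered at index
#' `floor((h + 1) / 2)` (so an even h spans offsets `-(h/2 - 1) .. h/2`),
#' normalized to sum to 1.
#'
#' @inheritParams smoothing_config
#' @return An h x h numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(kernel_size_h = 8, kernel_sigma = 3) {
  h <- as.integer(kernel_size_h)
  ctr <- floor((h + 1) / 2)
  off <- seq_len(h) - ctr
  g <- exp(-off^2 / (2 * kernel_sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Separable replicate-padded correlation of a matrix with outer(g, g)/sum^2.
# Offsets follow gaussian_kernel's center convention.
filter_separable <- function(x, g) {
  g <- g / sum(g)
  h <- length(g)
  ctr <- floor((h + 1) / 2)
  pad_lo <- ctr - 1L
  pad_hi <- h - ctr
  pass <- function(m) {          # filter along rows (dim 1)
    n <- nrow(m)
    idx <- c(rep(1L, pad_lo), seq_len(n), rep(n, pad_hi))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(h))
      out <- out + g[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(pass(t(pass(x))))
}

#' Smooth a normalized STMap with a Gaussian kernel
#'
#' 2-D correlation with the [gaussian_kernel] (default 8 x 8, sigma 3),
#' borders replicate-padded. The kernel sums to 1, so constant maps are
#' unchanged.
#'
#' @param map a row-normalized [stmap] (any stmap is accepted).
#' @param cfg a [smoothing_config].
#' @return The smoothed [stmap], same dimensions and calibration.
#' @export
smooth_stmap <- function(map, cfg = smoothing_config()) {
  stopifnot(is.stmap(map), inherits(cfg, "smoothing_config"))
  h <- cfg$kernel_size_h
  if (h > nrow(map) || h > ncol(map))
    stop("kernel size ", h, " exceeds a map dimension (",
         nrow(map), " x ", ncol(map), ")")
  g <- exp(-(seq_len(h) - floor((h + 1) / 2))^2 / (2 * cfg$kernel_sigma^2))
  out <- stmap(filter_separable(unclass(map), g),
               mm_per_row(map), s_per_frame(map),
               normalized = isTRUE(attr(map, "normalized")))
  out
}

#' Band-averaged intensity profiles of a normalized STMap
#'
#' Returns the initiation-band profile (proximal 5% of rows) followed by the
#' tracking-band profiles (ten contiguous 10% row blocks). Each profile
#' carries the band's mean trace over time and its deviation `|trace - 1|`
#' from the row-normalized baseline.
#'
#' @param map a normalized (and usually smoothed) [stmap].
#' @param cfg a [detection_config].
#' @return A list of `band_profile` lists with fields `band_id` (0 =
#'   initiation), `rows`, `center_mm`, `center_frac`, `trace`, `deviation`.
#' @export
band_profiles <- function(map, cfg = detection_config()) {
  stopifnot(is.stmap(map))
  n <- nrow(map)
  n_init <- floor(cfg$initiation_band_frac * n)
  if (n_init < 1L)
    stop("map has too few rows (", n, ") for a non-empty initiation band")
  n_bands <- round(1 / cfg$band_frac)
  bounds <- floor(seq(0, n, length.out = n_bands + 1L))
  centers <- (seq_len(n) - 0.5) * mm_per_row(map)
  mk <- function(id, rows) {
    tr <- colMeans(unclass(map)[rows, , drop = FALSE])
    ref <- if (identical(cfg$deviation_reference, "baseline")) 1
           else stats::median(tr)
    list(band_id = id, rows = rows,
         center_mm = mean(centers[rows]),
         center_frac = mean(centers[rows]) / colon_length_mm(map),
         trace = tr, deviation = abs(tr - ref))
  }
  out <- vector("list", n_bands + 1L)
  out[[1L]] <- mk(0L, seq_len(n_init))
  for (b in seq_len(n_bands))
    out[[b + 1L]] <- mk(b, (bounds[b] + 1L):bounds[b + 1L])
  out
}

# Topographic prominence of local maxima in a series. Returns a data.frame
# of candidate peaks (index, height, prominence), unfiltered.
peak_candidates <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_max)) return(data.frame(index = integer(), height = numeric(),
                                         prominence = numeric()))
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > h)
    min_l <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > h)
    min_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right)
    h - max(min_l, min_r)
  }, numeric(1))
  data.frame(index = is_max, height = y[is_max], prominence = prom)
}

#' Detect contraction peaks in a band profile
#'
#' Local maxima of the band's deviation trace whose topographic prominence
#' is at least `prominence_k` robust SDs (1.4826 x MAD of the trace), kept
#' greedily by height under a minimum pairwise separation of
#' `min_peak_separation_s`. Peak times are refined to sub-frame precision by
#' a parabola through the three samples around each maximum.
#'
#' @param profile one band profile from [band_profiles].
#' @param cfg a [detection_config].
#' @param s_per_frame temporal calibration of the source map (s).
#' @return A data.frame of peaks in time order: `band_id`, `time_s`,
#'   `height`, `prominence`.
#' @export
detect_peaks <- function(profile, cfg = detection_config(), s_per_frame = 1) {
  dev <- profile$deviation
  cand <- peak_candidates(dev)
  robust_sd <- 1.4826 * stats::mad(profile$trace, constant = 1)
  thr <- cfg$prominence_k * robust_sd
  cand <- cand[cand$prominence >= thr & cand$prominence > 0, , drop = FALSE]
  empty <- data.frame(band_id = integer(), time_s = numeric(),
                      height = numeric(), prominence = numeric())
  if (!nrow(cand)) return(empty)
  # enforce minimum separation, strongest first
  cand <- cand[order(-cand$height), , drop = FALSE]
  min_sep <- cfg$min_peak_separation_s / s_per_frame
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) || all(abs(cand$index[i] - cand$index[keep]) >= min_sep))
      keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-frame parabolic refinement
  n <- length(dev)
  t_ref <- vapply(cand$index, function(i) {
    if (i <= 1L || i >= n) return(i - 1)
    d2 <- dev[i - 1L] - 2 * dev[i] + dev[i + 1L]
    delta <- if (d2 < 0) 0.5 * (dev[i - 1L] - dev[i + 1L]) / d2 else 0
    (i - 1) + max(-0.5, min(0.5, delta))
  }, numeric(1))
  out <- data.frame(band_id = profile$band_id,
                    time_s = t_ref * s_per_frame,
                    height = cand$height,
                    prominence = cand$prominence)
  out[order(out$time_s), , drop = FALSE]
}

#' Delineate colonic moving contractions in a normalized STMap
#'
#' Each peak in the initiation band (proximal 5% of rows) seeds one
#' contraction. Its trajectory is then tracked distally: for each successive
#' 10% band, the band peak nearest in time within
#' `[t_prev - 1 frame, t_prev + delta_max]` is associated
#' (`delta_max` = band length / `v_min_mm_s`); tracking stops at the first
#' band without an associable peak. Onset is the initiation peak (time, band
#' center); end is the last associated peak. Span, velocity (endpoint
#' formula) and duration follow from those coordinates. Contractions whose
#' end time lies within `end_margin_s` of the end of the recording may not
#' have finished propagating and are discarded.
#'
#' @param map a row-normalized, smoothed [stmap].
#' @param cfg a [detection_config].
#' @return A data.frame, one row per retained contraction: `id`,
#'   `onset_time_s`, `onset_pos_mm`, `end_time_s`, `end_pos_mm`, `span_pct`,
#'   `velocity_mm_s` (`NA` when fewer than 2 tracking peaks), `duration_s`,
#'   `n_band_peaks`, `completed`. The `"n_truncated"` attribute counts
#'   discarded (possibly unfinished) contractions.
#' @export
delineate_contractions <- function(map, cfg = detection_config()) {
  stopifnot(is.stmap(map))
  profs <- band_profiles(map, cfg)
  spf <- s_per_frame(map)
  peaks <- lapply(profs, detect_peaks, cfg = cfg, s_per_frame = spf)
  init <- peaks[[1L]]
  band_len_mm <- cfg$band_frac * colon_length_mm(map)
  delta_max <- band_len_mm / cfg$v_min_mm_s
  end_margin <- if (is.null(cfg$end_margin_s)) delta_max else cfg$end_margin_s
  centers <- vapply(profs, `[[`, numeric(1), "center_mm")
  used <- lapply(peaks, function(p) rep(FALSE, nrow(p)))

  rows <- list()
  n_truncated <- 0L
  if (nrow(init)) for (i in order(init$time_s)) {
    t0 <- init$time_s[i]
    onset_pos <- centers[1L]
    t_prev <- t0
    assoc_t <- numeric(); assoc_h <- numeric(); assoc_b <- integer()
    for (b in 2:length(profs)) {
      pb <- peaks[[b]]
      if (!nrow(pb)) break
      ok <- !used[[b]] &
        pb$time_s >= t_prev - spf & pb$time_s <= t_prev + delta_max
      if (!any(ok)) break
      j <- which(ok)[which.min(abs(pb$time_s[ok] - t_prev))]
      used[[b]][j] <- TRUE
      t_prev <- pb$time_s[j]
      assoc_t <- c(assoc_t, pb$time_s[j])
      assoc_h <- c(assoc_h, pb$height[j])
      assoc_b <- c(assoc_b, b)
    }
    # coverage gate: a trailing band reached only partially (or by smoothing
    # smear) has a strongly attenuated peak; drop it so band-center
    # coordinates stay faithful to the trajectory actually traversed
    if (length(assoc_h) > 1L) {
      h_ref <- stats::median(assoc_h)
      while (length(assoc_h) > 1L &&
             assoc_h[length(assoc_h)] < cfg$min_rel_peak_height * h_ref) {
        assoc_t <- assoc_t[-length(assoc_t)]
        assoc_h <- assoc_h[-length(assoc_h)]
        assoc_b <- assoc_b[-length(assoc_b)]
      }
    }
    if (!length(assoc_b)) {
      end_t <- t0; end_pos <- onset_pos
    } else {
      end_t <- assoc_t[length(assoc_t)]
      end_pos <- centers[assoc_b[length(assoc_b)]]
    }
    truncated <- end_t + end_margin > recording_s(map)
    if (truncated) { n_truncated <- n_truncated + 1L; next }
    span_pct <- 100 * (end_pos - onset_pos) / colon_length_mm(map)
    # velocity over the propagation phase: the first tracking band overlaps
    # the initiation zone, where the band average mixes rows the contraction
    # has not yet reached; with >= 3 tracked bands, measure from the second
    vel <- NA_real_
    if (length(assoc_t) >= 2L) {
      i0 <- if (length(assoc_t) >= 3L) 2L else 1L
      dt <- assoc_t[length(assoc_t)] - assoc_t[i0]
      if (dt > 0)
        vel <- (centers[assoc_b[length(assoc_b)]] - centers[assoc_b[i0]]) / dt
    }
    rows[[length(rows) + 1L]] <- data.frame(
      onset_time_s = t0, onset_pos_mm = onset_pos,
      end_time_s = end_t, end_pos_mm = end_pos,
      span_pct = span_pct, velocity_mm_s = vel,
      duration_s = end_t - t0,
      n_band_peaks = length(assoc_t),
      completed = span_pct > cfg$completion_threshold_pct)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_time_s = numeric(), onset_pos_mm = numeric(),
               end_time_s = numeric(), end_pos_mm = numeric(),
               span_pct = numeric(), velocity_mm_s = numeric(),
               duration_s = numeric(), n_band_peaks = integer(),
               completed = logical())
  out <- out[order(out$onset_time_s), , drop = FALSE]
  if (nrow(out)) out <- cbind(id = seq_len(nrow(out)), out)
  else out <- cbind(id = integer(), out)
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_truncated
  out
}

#' Summarize motility metrics over the contractions of one recording
#'
#' @param contractions data.frame from [delineate_contractions].
#' @param map the source [stmap] (for recording metadata).
#' @param cfg the [detection_config] used (supplies the completion
#'   threshold, default span > 80% of colon length).
#' @return A list of class `motility_summary`: `n_initiated`,
#'   `mean_span_pct`, `pct_completed`, `mean_velocity_mm_s`,
#'   `mean_duration_s`, `mean_interval_s` (mean inter-contraction onset
#'   interval; `n_initiated - 1` intervals). All means are `NA` when no
#'   contractions were detected.
#' @export
summarize_motility <- function(contractions, map, cfg = detection_config()) {
  n <- nrow(contractions)
  if (n == 0L) {
    out <- list(n_initiated = 0L, mean_span_pct = NA_real_,
                pct_completed = NA_real_, mean_velocity_mm_s = NA_real_,
                mean_duration_s = NA_real_, mean_interval_s = NA_real_)
  } else {
    iv <- diff(sort(contractions$onset_time_s))
    out <- list(
      n_initiated = n,
      mean_span_pct = mean(contractions$span_pct),
      pct_completed = 100 * mean(contractions$span_pct >
                                   cfg$completion_threshold_pct),
      mean_velocity_mm_s = mean(contractions$velocity_mm_s, na.rm = TRUE),
      mean_duration_s = mean(contractions$duration_s),
      mean_interval_s = if (length(iv)) mean(iv) else NA_real_)
  }
  out$recording_s <- recording_s(map)
  out$colon_length_mm <- colon_length_mm(map)
  class(out) <- "motility_summary"
  out
}

#' @export
print.motility_summary <- function(x, ...) {
  cat("Colonic motility summary\n")
  cat(sprintf("  recording %.0f s, colon %.1f mm\n", x$recording_s, x$colon_length_mm))
  cat(sprintf("  contractions initiated : %d\n", x$n_initiated))
  fmt <- function(v, u) if (is.na(v)) "undefined (no contractions)" else sprintf("%.3g %s", v, u)
  cat("  mean span              :", fmt(x$mean_span_pct, "%"), "\n")
  cat("  completed propagation  :", fmt(x$pct_completed, "%"), "\n")
  cat("  mean velocity          :", fmt(x$mean_velocity_mm_s, "mm/s"), "\n")
  cat("  mean duration          :", fmt(x$mean_duration_s, "s"), "\n")
  cat("  mean onset interval    :", fmt(x$mean_interval_s, "s"), "\n")
  invisible(x)
}

#' Analyze an STMap for colonic moving contractions
#'
#' The full pipeline on a raw diameter map: row normalization (removes
#' banding), Gaussian smoothing (8 x 8, sigma 3 by default), banded peak
#' detection and proximal-to-distal tracking, and per-recording summary
#' metrics (counts, span, completion fraction under the >80% rule, velocity,
#' duration, inter-contraction interval).
#'
#' @param map a raw diameter [stmap].
#' @param detection a [detection_config].
#' @param smoothing a [smoothing_config].
#' @return An object of class `cmc_analysis` with elements `map` (input),
#'   `normalized` (smoothed normalized map), `contractions` (data.frame),
#'   `summary` (a `motility_summary`), and the two configs. Methods:
#'   `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' tc <- true_contraction(100, 0.02, 0.9, 1.0, 0.5)
#' fit <- cmc_analysis(simulate_stmap(contractions = list(tc)))
#' summary(fit)
#' @export
cmc_analysis <- function(map, detection = detection_config(),
                         smoothing = smoothing_config()) {
  stopifnot(is.stmap(map))
  norm <- smooth_stmap(normalize_rows(map), smoothing)
  contractions <- delineate_contractions(norm, detection)
  structure(list(map = map, normalized = norm,
                 contractions = contractions,
                 summary = summarize_motility(contractions, map, detection),
                 detection = detection, smoothing = smoothing),
            class = "cmc_analysis")
}

#' @export
print.cmc_analysis <- function(x, ...) {
  cat(sprintf("CMC analysis: %d contraction(s) in a %.0f s recording (%d discarded as possibly unfinished)\n",
              nrow(x$contractions), recording_s(x$map),
              attr(x$contractions, "n_truncated")))
  if (nrow(x$contractions))
    print(x$contractions, digits = 4)
  invisible(x)
}

#' @export
summary.cmc_analysis <- function(object, ...) object$summary

#' @export
as.data.frame.cmc_analysis <- function(x, ...) x$contractions

#' @export
plot.cmc_analysis <- function(x, ...) {
  plot(x$map, ...)
  cc <- x$contractions
  if (nrow(cc)) {
    L <- colon_length_mm(x$map)
    graphics::points(cc$onset_time_s, L - cc$onset_pos_mm, col = "green3", pch = 16)
    graphics::points(cc$end_time_s, L - cc$end_pos_mm, col = "red", pch = 16)
    graphics::segments(cc$onset_time_s, L - cc$onset_pos_mm,
                       cc$end_time_s, L - cc$end_pos_mm, col = "orange")
  }
  invisible(x)
}
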