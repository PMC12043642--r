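#' Describe a planted colonic moving contraction
#'
#' Ground-truth parameters for one propagating contraction rendered into a
#' synthetic STMap. The contraction initiates at `origin_frac` of the colon
#' length at `onset_time_s` and travels distally at constant
#' `velocity_mm_s`, reducing the local diameter by `amplitude_frac` with a
#' Gaussian temporal profile of width `width_sigma_s` at each position.
#'
#' @param onset_time_s time (s) at which the contraction passes its origin.
#' @param origin_frac initiation site as a fraction of colon length, in
#'   `[0, 1)`; the biological pattern initiates in the proximal few percent.
#' @param span_frac fraction of colon length traversed, in `(0, 1]`;
#'   `origin_frac + span_frac` must not exceed 1.
#' @param velocity_mm_s propagation speed (mm/s), > 0.
#' @param amplitude_frac fractional diameter reduction at the contraction
#'   center, in `(0, 1)`.
#' @param width_sigma_s temporal Gaussian width (s) at a fixed position.
#' @param truncated set `TRUE` to permit a trajectory that runs past the end
#'   of the recording; [simulate_stmap] rejects unflagged truncation.
#' @return A list of class `true_contraction`.
#' @export
true_contraction <- function(onset_time_s, origin_frac, span_frac,
                             velocity_mm_s, amplitude_frac,
                             width_sigma_s = 4, truncated = FALSE) {
  stopifnot(onset_time_s >= 0, origin_frac >= 0, origin_frac < 1,
            span_frac > 0, span_frac <= 1, velocity_mm_s > 0,
            amplitude_frac > 0, amplitude_frac < 1, width_sigma_s > 0)
  if (origin_frac + span_frac > 1 + 1e-12)
    stop("origin_frac + span_frac must be <= 1")
  structure(list(onset_time_s = onset_time_s, origin_frac = origin_frac,
                 span_frac = span_frac, velocity_mm_s = velocity_mm_s,
                 amplitude_frac = amplitude_frac,
                 width_sigma_s = width_sigma_s,
                 truncated = isTRUE(truncated)),
            class = "true_contraction")
}

#' Simulate a spatiotemporal diameter map with planted contractions
#'
#' Renders an STMap of a quiescent colon of constant baseline diameter on
#' which each planted contraction appears as a diameter-reduction stripe
#' propagating at constant velocity, plus two nuisance processes the analysis
#' pipeline must remove: static per-row multiplicative banding (baseline
#' diameter differences along the colon) and i.i.d. Gaussian pixel noise.
#'
#' The diameter at row r (position p_r mm) and frame t (time t_s) is
#' `gain[r] * baseline * (1 - sum_k a_k exp(-(t_s - tau_k(r))^2 / (2 w_k^2)))
#' + noise`, where `tau_k(r) = onset_k + (p_r - origin_k)/v_k` for rows with
#' p_r inside the contraction's span, and no contribution outside it.
#'
#' @param n_rows,n_cols map dimensions (>= 20 rows, >= 50 columns).
#' @param mm_per_row,s_per_frame calibration (see [stmap]).
#' @param baseline_diameter_mm resting diameter (mm).
#' @param banding_gain per-row multiplicative gain vector (recycled scalar
#'   allowed), each in `[0.5, 1.5]`; `1` disables banding.
#' @param noise_sd additive Gaussian noise SD in diameter units (mm).
#' @param contractions list of [true_contraction] objects.
#' @param max_origin_frac upper bound on allowed `origin_frac` (default 0.05:
#'   contractions initiate within the proximal 5%).
#' @param seed integer seed; identical seeds give identical maps.
#' @return The [stmap]; its `"truth"` attribute carries the contraction list
#'   with per-contraction `truncated` flags resolved against the recording.
#' @examples
#' tc <- true_contraction(100, 0.02, 0.9, 1.0, 0.5)
#' m <- simulate_stmap(contractions = list(tc), seed = 1)
#' @export
simulate_stmap <- function(n_rows = 120, n_cols = 900,
                           mm_per_row = 0.25, s_per_frame = 1,
                           baseline_diameter_mm = 2.5,
                           banding_gain = 1, noise_sd = 0,
                           contractions = list(),
                           max_origin_frac = 0.05,
                           seed = 1) {
  stopifnot(n_rows >= 20, n_cols >= 50, noise_sd >= 0)
  gain <- rep_len(banding_gain, n_rows)
  if (any(gain < 0.5 | gain > 1.5))
    stop("banding_gain values must lie in [0.5, 1.5]")
  colon_len <- n_rows * mm_per_row
  rec_s <- n_cols * s_per_frame
  pos <- (seq_len(n_rows) - 0.5) * mm_per_row
  tvec <- (seq_len(n_cols) - 1) * s_per_frame

  reduction <- matrix(0, n_rows, n_cols)
  truth <- list()
  for (k in seq_along(contractions)) {
    tc <- contractions[[k]]
    if (!inherits(tc, "true_contraction"))
      stop("contractions must be a list of true_contraction objects")
    if (tc$origin_frac >= max_origin_frac)
      stop(sprintf("contraction %d originates at %.3f of colon length; allowed < %.3f",
                   k, tc$origin_frac, max_origin_frac))
    origin_mm <- tc$origin_frac * colon_len
    end_mm <- (tc$origin_frac + tc$span_frac) * colon_len
    t_end <- tc$onset_time_s + (end_mm - origin_mm) / tc$velocity_mm_s
    runs_over <- t_end + 2 * tc$width_sigma_s > rec_s
    if (runs_over && !tc$truncated)
      stop(sprintf(paste0("contraction %d reaches %.1f s but the recording ends at %.1f s; ",
                          "set truncated = TRUE to plant it deliberately"), k, t_end, rec_s))
    inside <- pos >= origin_mm & pos <= end_mm
    if (any(inside)) {
      tau <- tc$onset_time_s + (pos[inside] - origin_mm) / tc$velocity_mm_s
      dt <- outer(tau, tvec, function(a, b) b - a)
      reduction[inside, ] <- reduction[inside, ] +
        tc$amplitude_frac * exp(-dt^2 / (2 * tc$width_sigma_s^2))
    }
    tc$truncated <- runs_over
    tc$end_time_s <- t_end
    truth[[k]] <- tc
  }

  vals <- gain * baseline_diameter_mm * (1 - reduction)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd),
                          n_rows, n_cols)
    vals[vals < 0] <- 0
  }
  m <- stmap(vals, mm_per_row, s_per_frame)
  attr(m, "truth") <- truth
  m
}
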