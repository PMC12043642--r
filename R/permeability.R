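#' Fit a linear fluorescence standard curve
#'
#' Ordinary least squares of `reading_au ~ concentration` over the standard
#' wells (a 0-concentration blank participates like any other standard; the
#' intercept is not forced through zero).
#'
#' @param conc standard concentrations (ug/mL), at least 3 distinct values.
#' @param reading_au fluorescence readings (AU), same length.
#' @return An object of class `standard_curve`: `slope_au_per_ug_ml`,
#'   `intercept_au`, `r_squared`, `n_points`, and the underlying [stats::lm]
#'   fit.
#' @export
fit_standard_curve <- function(conc, reading_au) {
  stopifnot(length(conc) == length(reading_au))
  if (length(unique(conc)) < 3L)
    stop("a standard curve needs at least 3 distinct concentrations")
  fit <- stats::lm(reading_au ~ conc)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted standard-curve slope is not positive; check the plate layout")
  ss_tot <- sum((reading_au - mean(reading_au))^2)
  structure(list(slope_au_per_ug_ml = slope,
                 intercept_au = unname(stats::coef(fit)[1]),
                 r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot,
                 n_points = length(conc),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: reading = %.4g x conc + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope_au_per_ug_ml, x$intercept_au, x$r_squared, x$n_points))
  invisible(x)
}

#' Quantify a sample against a standard curve
#'
#' Averages the triplicate readings, inverts the curve
#' (`conc = (mean - intercept) / slope`), and, when dilution correction is
#' on, multiplies by the dilution factor. Plasma diluted 1:7 (1 volume
#' plasma + 7 volumes PBS) gives the default factor of 8. Concentrations
#' inverting below zero (reading under the blank) are clipped to 0 and
#' flagged.
#'
#' @param curve a [fit_standard_curve] result.
#' @param replicates numeric vector of 3 well readings (AU).
#' @param dilution_factor multiplier back to undiluted plasma (default 8).
#' @param correct apply the dilution correction (default TRUE).
#' @param sample_id optional identifier carried into the result.
#' @return A one-row data.frame: `sample_id`, `mean_reading_au`,
#'   `conc_diluted_ug_ml`, `dilution_factor`, `conc_reported_ug_ml`,
#'   `below_blank`.
#' @export
quantify_sample <- function(curve, replicates, dilution_factor = 8,
                            correct = TRUE, sample_id = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"))
  if (length(replicates) != 3L)
    stop("expected 3 replicate readings, got ", length(replicates))
  if (curve$slope_au_per_ug_ml <= 0) stop("standard-curve slope must be positive")
  m <- mean(replicates)
  conc <- (m - curve$intercept_au) / curve$slope_au_per_ug_ml
  below <- conc < 0
  if (below) conc <- 0
  data.frame(sample_id = sample_id,
             mean_reading_au = m,
             conc_diluted_ug_ml = conc,
             dilution_factor = dilution_factor,
             conc_reported_ug_ml = if (correct) conc * dilution_factor else conc,
             below_blank = below)
}

#' Quantify a whole plate table
#'
#' Fits the standard curve from `role == "standard"` (and `"blank"`) wells
#' and quantifies each sample's replicate triplet.
#'
#' @param plate data.frame with columns `well_id`, `role`
#'   (standard/blank/sample), `concentration` (standards), `reading_au`,
#'   `sample_id`, `replicate`.
#' @inheritParams quantify_sample
#' @return A list of class `plate_result`: `curve`, `samples` (data.frame of
#'   [quantify_sample] rows).
#' @export
quantify_plate <- function(plate, dilution_factor = 8, correct = TRUE) {
  need <- c("role", "concentration", "reading_au", "sample_id")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate table lacks columns: ", paste(miss, collapse = ", "))
  std <- plate[plate$role %in% c("standard", "blank"), ]
  curve <- fit_standard_curve(std$concentration, std$reading_au)
  smp <- plate[plate$role == "sample", ]
  ids <- unique(smp$sample_id)
  samples <- do.call(rbind, lapply(ids, function(id)
    quantify_sample(curve, smp$reading_au[smp$sample_id == id],
                    dilution_factor, correct, sample_id = id)))
  structure(list(curve = curve, samples = samples), class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  print(x$curve)
  print(x$samples, digits = 4)
  invisible(x)
}

#' Simulate a plate-reader run with a known standard curve
#'
#' Standard wells read `slope * conc + intercept + noise`; each sample is
#' emitted as 3 replicate wells around `slope * true_conc + intercept`
#' (true concentrations are on the diluted scale).
#'
#' @param standard_concs_ug_ml ascending standards, >= 3 distinct values
#'   including a 0 blank.
#' @param slope_au_per_ug_ml,intercept_au planted curve parameters.
#' @param sample_true_concs_ug_ml planted diluted-sample concentrations.
#' @param replicate_noise_sd well noise SD (AU).
#' @param seed integer seed.
#' @return A list of class `plate_sim`: `plate` (well table, CSV dialect:
#'   well_id, role, concentration, reading_au, sample_id, replicate) and
#'   `truth` (planted parameters and concentrations).
#' @export
simulate_plate_run <- function(standard_concs_ug_ml = c(0, 0.5, 1, 2, 4, 8),
                               slope_au_per_ug_ml = 1000, intercept_au = 50,
                               sample_true_concs_ug_ml = c(0.5, 0.6, 0.9),
                               replicate_noise_sd = 0, seed = 1) {
  if (any(standard_concs_ug_ml < 0) || any(sample_true_concs_ug_ml < 0))
    stop("concentrations must be non-negative")
  if (length(unique(standard_concs_ug_ml)) < 3L)
    stop("need >= 3 distinct standard concentrations")
  set.seed(as.integer(seed))
  noise <- function(n) if (replicate_noise_sd > 0)
    stats::rnorm(n, sd = replicate_noise_sd) else rep(0, n)
  std <- data.frame(
    well_id = sprintf("S%02d", seq_along(standard_concs_ug_ml)),
    role = ifelse(standard_concs_ug_ml == 0, "blank", "standard"),
    concentration = standard_concs_ug_ml,
    reading_au = slope_au_per_ug_ml * standard_concs_ug_ml + intercept_au +
      noise(length(standard_concs_ug_ml)),
    sample_id = NA_character_, replicate = NA_integer_)
  smp <- do.call(rbind, lapply(seq_along(sample_true_concs_ug_ml), function(i) {
    data.frame(well_id = sprintf("A%02d_%d", i, 1:3),
               role = "sample", concentration = NA_real_,
               reading_au = slope_au_per_ug_ml * sample_true_concs_ug_ml[i] +
                 intercept_au + noise(3),
               sample_id = sprintf("sample_%02d", i), replicate = 1:3)
  }))
  structure(list(plate = rbind(std, smp),
                 truth = list(slope_au_per_ug_ml = slope_au_per_ug_ml,
                              intercept_au = intercept_au,
                              sample_true_concs_ug_ml = sample_true_concs_ug_ml)),
            class = "plate_sim")
}

#' Simulate group-structured scalar measurements
#'
#' Normal draws per group, e.g. per-animal transit times or densities for
#' the group-comparison statistics.
#'
#' @param group_means,group_sds,n_per_group equal-length vectors.
#' @param group_names optional labels (default `group_1`, ...).
#' @param seed integer seed.
#' @return data.frame with `animal_id`, `group`, `value`.
#' @export
simulate_group_data <- function(group_means, group_sds, n_per_group,
                                group_names = NULL, seed = 1) {
  k <- length(group_means)
  stopifnot(length(group_sds) == k, length(n_per_group) == k,
            all(group_sds >= 0))
  if (any(n_per_group < 1)) stop("each group needs at least one draw")
  if (any(n_per_group < 2 & group_sds > 0))
    warning("groups of size 1 with positive SD have undefined SEM")
  if (is.null(group_names)) group_names <- sprintf("group_%d", seq_len(k))
  set.seed(as.integer(seed))
  do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(animal_id = sprintf("%s_a%02d", group_names[i],
                                   seq_len(n_per_group[i])),
               group = group_names[i],
               value = stats::rnorm(n_per_group[i], group_means[i],
                                    group_sds[i]))
  }))
}
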