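#' Soma-counting configuration
#'
#' Parameters of the deterministic neuron detector: light Gaussian
#' smoothing, thresholding inside the ROI, a distance-transform watershed to
#' split touching somata, and a minimum-area filter on the resulting
#' regions. This detector replaces interactive/trained pixel classification
#' with a reproducible, parameter-light procedure suited to disk-like
#' somata.
#'
#' @param soma_threshold_method `"otsu"` or a fixed numeric threshold.
#' @param min_soma_area_px minimum region area counted as a soma.
#' @param smoothing_px Gaussian sigma (px) of the pre-threshold blur.
#' @param watershed_tolerance intensity tolerance of the watershed split.
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(soma_threshold_method = "otsu",
                            min_soma_area_px = 50, smoothing_px = 2,
                            watershed_tolerance = 1) {
  stopifnot(min_soma_area_px > 0, smoothing_px >= 0)
  structure(list(soma_threshold_method = soma_threshold_method,
                 min_soma_area_px = min_soma_area_px,
                 smoothing_px = smoothing_px,
                 watershed_tolerance = watershed_tolerance),
            class = "counting_config")
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' Even-odd (crossing-number) point-in-polygon test on pixel centers.
#' Vertices are `(x = column, y = row)` in 0-based pixel coordinates; the
#' pixel at matrix position `[r, c]` has center `(c - 0.5, r - 0.5)`.
#'
#' @param polygon numeric matrix of vertices, columns x and y.
#' @param dim_hw image dimensions `c(H, W)`.
#' @return Logical H x W mask of pixels inside the polygon.
#' @export
roi_mask <- function(polygon, dim_hw) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  H <- dim_hw[1]; W <- dim_hw[2]
  if (min(polygon[, 1]) < -0.5 || max(polygon[, 1]) > W + 0.5 ||
      min(polygon[, 2]) < -0.5 || max(polygon[, 2]) > H + 0.5)
    stop("ROI polygon extends outside the image bounds")
  px <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  py <- matrix(seq_len(H) - 0.5, H, W)
  inside <- matrix(FALSE, H, W)
  n <- nrow(polygon)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Segment the ganglionic area inside an ROI
#'
#' Thresholds the PGP 9.5 channel (pan-neuronal: somata plus projections)
#' within the ROI polygon to obtain the ganglion mask whose pixels carry the
#' intensity statistics.
#'
#' @param pgp_channel numeric matrix.
#' @param roi polygon vertex matrix (see [roi_mask]).
#' @param cfg a [counting_config] (supplies the threshold method).
#' @return Logical mask with attributes `area_px` and `empty` (flag set when
#'   nothing inside the ROI crossed threshold).
#' @export
ganglion_mask <- function(pgp_channel, roi, cfg = counting_config()) {
  rmask <- roi_mask(roi, dim(pgp_channel))
  vals <- pgp_channel[rmask]
  if (!length(vals)) stop("ROI covers no pixels")
  thr <- if (identical(cfg$soma_threshold_method, "otsu")) otsu_threshold(vals)
         else as.numeric(cfg$soma_threshold_method)
  mask <- pgp_channel > thr & rmask
  structure(mask, area_px = sum(mask), empty = !any(mask))
}

#' SHANK3 expression normalized to PGP 9.5
#'
#' Mean SHANK3 intensity over the ganglion mask divided by mean PGP 9.5
#' intensity over the same mask. Scaling both channels by a common factor
#' leaves the ratio unchanged; scaling only SHANK3 scales it exactly.
#'
#' @param shank3_channel,pgp_channel numeric matrices.
#' @param mask logical ganglion mask (from [ganglion_mask]).
#' @return The intensity ratio (unitless).
#' @export
expression_ratio <- function(shank3_channel, pgp_channel, mask) {
  if (!any(mask)) stop("empty ganglion mask")
  pgp_mean <- mean(pgp_channel[mask])
  if (pgp_mean <= 0) stop("PGP 9.5 mean intensity is not positive; ratio undefined")
  mean(shank3_channel[mask]) / pgp_mean
}

#' Count neurons (HuC/D somata) inside an ROI
#'
#' Smooth, threshold inside the ROI, split touching somata with a
#' distance-transform watershed, drop regions smaller than
#' `min_soma_area_px`, and count the remainder.
#'
#' @param hucd_channel numeric matrix.
#' @param roi polygon vertex matrix.
#' @param cfg a [counting_config].
#' @return Integer count (0 is valid).
#' @export
count_neurons <- function(hucd_channel, roi, cfg = counting_config()) {
  rmask <- roi_mask(roi, dim(hucd_channel))
  x <- hucd_channel
  x[!rmask] <- 0       # nothing outside the polygon may leak in via the blur
  if (cfg$smoothing_px > 0) {
    s <- cfg$smoothing_px
    half <- max(1L, ceiling(2 * s))
    g <- exp(-(-half:half)^2 / (2 * s^2))
    x <- filter_separable(x, g)
  }
  vals <- x[rmask]
  if (!length(vals)) stop("ROI covers no pixels")
  thr <- if (identical(cfg$soma_threshold_method, "otsu")) otsu_threshold(vals)
         else as.numeric(cfg$soma_threshold_method)
  mask <- x > thr & rmask
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  ws <- EBImage::watershed(dm, tolerance = cfg$watershed_tolerance)
  lab <- matrix(as.integer(round(ws)), nrow(mask), ncol(mask))
  if (max(lab) == 0L) return(0L)
  areas <- tabulate(lab[lab > 0], max(lab))
  sum(areas >= cfg$min_soma_area_px)
}

#' Quantify every ganglion ROI of a 3-channel image
#'
#' @param image H x W x 3 array with channels in the order declared by
#'   `channel_order` (default hucd, pgp, shank3).
#' @param rois list of polygon vertex matrices, or a single matrix.
#' @param cfg a [counting_config].
#' @param channel_order names of the three channels in storage order.
#' @return A data.frame, one row per ROI: `roi_id`, `ganglion_area_px`,
#'   `shank3_mean_au`, `pgp_mean_au`, `expression_ratio`, `neuron_count`,
#'   `flagged` (empty ganglion mask).
#' @export
quantify_ganglia <- function(image, rois, cfg = counting_config(),
                             channel_order = c("hucd", "pgp", "shank3")) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  ch <- function(nm) image[, , match(nm, channel_order)]
  if (is.matrix(rois)) rois <- list(rois)
  out <- lapply(seq_along(rois), function(i) {
    gm <- ganglion_mask(ch("pgp"), rois[[i]], cfg)
    flagged <- isTRUE(attr(gm, "empty"))
    ratio <- if (flagged) NA_real_ else
      expression_ratio(ch("shank3"), ch("pgp"), gm)
    data.frame(roi_id = i,
               ganglion_area_px = attr(gm, "area_px"),
               shank3_mean_au = if (flagged) NA_real_ else mean(ch("shank3")[gm]),
               pgp_mean_au = if (flagged) NA_real_ else mean(ch("pgp")[gm]),
               expression_ratio = ratio,
               neuron_count = count_neurons(ch("hucd"), rois[[i]], cfg),
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Per-animal mean of a ganglion-level statistic
#'
#' Expression is measured in multiple ganglia per animal; the animal's value
#' is the arithmetic mean over its unflagged ganglion records.
#'
#' @param records data.frame with one row per ganglion.
#' @param animal_id vector assigning each record to an animal.
#' @param value name of the column to average (default `"expression_ratio"`).
#' @return data.frame with `animal_id`, `n_ganglia`, `mean_value`.
#' @export
per_animal_mean <- function(records, animal_id, value = "expression_ratio") {
  stopifnot(nrow(records) == length(animal_id))
  ok <- if ("flagged" %in% names(records)) !records$flagged else
    rep(TRUE, nrow(records))
  ok <- ok & is.finite(records[[value]])
  if (!any(ok)) stop("no unflagged records to aggregate")
  records <- records[ok, , drop = FALSE]
  animal_id <- animal_id[ok]
  sp <- split(records[[value]], animal_id)
  data.frame(animal_id = names(sp),
             n_ganglia = lengths(sp),
             mean_value = vapply(sp, mean, numeric(1)),
             row.names = NULL)
}
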