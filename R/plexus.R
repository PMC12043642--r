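#' Configuration of the plexus segmentation pipeline
#'
#' Parameters of the REAVER-style curvilinear-network segmentation: a large
#' averaging filter estimates background illumination (subtracted), a light
#' blur suppresses pixel noise before thresholding, the binary border is
#' cleaned by an averaging filter re-binarized at 0.5, morphological closing
#' and hole filling consolidate the mask, and connected components smaller
#' than `min_area_px` or thinner than `min_diameter_px` are removed.
#'
#' @param bg_window_px odd width of the background-estimation averaging
#'   filter (default 101 px).
#' @param light_blur_px odd width of the pre-threshold blur (default 3 px).
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param border_clean_px odd width of the mask-cleaning averaging filter
#'   (default 3; 1 disables it).
#' @param close_radius_px radius of the closing brush (default 2; 0 disables
#'   closing and hole filling).
#' @param max_hole_area_px holes (enclosed background regions) up to this
#'   area are filled (default 64 px); large enclosed regions between
#'   crossing strands are genuine background and stay open.
#' @param min_area_px minimum retained component area (default 1200 px).
#' @param min_diameter_px minimum retained mean component thickness
#'   (default 8 px).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(bg_window_px = 101, light_blur_px = 3,
                                threshold_method = "otsu",
                                border_clean_px = 3, close_radius_px = 2,
                                max_hole_area_px = 64,
                                min_area_px = 1200, min_diameter_px = 8) {
  stopifnot(bg_window_px %% 2 == 1, bg_window_px > light_blur_px,
            light_blur_px %% 2 == 1, border_clean_px %% 2 == 1,
            close_radius_px >= 0, max_hole_area_px >= 0,
            min_area_px > 0, min_diameter_px >= 0)
  if (!identical(threshold_method, "otsu") && !is.numeric(threshold_method))
    stop("threshold_method must be \"otsu\" or a fixed numeric value")
  structure(list(bg_window_px = as.integer(bg_window_px),
                 light_blur_px = as.integer(light_blur_px),
                 threshold_method = threshold_method,
                 border_clean_px = as.integer(border_clean_px),
                 close_radius_px = as.integer(close_radius_px),
                 max_hole_area_px = max_hole_area_px,
                 min_area_px = min_area_px,
                 min_diameter_px = min_diameter_px),
            class = "segmentation_config")
}

# Box (averaging) filter with replicate padding, separable.
box_filter <- function(x, width) {
  if (width <= 1L) return(x)
  filter_separable(x, rep(1, width))
}

#' Otsu threshold of a numeric matrix
#'
#' Maximizes between-class variance over a 256-bin histogram of the values;
#' works on any finite value range.
#'
#' @param x numeric matrix or vector.
#' @param n_bins histogram bins (default 256).
#' @return The threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Fill enclosed background regions (holes) of at most max_area pixels.
fill_small_holes <- function(mask, max_area) {
  if (max_area <= 0) return(mask)
  bg <- EBImage::bwlabel(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  bg <- matrix(as.integer(round(bg)), nrow(mask), ncol(mask))
  if (max(bg) == 0L) return(mask)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  areas <- tabulate(bg[bg > 0], max(bg))
  fill <- setdiff(which(areas <= max_area), border_labs)
  if (length(fill)) mask[bg %in% fill] <- TRUE
  mask
}

# 8-connected labelling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Zhang-Suen thinning to a 1-px skeleton; vectorized over the whole mask.
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m)
  pad <- function(x) {
    out <- matrix(0L, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      p2 <- p[ri - 1L, ci]; p3 <- p[ri - 1L, ci + 1L]; p4 <- p[ri, ci + 1L]
      p5 <- p[ri + 1L, ci + 1L]; p6 <- p[ri + 1L, ci]; p7 <- p[ri + 1L, ci - 1L]
      p8 <- p[ri, ci - 1L]; p9 <- p[ri - 1L, ci - 1L]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
           (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1L) {
        cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Per-component area and mean thickness (2 x mean distance-transform value
# sampled along the component's skeleton, the vessel-diameter convention).
component_stats <- function(lab) {
  nl <- max(lab)
  if (nl == 0L)
    return(data.frame(label = integer(), area_px = numeric(),
                      mean_thickness_px = numeric()))
  areas <- tabulate(lab[lab > 0], nl)
  dm <- EBImage::distmap(matrix(as.numeric(lab > 0), nrow(lab), ncol(lab)))
  dm <- matrix(as.numeric(dm), nrow(lab), ncol(lab))
  skel <- skeletonize(lab > 0)
  thick <- vapply(seq_len(nl), function(l) {
    on_skel <- skel == 1L & lab == l
    if (!any(on_skel)) return(2 * max(dm[lab == l]))
    2 * mean(dm[on_skel])
  }, numeric(1))
  data.frame(label = seq_len(nl), area_px = areas, mean_thickness_px = thick)
}

#' Filter mask components by area and thickness
#'
#' Removes every 8-connected component whose pixel area is below
#' `min_area_px` or whose mean thickness (twice the mean Euclidean
#' distance-transform value sampled along the component skeleton) is below
#' `min_diameter_px`. Defaults follow the plexus rule: regions under 1200 px
#' in area or under 8 px in diameter are removed.
#'
#' @param mask logical/0-1 matrix.
#' @param min_area_px,min_diameter_px retention thresholds.
#' @return The filtered logical mask, with a `"components"` attribute
#'   listing retained components (label, area_px, mean_thickness_px).
#' @export
component_filter <- function(mask, min_area_px = 1200, min_diameter_px = 8) {
  mask <- mask > 0
  lab <- label8(mask)
  st <- component_stats(lab)
  keep <- st$area_px >= min_area_px & st$mean_thickness_px >= min_diameter_px
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (any(keep))
    out[lab %in% st$label[keep]] <- TRUE
  st_keep <- st[keep, , drop = FALSE]
  rownames(st_keep) <- NULL
  attr(out, "components") <- st_keep
  out
}

#' Fraction of image area covered by a plexus mask
#'
#' @param mask logical/0-1 matrix.
#' @return Foreground pixel count divided by total pixel count, in `[0, 1]`.
#' @export
plexus_density <- function(mask) {
  if (length(mask) == 0L) stop("empty mask")
  mean(mask > 0)
}

#' Segment the myenteric plexus in a fluorescence micrograph
#'
#' Pipeline: estimate background illumination with a large averaging filter
#' and subtract it; lightly blur; threshold (Otsu by default); clean the
#' binary border with a small averaging filter re-binarized at 0.5;
#' morphological closing and hole filling; remove components below the area
#' or thickness thresholds. Multi-channel input is reduced to grayscale by
#' the channel mean.
#'
#' @param image numeric matrix (grayscale) or 3-D array (H x W x channels).
#' @param cfg a [segmentation_config].
#' @return A list of class `plexus_mask`: `mask` (logical matrix),
#'   `components` (data.frame of retained components), `density` (fraction
#'   of image pixels in the mask), `threshold`.
#' @export
segment_plexus <- function(image, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (!is.matrix(image)) stop("image must be a matrix or H x W x C array")
  if (min(dim(image)) < cfg$bg_window_px)
    stop("image (", nrow(image), " x ", ncol(image),
         ") is smaller than bg_window_px = ", cfg$bg_window_px)
  bg <- box_filter(image, cfg$bg_window_px)
  sub <- image - bg
  sm <- box_filter(sub, cfg$light_blur_px)
  thr <- if (identical(cfg$threshold_method, "otsu")) otsu_threshold(sm)
         else as.numeric(cfg$threshold_method)
  mask <- sm > thr
  if (cfg$border_clean_px > 1L)
    mask <- box_filter(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       cfg$border_clean_px) >= 0.5
  if (cfg$close_radius_px > 0L && any(mask)) {
    brush <- EBImage::makeBrush(2L * cfg$close_radius_px + 1L, shape = "disc")
    m2 <- EBImage::closing(matrix(as.numeric(mask), nrow(mask), ncol(mask)), brush)
    mask <- matrix(as.numeric(m2), nrow(mask), ncol(mask)) > 0
    mask <- fill_small_holes(mask, cfg$max_hole_area_px)
  }
  mask <- component_filter(mask, cfg$min_area_px, cfg$min_diameter_px)
  structure(list(mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
                 components = attr(mask, "components"),
                 density = plexus_density(mask),
                 threshold = thr),
            class = "plexus_mask")
}

#' @export
print.plexus_mask <- function(x, ...) {
  cat(sprintf("Plexus segmentation: density %.2f%% (%d component(s), threshold %.4g)\n",
              100 * x$density, nrow(x$components), x$threshold))
  invisible(x)
}
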