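#' Simulate a myenteric-plexus-like fluorescence micrograph
#'
#' Renders bright curvilinear strands (random-walk polylines dilated to a
#' fixed width) over a smooth illumination gradient plus Gaussian noise,
#' with optional bright distractor blobs of exact pixel area and thickness.
#' The returned truth mask contains exactly the strand pixels (never the
#' distractors or background), so the true plexus density is an exact pixel
#' count.
#'
#' @param image_size_px `c(H, W)` image size (default 600 x 600).
#' @param n_strands number of strands.
#' @param strand_width_px strand thickness in pixels (>= 1).
#' @param strand_intensity strand brightness above background (AU).
#' @param background_gradient_amp peak-to-center amplitude of a smooth
#'   linear illumination gradient (AU); 0 disables it.
#' @param noise_sd additive Gaussian noise SD (AU).
#' @param distractor_blobs list of `c(area_px, thickness_px)` rectangles of
#'   exact area rendered away from the strands.
#' @param seed integer seed.
#' @return A list of class `plexus_sim`: `image` (matrix), `truth_mask`
#'   (logical), `truth_density`, `distractors` (data.frame of planted blob
#'   areas/thicknesses).
#' @export
simulate_plexus_image <- function(image_size_px = c(600, 600),
                                  n_strands = 12, strand_width_px = 12,
                                  strand_intensity = 1,
                                  background_gradient_amp = 0,
                                  noise_sd = 0,
                                  distractor_blobs = list(),
                                  seed = 1) {
  if (strand_width_px < 1) stop("strand_width_px must be >= 1")
  H <- image_size_px[1]; W <- image_size_px[2]
  set.seed(as.integer(seed))
  pts <- matrix(FALSE, H, W)
  for (s in seq_len(n_strands)) {
    r <- stats::runif(1, 1, H); c <- stats::runif(1, 1, W)
    ang <- stats::runif(1, 0, 2 * pi)
    n_steps <- round(0.6 * max(H, W))
    for (i in seq_len(n_steps)) {
      ang <- ang + stats::rnorm(1, sd = 0.15)
      r <- r + sin(ang); c <- c + cos(ang)
      if (r < 1 || r > H || c < 1 || c > W) break
      pts[round(r), round(c)] <- TRUE
    }
  }
  truth <- if (any(pts)) {
    br <- EBImage::makeBrush(max(1L, 2L * floor(strand_width_px / 2) + 1L),
                             shape = "disc")
    matrix(as.numeric(EBImage::dilate(matrix(as.numeric(pts), H, W), br)), H, W) > 0
  } else pts

  img <- matrix(0, H, W)
  img[truth] <- strand_intensity

  blob_info <- list()
  if (length(distractor_blobs)) {
    occupied <- truth
    for (k in seq_along(distractor_blobs)) {
      spec_k <- distractor_blobs[[k]]
      area <- as.integer(spec_k[1]); thick <- as.integer(spec_k[2])
      len <- ceiling(area / thick)
      placed <- FALSE
      for (try in 1:200) {
        r0 <- sample.int(H - thick - 2L, 1); c0 <- sample.int(W - len - 2L, 1)
        rows <- r0:(r0 + thick - 1L); cols <- c0:(c0 + len - 1L)
        pad_r <- max(1, r0 - 3):min(H, r0 + thick + 2)
        pad_c <- max(1, c0 - 3):min(W, c0 + len + 2)
        if (any(occupied[pad_r, pad_c])) next
        blob <- matrix(FALSE, H, W)
        blob[rows, cols[-length(cols)]] <- TRUE
        rem <- area - thick * (len - 1L)  # partial last column, exact area
        if (rem > 0) blob[r0:(r0 + rem - 1L), cols[length(cols)]] <- TRUE
        img[blob] <- strand_intensity
        occupied <- occupied | blob
        blob_info[[k]] <- data.frame(area_px = sum(blob), thickness_px = thick)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place distractor blob ", k)
    }
  }
  if (background_gradient_amp != 0) {
    gx <- seq(-1, 1, length.out = W)
    img <- img + background_gradient_amp *
      (matrix(seq(-1, 1, length.out = H), H, W) + matrix(gx, H, W, byrow = TRUE)) / 2
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
  structure(list(image = img, truth_mask = truth,
                 truth_density = mean(truth),
                 distractors = if (length(blob_info)) do.call(rbind, blob_info)
                               else data.frame(area_px = numeric(),
                                               thickness_px = numeric())),
            class = "plexus_sim")
}

#' Simulate a 3-channel ganglion micrograph with planted somata
#'
#' The HuC/D channel shows `n_somata` non-overlapping disks (neuronal cell
#' bodies); the PGP 9.5 channel covers the somata plus connecting strokes
#' (projections); the SHANK3 channel is an exact pixelwise multiple of the
#' PGP channel, so the planted SHANK3:PGP intensity ratio is known exactly.
#'
#' @param n_somata number of somata.
#' @param soma_radius_px disk radius (px).
#' @param min_separation_px minimum center-to-center distance; defaults to
#'   `3 * soma_radius_px` (disjoint disks).
#' @param image_size_px `c(H, W)`.
#' @param hucd_gain,pgp_gain,shank3_gain peak channel intensities (AU); the
#'   planted expression ratio is `shank3_gain / pgp_gain`.
#' @param noise_sd per-channel additive Gaussian noise SD (AU).
#' @param roi_margin_px margin of the rectangular ROI around the somata.
#' @param max_tries placement retries before giving up.
#' @param seed integer seed.
#' @return A list of class `ganglia_sim`: `image` (H x W x 3 array, channels
#'   hucd/pgp/shank3), `roi` (polygon vertex matrix, columns x,y in 0-based
#'   pixel coordinates), `truth` (list: `n_somata`, `shank3_pgp_ratio`,
#'   `centers`, `soma_radius_px`, `pgp_mask`, `hucd_mask`).
#' @export
simulate_ganglia_image <- function(n_somata = 30, soma_radius_px = 8,
                                   min_separation_px = NULL,
                                   image_size_px = c(400, 400),
                                   hucd_gain = 1, pgp_gain = 1,
                                   shank3_gain = 0.8, noise_sd = 0,
                                   roi_margin_px = 15, max_tries = 5000,
                                   seed = 1) {
  H <- image_size_px[1]; W <- image_size_px[2]
  if (is.null(min_separation_px)) min_separation_px <- 3 * soma_radius_px
  set.seed(as.integer(seed))
  centers <- matrix(numeric(0), 0, 2)
  lim <- soma_radius_px + roi_margin_px + 2
  tries <- 0
  while (nrow(centers) < n_somata) {
    if ((tries <- tries + 1) > max_tries)
      stop("could not place ", n_somata, " somata with separation ",
           min_separation_px, " after ", max_tries, " tries")
    cand <- c(stats::runif(1, lim, H - lim), stats::runif(1, lim, W - lim))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_separation_px))
      centers <- rbind(centers, cand)
  }
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  hucd_mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(centers)))
    hucd_mask <- hucd_mask |
      ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= soma_radius_px^2)
  # projections: strokes between consecutive somata
  proj <- matrix(FALSE, H, W)
  if (nrow(centers) >= 2) {
    ord <- order(centers[, 2])
    for (i in seq_len(nrow(centers) - 1)) {
      a <- centers[ord[i], ]; b <- centers[ord[i + 1], ]
      n_pt <- max(2L, ceiling(sqrt(sum((b - a)^2))))
      t_ <- seq(0, 1, length.out = n_pt)
      pr <- round(a[1] + t_ * (b[1] - a[1])); pc <- round(a[2] + t_ * (b[2] - a[2]))
      ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
      proj[cbind(pr[ok], pc[ok])] <- TRUE
    }
    proj <- matrix(as.numeric(EBImage::dilate(
      matrix(as.numeric(proj), H, W), EBImage::makeBrush(3, "diamond"))), H, W) > 0
  }
  pgp_mask <- hucd_mask | proj
  hucd <- hucd_gain * hucd_mask
  pgp <- pgp_gain * pgp_mask
  shank3 <- (shank3_gain / pgp_gain) * pgp
  img <- array(c(hucd, pgp, shank3), dim = c(H, W, 3),
               dimnames = list(NULL, NULL, c("hucd", "pgp", "shank3")))
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim = dim(img))
  if (n_somata > 0) {
    r0 <- max(1, floor(min(centers[, 1]) - soma_radius_px - roi_margin_px))
    r1 <- min(H, ceiling(max(centers[, 1]) + soma_radius_px + roi_margin_px))
    c0 <- max(1, floor(min(centers[, 2]) - soma_radius_px - roi_margin_px))
    c1 <- min(W, ceiling(max(centers[, 2]) + soma_radius_px + roi_margin_px))
  } else { r0 <- 1; r1 <- H; c0 <- 1; c1 <- W }
  # polygon in (x = column, y = row), 0-based vertex coordinates
  roi <- cbind(x = c(c0, c1, c1, c0) - 1, y = c(r0, r0, r1, r1) - 1)
  structure(list(image = img, roi = roi,
                 truth = list(n_somata = n_somata,
                              shank3_pgp_ratio = shank3_gain / pgp_gain,
                              centers = centers,
                              soma_radius_px = soma_radius_px,
                              pgp_mask = pgp_mask, hucd_mask = hucd_mask)),
            class = "ganglia_sim")
}
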