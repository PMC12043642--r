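#' Read a video frame stack
#'
#' Accepts a multi-page TIFF file or a directory of numbered single-frame
#' TIFF/PNG images (sorted by file name). Frames are returned as grayscale
#' matrices (channel mean for color frames).
#'
#' @param path TIFF file or directory.
#' @return A list of numeric matrices, one per frame.
#' @export
read_frames <- function(path) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                    c(1, 2), mean) else a
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG frames found in ", path)
    lapply(files, function(f) {
      a <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
      to_gray(a)
    })
  } else {
    fr <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    lapply(fr, to_gray)
  }
}

#' Build a spatiotemporal diameter map from a colon video
#'
#' Per frame, the colon silhouette is segmented by thresholding (Otsu by
#' default; the preparation is assumed darker than the bath, pre-cropped and
#' axis-aligned). For each position along the colon axis the diameter is the
#' count of silhouette pixels along the transverse line times `mm_per_px`
#' (a pixel count is robust to interior holes, unlike a bounding extent).
#' One STMap column is produced per frame.
#'
#' @param frames list of grayscale matrices (see [read_frames]) or an
#'   H x W x N array.
#' @param mm_per_px spatial calibration (mm per pixel).
#' @param fps frame rate (frames per second).
#' @param orientation `"colon-along-x"` (axis along columns; default) or
#'   `"colon-along-y"`.
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param object `"dark"` (silhouette below threshold; default) or
#'   `"bright"`.
#' @param min_colon_px minimum silhouette size per frame; a frame below it
#'   stops the build with an error naming the frame.
#' @return An [stmap] with `mm_per_row = mm_per_px` and
#'   `s_per_frame = 1 / fps`.
#' @export
build_stmap <- function(frames, mm_per_px, fps,
                        orientation = c("colon-along-x", "colon-along-y"),
                        threshold_method = "otsu", object = c("dark", "bright"),
                        min_colon_px = 50) {
  orientation <- match.arg(orientation)
  object <- match.arg(object)
  stopifnot(mm_per_px > 0, fps > 0)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("all frames must have identical dimensions")
  cols <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (orientation == "colon-along-y") f <- t(f)
    thr <- if (identical(threshold_method, "otsu")) otsu_threshold(f)
           else as.numeric(threshold_method)
    sil <- if (object == "dark") f < thr else f > thr
    if (sum(sil) < min_colon_px)
      stop("frame ", i, ": no colon silhouette of at least ",
           min_colon_px, " px found")
    colSums(sil) * mm_per_px   # diameter per along-axis position
  })
  stmap(do.call(cbind, cols), mm_per_row = mm_per_px, s_per_frame = 1 / fps)
}

#' Render a synthetic colon video from a planted diameter profile
#'
#' Produces frames showing a dark horizontal bar on a light field whose
#' width at along-axis position x in frame t is `diam[x, t] / mm_per_px`
#' pixels, for exercising [build_stmap] against a known map.
#'
#' @param map an [stmap] giving the planted diameters.
#' @param mm_per_px pixel calibration of the rendered video.
#' @param height_px frame height (the bar is vertically centered).
#' @return A list of frames (matrices in `[0, 1]`, bar = 0, bath = 1).
#' @export
render_colon_video <- function(map, mm_per_px = mm_per_row(map),
                               height_px = NULL) {
  stopifnot(is.stmap(map))
  wmax <- ceiling(max(map) / mm_per_px)
  if (is.null(height_px)) height_px <- 2L * wmax + 20L
  mid <- height_px / 2
  lapply(seq_len(ncol(map)), function(t) {
    f <- matrix(1, height_px, nrow(map))
    w <- round(unclass(map)[, t] / mm_per_px)
    for (x in seq_len(nrow(map))) {
      if (w[x] > 0) {
        lo <- max(1L, floor(mid - w[x] / 2) + 1L)
        f[lo:(lo + w[x] - 1L), x] <- 0
      }
    }
    f
  })
}
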