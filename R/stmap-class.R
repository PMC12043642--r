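#' Spatiotemporal diameter map (STMap)
#'
#' An STMap is a matrix of colon diameters indexed by position along the colon
#' (rows; row 1 is the most proximal) and time (columns; one column per video
#' frame), together with its spatial and temporal calibration. Propagating
#' contractions appear as oblique stripes of reduced diameter.
#'
#' @param values numeric matrix of diameters in mm, rows = positions,
#'   columns = frames. Must be non-negative with at least 20 rows and 50
#'   columns.
#' @param mm_per_row spatial calibration, mm of colon per row (> 0).
#' @param s_per_frame temporal calibration, seconds per column (> 0).
#' @param normalized logical; `TRUE` marks a unitless row-normalized map.
#'
#' @return An object of class `stmap`: the values matrix with calibration
#'   attributes. `colon_length_mm(x)` equals `nrow(x) * mm_per_row` and
#'   `recording_s(x)` equals `ncol(x) * s_per_frame`.
#' @export
stmap <- function(values, mm_per_row, s_per_frame, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 20L || ncol(values) < 50L)
    stop("an STMap needs at least 20 rows (positions) and 50 columns (frames); got ",
         nrow(values), " x ", ncol(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("STMap values must be finite and non-negative")
  if (!is.numeric(mm_per_row) || length(mm_per_row) != 1L || mm_per_row <= 0)
    stop("`mm_per_row` must be a single positive number")
  if (!is.numeric(s_per_frame) || length(s_per_frame) != 1L || s_per_frame <= 0)
    stop("`s_per_frame` must be a single positive number")
  structure(values,
            mm_per_row = mm_per_row,
            s_per_frame = s_per_frame,
            normalized = isTRUE(normalized),
            class = c("stmap", "matrix", "array"))
}

#' @export
#' @rdname stmap
#' @param x an `stmap` object.
is.stmap <- function(x) inherits(x, "stmap")

#' @export
#' @rdname stmap
mm_per_row <- function(x) attr(x, "mm_per_row")

#' @export
#' @rdname stmap
s_per_frame <- function(x) attr(x, "s_per_frame")

#' @export
#' @rdname stmap
colon_length_mm <- function(x) nrow(x) * attr(x, "mm_per_row")

#' @export
#' @rdname stmap
recording_s <- function(x) ncol(x) * attr(x, "s_per_frame")

# Positions (mm) of row centers; row r covers [(r-1), r) * mm_per_row.
row_center_mm <- function(x) (seq_len(nrow(x)) - 0.5) * mm_per_row(x)

# Times (s) of frame centers, frame t covers [(t-1), t) * s_per_frame.
frame_time_s <- function(x) (seq_len(ncol(x)) - 1) * s_per_frame(x)

#' @export
print.stmap <- function(x, ...) {
  kind <- if (isTRUE(attr(x, "normalized"))) "normalized (unitless)" else "diameter (mm)"
  cat(sprintf("STMap: %d positions x %d frames, %s\n", nrow(x), ncol(x), kind))
  cat(sprintf("  colon length %.2f mm (%.3f mm/row), recording %.1f s (%.3f s/frame)\n",
              colon_length_mm(x), mm_per_row(x), recording_s(x), s_per_frame(x)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
plot.stmap <- function(x, main = "Spatiotemporal map", ...) {
  # time on x, proximal colon at top, darker = narrower (contraction stripes)
  z <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  graphics::image(x = frame_time_s(x), y = rev(colon_length_mm(x) - row_center_mm(x)),
                  z = z, col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "time (s)", ylab = "position from distal end (mm)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Write / read an STMap as CSV plus JSON sidecar
#'
#' The CSV holds the raw matrix (rows = positions, no header); the JSON
#' sidecar (`<path>.json`) holds the calibration, which is required on read
#' and never defaulted.
#'
#' @param map an [stmap] object.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param truth optional list of planted contraction truth (from
#'   [simulate_stmap]); stored in the sidecar verbatim.
#' @return `write_stmap` returns `path` invisibly; `read_stmap` returns the
#'   [stmap] (with a `"truth"` attribute if the sidecar carries one).
#' @export
write_stmap <- function(map, path, truth = NULL) {
  stopifnot(is.stmap(map))
  utils::write.table(unclass(map), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- list(mm_per_row = mm_per_row(map),
               s_per_frame = s_per_frame(map),
               n_rows = nrow(map), n_cols = ncol(map),
               normalized = isTRUE(attr(map, "normalized")))
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stmap
#' @export
read_stmap <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("calibration sidecar not found: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing_keys <- setdiff(c("mm_per_row", "s_per_frame"), names(side))
  if (length(missing_keys))
    stop("sidecar is missing required calibration keys: ",
         paste(missing_keys, collapse = ", "))
  if (file.info(path)$size == 0) stop("empty STMap CSV: ", path)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  m <- stmap(vals, side$mm_per_row, side$s_per_frame,
             normalized = isTRUE(side$normalized))
  if (!is.null(side$truth)) attr(m, "truth") <- side$truth
  m
}
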