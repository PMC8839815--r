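# Per-camera segmentation configuration: every constant the pipeline needs.

#' CIELAB interval threshold
#'
#' Open intervals on the L, a and b channels; a pixel matches iff all three
#' channel values lie strictly inside their interval.
#'
#' @param L,a,b numeric length-2 vectors c(min, max), min < max.
#' @return An object of class \code{lab_threshold}.
#' @export
lab_threshold <- function(L, a, b) {
  t <- list(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  for (ch in names(t)) {
    if (length(t[[ch]]) != 2L || !all(is.finite(t[[ch]])))
      stop("channel ", ch, " must be a finite c(min, max) pair")
    if (t[[ch]][1] >= t[[ch]][2])
      stop("channel ", ch, ": min must be < max")
  }
  structure(t, class = "lab_threshold")
}

#' Segmentation configuration for one camera
#'
#' Bundles the region of interest, the garment (swimwear/cap/harness)
#' colour intervals, the replacement colour, the water-removal L* interval,
#' the water-line row, and the minimum blob area.
#'
#' Row coordinates are 1-based, as in R matrices: the water-line row
#' \code{i} means rows with index >= i (at and below the line) are kept and
#' rows above it are discarded, which removes the mirrored reflection of
#' the swimmer on the water surface.
#'
#' @param roi NULL for the full frame, or c(top, left, height, width)
#'   (1-based top/left).
#' @param garment_threshold a \code{\link{lab_threshold}}; pixels inside it
#'   are repainted with \code{replacement_rgb}.
#' @param replacement_rgb length-3 RGB triple in [0, 255].
#' @param water_lstar_range c(min, max) open L* interval of pixels to keep.
#' @param waterline_row 1-based row index of the water line within the ROI.
#' @param min_blob_area connected components smaller than this many pixels
#'   are discarded.
#' @param camera_label "frontal" or "lateral".
#' @return An object of class \code{segmentation_config}.
#' @export
segmentation_config <- function(roi = NULL,
                                garment_threshold = lab_threshold(
                                  L = c(25.466, 98.620),
                                  a = c(-46.336, 8.860),
                                  b = c(-31.446, 60.616)),
                                replacement_rgb = c(27, 131, 135),
                                water_lstar_range = c(5, 160),
                                waterline_row = 97L,
                                min_blob_area = 3000L,
                                camera_label = c("frontal", "lateral")) {
  camera_label <- match.arg(camera_label)
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4L || any(roi[3:4] < 1L) || any(roi[1:2] < 1L))
      stop("roi must be c(top, left, height, width) with height, width >= 1")
  }
  if (!inherits(garment_threshold, "lab_threshold"))
    stop("garment_threshold must be a lab_threshold()")
  replacement_rgb <- as.numeric(replacement_rgb)
  if (length(replacement_rgb) != 3L ||
      any(replacement_rgb < 0) || any(replacement_rgb > 255))
    stop("replacement_rgb must be three values in [0, 255]")
  water_lstar_range <- as.numeric(water_lstar_range)
  if (length(water_lstar_range) != 2L ||
      water_lstar_range[1] >= water_lstar_range[2])
    stop("water_lstar_range must be c(min, max) with min < max")
  waterline_row <- as.integer(waterline_row)
  if (waterline_row < 1L) stop("waterline_row must be >= 1 (1-based row index)")
  min_blob_area <- as.integer(min_blob_area)
  if (min_blob_area < 0L) stop("min_blob_area must be >= 0")
  structure(list(roi = roi,
                 garment_threshold = garment_threshold,
                 replacement_rgb = replacement_rgb,
                 water_lstar_range = water_lstar_range,
                 waterline_row = waterline_row,
                 min_blob_area = min_blob_area,
                 camera_label = camera_label),
            class = "segmentation_config")
}

#' Shipped frontal-camera configuration
#'
#' The published frontal constants: garment intervals
#' 25.466 < L < 98.620, -46.336 < a < 8.860, -31.446 < b < 60.616;
#' replacement colour (27, 131, 135); water interval 5 < L* < 160;
#' water-line row i = 97; minimum blob area 3000 px.
#'
#' @param ... overrides passed to \code{\link{segmentation_config}}.
#' @return A \code{segmentation_config}.
#' @export
frontal_config <- function(...) {
  segmentation_config(camera_label = "frontal", ...)
}

#' Lateral-camera configuration
#'
#' No lateral threshold values are published; the lateral defaults equal the
#' frontal ones and are meant to be customised per recording via \code{...}.
#'
#' @param ... overrides passed to \code{\link{segmentation_config}}.
#' @return A \code{segmentation_config}.
#' @export
lateral_config <- function(...) {
  segmentation_config(camera_label = "lateral", ...)
}

#' Read / write a segmentation configuration as YAML
#'
#' The YAML file stores every field of \code{\link{segmentation_config}};
#' a write/read round trip reproduces each value exactly.
#'
#' @param path file path.
#' @return \code{read_config}: a \code{segmentation_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  segmentation_config(
    roi = y$roi,
    garment_threshold = lab_threshold(L = unlist(y$garment_threshold$L),
                                      a = unlist(y$garment_threshold$a),
                                      b = unlist(y$garment_threshold$b)),
    replacement_rgb = unlist(y$replacement_rgb),
    water_lstar_range = unlist(y$water_lstar_range),
    waterline_row = y$waterline_row,
    min_blob_area = y$min_blob_area,
    camera_label = y$camera_label)
}

#' @param config a \code{segmentation_config}.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "segmentation_config"))
  y <- list(camera_label = config$camera_label,
            roi = config$roi,
            garment_threshold = list(L = config$garment_threshold$L,
                                     a = config$garment_threshold$a,
                                     b = config$garment_threshold$b),
            replacement_rgb = config$replacement_rgb,
            water_lstar_range = config$water_lstar_range,
            waterline_row = config$waterline_row,
            min_blob_area = config$min_blob_area)
  yaml::write_yaml(y, path, precision = 12L)
  invisible(path)
}

#' @export
print.segmentation_config <- function(x, ...) {
  t <- x$garment_threshold
  cat("Segmentation config (", x$camera_label, " camera)\n", sep = "")
  cat("  ROI:              ",
      if (is.null(x$roi)) "full frame"
      else sprintf("top %d, left %d, %d x %d", x$roi[1], x$roi[2],
                   x$roi[3], x$roi[4]), "\n", sep = "")
  cat(sprintf("  garment mask:     %.3f < L < %.3f, %.3f < a < %.3f, %.3f < b < %.3f\n",
              t$L[1], t$L[2], t$a[1], t$a[2], t$b[1], t$b[2]))
  cat(sprintf("  replacement RGB:  (%g, %g, %g)\n", x$replacement_rgb[1],
              x$replacement_rgb[2], x$replacement_rgb[3]))
  cat(sprintf("  water keep range: %g < L* < %g\n",
              x$water_lstar_range[1], x$water_lstar_range[2]))
  cat(sprintf("  water-line row:   i = %d\n", x$waterline_row))
  cat(sprintf("  min blob area:    %d px\n", x$min_blob_area))
  invisible(x)
}
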