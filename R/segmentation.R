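# The per-frame area-detection pipeline: ROI crop, garment replacement,
# water removal, water-line filter, binarisation, blob filtering, hole
# filling and pixel counting. Binary masks are logical H x W matrices;
# area is the number of TRUE pixels.

#' Crop a frame to a region of interest
#'
#' @param frame H x W x 3 array.
#' @param roi c(top, left, height, width), 1-based.
#' @return the cropped frame (height x width x 3).
#' @export
crop_roi <- function(frame, roi) {
  .validate_frame(frame)
  roi <- as.integer(roi)
  if (length(roi) != 4L) stop("roi must be c(top, left, height, width)")
  d <- dim(frame)
  top <- roi[1]; left <- roi[2]; h <- roi[3]; w <- roi[4]
  if (h < 1L || w < 1L) stop("roi height and width must be >= 1")
  if (top < 1L) stop("roi top edge ", top, " is above the frame")
  if (left < 1L) stop("roi left edge ", left, " is left of the frame")
  if (top + h - 1L > d[1])
    stop("roi bottom edge ", top + h - 1L, " exceeds frame height ", d[1])
  if (left + w - 1L > d[2])
    stop("roi right edge ", left + w - 1L, " exceeds frame width ", d[2])
  frame[top:(top + h - 1L), left:(left + w - 1L), , drop = FALSE]
}

#' Threshold a Lab frame with open per-channel intervals
#'
#' A pixel is marked iff its L, a and b values all lie strictly inside the
#' threshold's intervals. With the shipped frontal intervals this marks the
#' swimmer's swimwear, cap and harness (desaturated by the underwater colour
#' cast) for replacement by the skin colour.
#'
#' @param lab H x W x 3 Lab array.
#' @param threshold a \code{\link{lab_threshold}}.
#' @return logical H x W mask.
#' @export
threshold_mask <- function(lab, threshold) {
  stopifnot(inherits(threshold, "lab_threshold"))
  L <- lab[, , 1L, drop = TRUE]
  a <- lab[, , 2L, drop = TRUE]
  b <- lab[, , 3L, drop = TRUE]
  m <- (L > threshold$L[1] & L < threshold$L[2] &
        a > threshold$a[1] & a < threshold$a[2] &
        b > threshold$b[1] & b < threshold$b[2])
  if (is.null(dim(m))) dim(m) <- dim(lab)[1:2]
  m
}

#' Repaint masked pixels with a single RGB colour
#'
#' @param frame H x W x 3 array.
#' @param mask logical H x W matrix.
#' @param rgb length-3 replacement colour in [0, 255].
#' @return frame with masked pixels set to \code{rgb}; all other pixels
#'   are unchanged.
#' @export
replace_pixels <- function(frame, mask, rgb) {
  .validate_frame(frame)
  if (!identical(dim(mask), dim(frame)[1:2]))
    stop("mask dimensions ", paste(dim(mask), collapse = " x "),
         " do not match frame ", paste(dim(frame)[1:2], collapse = " x "))
  rgb <- as.numeric(rgb)
  stopifnot(length(rgb) == 3L, all(rgb >= 0), all(rgb <= 255))
  if (!any(mask)) return(frame)
  if (is.integer(frame) && all(rgb == round(rgb))) rgb <- as.integer(rgb)
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[mask] <- rgb[ch]
    frame[, , ch] <- plane
  }
  frame
}

#' Water-removal mask on normalized lightness
#'
#' Marks the pixels to keep as swimmer candidates: those with
#' min < L* < max (open interval). Water and bright background fall outside
#' the interval and are discarded.
#'
#' @param lstar H x W matrix of L* values (0-255 scale).
#' @param range c(min, max), open interval.
#' @return logical H x W mask of pixels to keep.
#' @export
water_mask <- function(lstar, range = c(5, 160)) {
  stopifnot(is.matrix(lstar), length(range) == 2L, range[1] < range[2])
  lstar > range[1] & lstar < range[2]
}

#' Discard everything above the water line
#'
#' Rows with 1-based index < \code{waterline_row} are set to FALSE; rows at
#' and below the line (index >= waterline_row) are kept. This removes the
#' mirrored reflection of the swimmer above the water surface.
#'
#' @param mask logical H x W matrix.
#' @param waterline_row 1-based row index of the water line.
#' @return the filtered mask.
#' @export
waterline_filter <- function(mask, waterline_row) {
  stopifnot(is.matrix(mask))
  waterline_row <- as.integer(waterline_row)
  if (waterline_row < 1L || waterline_row > nrow(mask))
    stop("waterline_row ", waterline_row, " outside mask rows 1..", nrow(mask))
  if (waterline_row > 1L) mask[seq_len(waterline_row - 1L), ] <- FALSE
  mask
}

#' Global Otsu binarisation
#'
#' Chooses the threshold T in 0..255 that maximizes the between-class
#' variance of the gray-level histogram (ties broken toward the lowest T);
#' a pixel is foreground iff its value > T. A constant image has no
#' separable foreground: the result is an all-FALSE mask and a warning is
#' signalled.
#'
#' @param gray H x W matrix of integer gray levels in [0, 255].
#' @return logical H x W mask with attribute \code{"threshold"} (NA for a
#'   constant image).
#' @export
binarise <- function(gray) {
  stopifnot(is.matrix(gray), length(gray) >= 1L)
  g <- as.integer(gray)
  if (any(g < 0L | g > 255L)) stop("gray levels must lie in [0, 255]")
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- length(g)
  if (sum(counts > 0L) < 2L) {
    warning("constant image: no foreground separable", call. = FALSE)
    out <- matrix(FALSE, nrow(gray), ncol(gray))
    attr(out, "threshold") <- NA_integer_
    return(out)
  }
  p <- counts / n
  omega <- cumsum(p)                 # P(class <= T), T = 0..255
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (muT * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  T <- which.max(sigma_b) - 1L       # first maximum = lowest threshold
  out <- gray > T
  attr(out, "threshold") <- T
  out
}

#' Remove small connected components
#'
#' Labels foreground blobs with 8-connectivity and discards every component
#' whose pixel area is below \code{min_area}; surviving components are kept
#' intact.
#'
#' @param mask logical H x W matrix.
#' @param min_area minimum component area in pixels (>= 0).
#' @return the filtered mask.
#' @export
filter_blobs <- function(mask, min_area) {
  stopifnot(is.matrix(mask))
  min_area <- as.integer(min_area)
  if (min_area < 0L) stop("min_area must be >= 0")
  if (min_area <= 1L || !any(mask)) return(mask & TRUE)
  lab <- .label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions not 4-connected to the raster border are converted to
#' foreground; background touching the border (including bays open to it)
#' is preserved. Idempotent.
#'
#' @param mask logical H x W matrix.
#' @return the filled mask (a superset of the input).
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  .fill_holes_cpp(mask)
}

#' Count foreground pixels
#'
#' @param mask logical H x W matrix.
#' @return integer pixel count.
#' @export
count_area <- function(mask) {
  stopifnot(is.matrix(mask))
  as.integer(sum(mask))
}

#' Run the full area-detection pipeline on one frame
#'
#' Sequences: ROI crop, RGB to Lab, garment threshold, replacement by the
#' skin colour, Lab of the repainted frame, L* water removal, water-line
#' filter, background-suppressed grayscale, Otsu binarisation, minimum-area
#' blob filter, hole filling, pixel count. A frame in which no blob
#' survives yields area 0 with a warning code rather than an error.
#'
#' Warning codes: \code{"constant_image"} (binarisation found no separable
#' foreground), \code{"polarity_inverted"} (the binarised foreground covered
#' more than half the ROI, so the polarity was flipped), \code{"no_blobs"}
#' (nothing survived the minimum-area filter).
#'
#' @param frame H x W x 3 array.
#' @param config a \code{\link{segmentation_config}}.
#' @param frame_index integer identifier carried into the result.
#' @return An object of class \code{frame_result}: list with
#'   \code{area_pixels}, \code{final_mask} (ROI-sized), \code{frame_index},
#'   \code{warnings} (character codes) and \code{otsu_threshold}.
#' @export
process_frame <- function(frame, config = frontal_config(), frame_index = 0L) {
  stopifnot(inherits(config, "segmentation_config"))
  warnings <- character(0)

  roi_frame <- if (is.null(config$roi)) {
    .validate_frame(frame)
    frame
  } else crop_roi(frame, config$roi)
  if (config$waterline_row > nrow(roi_frame))
    stop("waterline_row ", config$waterline_row,
         " exceeds ROI height ", nrow(roi_frame))

  lab <- rgb_to_lab(roi_frame)
  garment <- threshold_mask(lab, config$garment_threshold)
  repainted <- replace_pixels(roi_frame, garment, config$replacement_rgb)

  # Lab of the repainted frame: repainted pixels all carry the replacement
  # colour, whose Lab is known, so only those entries need updating.
  repl_lab <- rgb_to_lab(array(config$replacement_rgb, dim = c(1, 1, 3)))
  lab2 <- lab
  for (ch in 1:3) {
    plane <- lab2[, , ch]
    plane[garment] <- repl_lab[1, 1, ch]
    lab2[, , ch] <- plane
  }
  keep <- water_mask(normalize_lightness(lab2), config$water_lstar_range)
  keep <- waterline_filter(keep, config$waterline_row)

  # suppress removed background to black so water is the dark class
  suppressed <- replace_pixels(repainted, !keep, c(0, 0, 0))
  gray <- rgb_to_gray(suppressed)

  bw <- withCallingHandlers(
    binarise(gray),
    warning = function(w) {
      warnings <<- c(warnings, "constant_image")
      invokeRestart("muffleWarning")
    })
  thr <- attr(bw, "threshold")
  if (mean(bw) > 0.5) {
    bw <- !bw
    warnings <- c(warnings, "polarity_inverted")
  }

  blobs <- filter_blobs(bw, config$min_blob_area)
  if (!any(blobs) && !("constant_image" %in% warnings))
    warnings <- c(warnings, "no_blobs")
  final <- fill_holes(blobs)

  structure(list(area_pixels = count_area(final),
                 final_mask = final,
                 frame_index = as.integer(frame_index),
                 warnings = warnings,
                 otsu_threshold = thr),
            class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat(sprintf("Frame %d: area %d px%s\n", x$frame_index, x$area_pixels,
              if (length(x$warnings))
                paste0(" [", paste(x$warnings, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Run the pipeline over a sequence of frames
#'
#' @param frames list of H x W x 3 arrays in temporal order.
#' @param config a \code{\link{segmentation_config}}.
#' @param fs_hz sampling rate in Hz used for timestamps (default 30).
#' @param keep_masks retain each frame's final mask in the attached
#'   results (FALSE by default: a long run at full resolution would hold
#'   hundreds of megabytes of masks).
#' @return An \code{\link{area_series}} whose rows carry frame_index,
#'   time_s, area_pixels and a semicolon-joined warning string; the list of
#'   \code{frame_result}s is attached as attribute \code{"results"}.
#' @export
process_frames <- function(frames, config = frontal_config(), fs_hz = 30,
                           keep_masks = FALSE) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  results <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    results[[i]] <- process_frame(frames[[i]], config, frame_index = i - 1L)
    if (!keep_masks) results[[i]]$final_mask <- NULL
  }
  areas <- vapply(results, `[[`, integer(1), "area_pixels")
  warn <- vapply(results, function(r) paste(r$warnings, collapse = ";"),
                 character(1))
  s <- area_series(areas, fs_hz = fs_hz, camera_label = config$camera_label)
  s$warnings <- warn
  attr(s, "results") <- results
  s
}
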