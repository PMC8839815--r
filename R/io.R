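# Frame ingestion (PNG/TIFF files or directories), result serialization
# (per-frame CSV, analysis JSON), overlay rendering and the end-to-end run.

.read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF frames")
      tiff::readTIFF(path)
    },
    stop("unsupported frame format '.", ext, "' (PNG or TIFF expected): ",
         path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  out <- floor(img * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Load an ordered frame sequence
#'
#' Accepts a single PNG/TIFF file or a directory of numbered frames (sorted
#' by file name). Timestamps are frame_index / fs_hz.
#'
#' @param source file or directory path.
#' @param fs_hz frame rate used for timestamps (default 30).
#' @return list of H x W x 3 integer arrays with attributes
#'   \code{frame_index} (0-based), \code{time_s} and \code{paths}.
#' @export
load_frames <- function(source, fs_hz = 30) {
  if (!file.exists(source)) stop("input not found: ", source)
  if (dir.exists(source)) {
    paths <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(paths) == 0L)
      stop("no frames found in directory: ", source)
  } else paths <- source
  frames <- lapply(paths, .read_image)
  d1 <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d1))
      stop("frames have inconsistent dimensions")
  structure(frames,
            frame_index = seq_along(frames) - 1L,
            time_s = (seq_along(frames) - 1) / fs_hz,
            paths = paths)
}

#' Write frames as numbered PNG files
#'
#' @param frames list of H x W x 3 arrays in [0, 255] (or a
#'   \code{pool_scene_sequence}).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (inherits(frames, "pool_scene_sequence") ||
      (is.list(frames) && length(frames) && inherits(frames[[1]], "pool_scene")))
    frames <- lapply(frames, `[[`, "frame")
  if (inherits(frames, "pool_scene")) frames <- list(frames$frame)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix,
                                  seq_along(frames) - 1L))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255, paths[i])
  invisible(paths)
}

#' Write / read the per-frame area CSV
#'
#' Fixed schema: columns \code{frame_index}, \code{time_s},
#' \code{area_pixels}, \code{warnings} (semicolon-joined codes); comma
#' separated, '.' decimal separator, header row, UTF-8.
#'
#' @param series an \code{\link{area_series}} (as returned by
#'   \code{\link{process_frames}}).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_area_csv <- function(series, path) {
  stopifnot(inherits(series, "area_series"))
  df <- data.frame(frame_index = series$frame_index,
                   time_s = series$time_s,
                   area_pixels = series$area_pixels,
                   warnings = if (!is.null(series$warnings))
                     series$warnings else "")
  utils::write.csv(df, path, row.names = FALSE, quote = 4L,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @param fs_hz frame rate assumed when rebuilding the series.
#' @param camera_label label attached to the series.
#' @rdname write_area_csv
#' @export
read_area_csv <- function(path, fs_hz = 30, camera_label = "frontal") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  s <- area_series(df$area_pixels, fs_hz = fs_hz, time_s = df$time_s,
                   camera_label = camera_label)
  s$warnings <- as.character(df$warnings)
  s
}

#' Paint a segmentation mask over a frame
#'
#' The final mask is blended translucent red onto the original frame for
#' visual inspection of the segmentation.
#'
#' @param frame H x W x 3 array in [0, 255].
#' @param mask logical mask, ROI-sized.
#' @param roi the config ROI the mask lives in (NULL = full frame).
#' @param alpha blend weight of the red overlay in (0, 1].
#' @return H x W x 3 integer array.
#' @export
render_overlay <- function(frame, mask, roi = NULL, alpha = 0.5) {
  .validate_frame(frame)
  full <- matrix(FALSE, dim(frame)[1], dim(frame)[2])
  if (is.null(roi)) {
    full[] <- mask
  } else {
    full[roi[1]:(roi[1] + roi[3] - 1L), roi[2]:(roi[2] + roi[4] - 1L)] <- mask
  }
  red <- c(255, 0, 0)
  out <- frame
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[full] <- (1 - alpha) * plane[full] + alpha * red[ch]
    out[, , ch] <- plane
  }
  out <- floor(out + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Segment a frame source and write the per-frame CSV
#'
#' @param input frame file/directory, or a list of frames.
#' @param config a \code{\link{segmentation_config}} or a YAML config path.
#' @param out_dir output directory (created).
#' @param overlay also write one overlay PNG per frame.
#' @param fs_hz frame rate for timestamps.
#' @return the \code{\link{area_series}}, invisibly; writes
#'   \code{<camera>_areas.csv} (and \code{overlays/} when requested).
#' @export
segment_run <- function(input, config = frontal_config(), out_dir,
                        overlay = FALSE, fs_hz = 30) {
  if (is.character(config)) config <- read_config(config)
  frames <- if (is.list(input)) input else load_frames(input, fs_hz = fs_hz)
  if (inherits(frames, "pool_scene_sequence") ||
      (length(frames) && inherits(frames[[1]], "pool_scene")))
    frames <- lapply(frames, `[[`, "frame")
  series <- process_frames(frames, config, fs_hz = fs_hz,
                           keep_masks = overlay)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_area_csv(series,
                 file.path(out_dir, paste0(config$camera_label, "_areas.csv")))
  if (overlay) {
    results <- attr(series, "results")
    ov_dir <- file.path(out_dir, "overlays")
    dir.create(ov_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames)) {
      ov <- render_overlay(frames[[i]], results[[i]]$final_mask,
                           roi = config$roi)
      png::writePNG(ov / 255,
                    file.path(ov_dir, sprintf("%s_%05d.png",
                                              config$camera_label, i - 1L)))
    }
  }
  invisible(series)
}

#' Analyse one or two area series
#'
#' Computes the amplitude spectrum and dominant frequency per camera and,
#' when both cameras are supplied, the frame-paired linear regression of
#' lateral on frontal area.
#'
#' @param frontal an \code{\link{area_series}} (or CSV path).
#' @param lateral optional second series (or CSV path).
#' @param pad_factor zero-padding factor for the spectra.
#' @param min_hz lower bound for the dominant-frequency search.
#' @return list (class \code{area_analysis}) with per-camera
#'   \code{dominant_frequency_hz}, \code{peak_magnitude}, and — with two
#'   cameras — \code{regression} (slope, intercept, r_squared).
#' @export
analyze_areas <- function(frontal, lateral = NULL, pad_factor = 8L,
                          min_hz = 0.1) {
  if (is.character(frontal))
    frontal <- read_area_csv(frontal, camera_label = "frontal")
  if (is.character(lateral))
    lateral <- read_area_csv(lateral, camera_label = "lateral")
  one <- function(s) {
    spec <- compute_spectrum(s, pad_factor = pad_factor)
    pk <- dominant_frequency(spec, min_hz = min_hz)
    list(n_frames = nrow(s),
         mean_area_pixels = mean(s$area_pixels),
         dominant_frequency_hz = unname(pk["frequency_hz"]),
         peak_magnitude = unname(pk["magnitude"]))
  }
  report <- list(frontal = one(frontal))
  if (!is.null(lateral)) {
    report$lateral <- one(lateral)
    fit <- linear_fit(frontal, lateral)
    report$regression <- list(slope = fit$slope, intercept = fit$intercept,
                              r_squared = fit$r_squared, n = fit$n)
  }
  structure(report, class = "area_analysis")
}

#' @export
print.area_analysis <- function(x, ...) {
  for (cam in intersect(c("frontal", "lateral"), names(x)))
    cat(sprintf("%s: %d frames, mean area %.1f px, peak %.5f Hz (amp %.1f)\n",
                cam, x[[cam]]$n_frames, x[[cam]]$mean_area_pixels,
                x[[cam]]$dominant_frequency_hz, x[[cam]]$peak_magnitude))
  if (!is.null(x$regression))
    cat(sprintf("lateral ~ frontal: slope %.4g, intercept %.4g, R^2 %.4g\n",
                x$regression$slope, x$regression$intercept,
                x$regression$r_squared))
  invisible(x)
}

#' End-to-end run: segment one or two cameras and write all artifacts
#'
#' Writes per-camera \code{<camera>_areas.csv}, an \code{analysis.json}
#' report (regression included when both cameras are given) and optional
#' overlay PNGs. Identical inputs and configuration produce byte-identical
#' outputs.
#'
#' @param frontal_input,lateral_input frame sources
#'   (see \code{\link{segment_run}}); lateral may be NULL.
#' @param frontal_config,lateral_config per-camera configs or YAML paths.
#' @param out_dir output directory.
#' @param overlay write overlay PNGs.
#' @param fs_hz frame rate.
#' @param pad_factor spectrum zero-padding factor.
#' @return the \code{area_analysis} report, invisibly.
#' @export
run_pipeline <- function(frontal_input, lateral_input = NULL,
                         frontal_config = swimarea::frontal_config(),
                         lateral_config = swimarea::lateral_config(),
                         out_dir, overlay = FALSE, fs_hz = 30,
                         pad_factor = 8L) {
  if (is.character(frontal_config)) frontal_config <- read_config(frontal_config)
  if (is.character(lateral_config)) lateral_config <- read_config(lateral_config)
  fr <- segment_run(frontal_input, frontal_config, out_dir,
                    overlay = overlay, fs_hz = fs_hz)
  la <- if (!is.null(lateral_input))
    segment_run(lateral_input, lateral_config, out_dir,
                overlay = overlay, fs_hz = fs_hz)
  report <- analyze_areas(fr, la, pad_factor = pad_factor)
  jsonlite::write_json(unclass(report), file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
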