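# Parametric synthetic pool scenes with exact ground-truth silhouettes.
#
# A scene emulates the elements the segmentation pipeline must handle:
# bluish-green water, a horizontal water line with a mirrored (attenuated)
# reflection of the swimmer above it, lane-rope stripes at the surface, and
# a swimmer composed of skin, swimwear and cap regions. Default colours are
# chosen so the garments fall strictly inside the shipped garment Lab
# intervals (they get repainted with the chest colour) while water and lane
# ropes fall outside both the garment intervals and the 5 < L* < 160 keep
# range — the printed constants are exercised, not bypassed.

#' Synthetic pool-scene specification
#'
#' @param frame_height,frame_width raster size in pixels.
#' @param water_rgb,lane_rgb,skin_rgb,swimwear_rgb,cap_rgb colour triples in
#'   [0, 255]. Garment colours are desaturated, as under the underwater
#'   colour cast.
#' @param waterline_row 1-based row of the water line; the swimmer sits at
#'   or below it, the reflection above it.
#' @param swimmer list with \code{torso} (ellipse: \code{centre} c(row, col),
#'   \code{semi_axes} c(rows, cols)), \code{head} (disc: \code{centre},
#'   \code{radius}) and \code{limbs} (list of rotated rectangles:
#'   \code{centre}, \code{length}, \code{width}, \code{angle_deg} measured
#'   from the horizontal). NULL for an empty scene.
#' @param reflection_enabled draw the mirrored reflection above the line,
#'   attenuated 30 percent toward the water colour.
#' @param noise_sd per-channel i.i.d. Gaussian noise, clipped to [0, 255].
#' @param seed integer RNG seed making the render deterministic.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(frame_height = 240L, frame_width = 360L,
                       water_rgb = c(0, 190, 250),
                       lane_rgb = c(240, 220, 60),
                       skin_rgb = c(35, 140, 140),
                       swimwear_rgb = c(75, 60, 62),
                       cap_rgb = c(70, 70, 75),
                       waterline_row = 97L,
                       swimmer = default_swimmer(),
                       reflection_enabled = TRUE,
                       noise_sd = 3,
                       seed = 1L) {
  for (nm in c("water_rgb", "lane_rgb", "skin_rgb", "swimwear_rgb",
               "cap_rgb")) {
    v <- get(nm)
    if (length(v) != 3L || any(v < 0) || any(v > 255))
      stop(nm, " must be three values in [0, 255]")
  }
  frame_height <- as.integer(frame_height)
  frame_width <- as.integer(frame_width)
  stopifnot(frame_height >= 1L, frame_width >= 1L)
  waterline_row <- as.integer(waterline_row)
  if (waterline_row < 1L || waterline_row > frame_height)
    stop("waterline_row outside the frame")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(frame_height = frame_height, frame_width = frame_width,
                 water_rgb = as.numeric(water_rgb),
                 lane_rgb = as.numeric(lane_rgb),
                 skin_rgb = as.numeric(skin_rgb),
                 swimwear_rgb = as.numeric(swimwear_rgb),
                 cap_rgb = as.numeric(cap_rgb),
                 waterline_row = waterline_row,
                 swimmer = swimmer,
                 reflection_enabled = isTRUE(reflection_enabled),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default swimmer silhouette (frontal view)
#'
#' Torso ellipse, head disc and two slanted arm rectangles sized for the
#' default 240 x 360 frame: about 5000 px of silhouette, comfortably above
#' the 3000 px minimum-blob threshold, fully below the water line at row 97.
#'
#' @param size_scale multiplies every size (semi-axes, radius, limb
#'   length/width); centres are fixed.
#' @return list understood by \code{\link{scene_spec}}.
#' @export
default_swimmer <- function(size_scale = 1) {
  list(torso = list(centre = c(158, 180), semi_axes = c(42, 27) * size_scale),
       head = list(centre = c(121, 180), radius = 13 * size_scale),
       limbs = list(
         list(centre = c(150, 146), length = 58 * size_scale,
              width = 13 * size_scale, angle_deg = 60),
         list(centre = c(150, 214), length = 58 * size_scale,
              width = 13 * size_scale, angle_deg = 120)))
}

# Rasterize the swimmer at a given size scale. Returns region masks and the
# analytic bounding box used for containment checks.
.swimmer_regions <- function(swimmer, H, W, scale = 1) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  empty <- matrix(FALSE, H, W)
  if (is.null(swimmer))
    return(list(torso = empty, head = empty, cap = empty, limbs = empty,
                silhouette = empty, bbox = NULL))

  bbox <- c(top = Inf, bottom = -Inf, left = Inf, right = -Inf)
  grow <- function(bbox, top, bottom, left, right)
    c(top = min(bbox[["top"]], top), bottom = max(bbox[["bottom"]], bottom),
      left = min(bbox[["left"]], left), right = max(bbox[["right"]], right))

  torso <- head <- cap <- empty
  if (!is.null(swimmer$torso)) {
    t <- swimmer$torso
    ax <- t$semi_axes * scale
    torso <- ((rr - t$centre[1]) / ax[1])^2 +
      ((cc - t$centre[2]) / ax[2])^2 <= 1
    bbox <- grow(bbox, t$centre[1] - ax[1], t$centre[1] + ax[1],
                 t$centre[2] - ax[2], t$centre[2] + ax[2])
  }

  if (!is.null(swimmer$head)) {
    h <- swimmer$head
    rad <- h$radius * scale
    head <- (rr - h$centre[1])^2 + (cc - h$centre[2])^2 <= rad^2
    cap <- head & rr <= h$centre[1] - 0.4 * rad
    bbox <- grow(bbox, h$centre[1] - rad, h$centre[1] + rad,
                 h$centre[2] - rad, h$centre[2] + rad)
  }

  limbs <- empty
  for (lb in swimmer$limbs) {
    th <- lb$angle_deg * pi / 180
    len <- lb$length * scale; wid <- lb$width * scale
    dy <- rr - lb$centre[1]; dx <- cc - lb$centre[2]
    u <- dx * cos(th) + dy * sin(th)    # along the limb axis
    v <- -dx * sin(th) + dy * cos(th)   # across it
    limbs <- limbs | (abs(u) <= len / 2 & abs(v) <= wid / 2)
    half <- (len + wid) / 2             # conservative rotated-rect extent
    bbox <- grow(bbox, lb$centre[1] - half, lb$centre[1] + half,
                 lb$centre[2] - half, lb$centre[2] + half)
  }

  list(torso = torso, head = head, cap = cap, limbs = limbs,
       silhouette = torso | head | limbs, bbox = bbox)
}

.render_scene_impl <- function(spec, scale = 1) {
  H <- spec$frame_height; W <- spec$frame_width
  reg <- .swimmer_regions(spec$swimmer, H, W, scale)

  if (!is.null(reg$bbox)) {
    bb <- reg$bbox
    if (bb[["top"]] < 1 || bb[["bottom"]] > H ||
        bb[["left"]] < 1 || bb[["right"]] > W)
      stop("silhouette exceeds the frame bounds")
    if (spec$reflection_enabled && bb[["top"]] < spec$waterline_row)
      stop("silhouette must lie fully below the water line when the ",
           "reflection is enabled")
  }

  frame <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) frame[, , ch] <- spec$water_rgb[ch]

  # lane-rope stripes straddling the surface, alternating with white floats
  rope_rows <- (spec$waterline_row - 2L):(spec$waterline_row + 1L)
  rope_rows <- rope_rows[rope_rows >= 1L & rope_rows <= H]
  if (length(rope_rows)) {
    stripe <- ((seq_len(W) - 1L) %/% 20L) %% 2L == 0L
    for (ch in 1:3) {
      band <- matrix(ifelse(stripe, spec$lane_rgb[ch], 255),
                     length(rope_rows), W, byrow = TRUE)
      frame[rope_rows, , ch] <- band
    }
  }

  paint <- function(frame, mask, rgb) {
    for (ch in 1:3) {
      plane <- frame[, , ch]
      plane[mask] <- rgb[ch]
      frame[, , ch] <- plane
    }
    frame
  }

  # mirrored reflection above the water line, attenuated toward the water
  if (spec$reflection_enabled && any(reg$silhouette)) {
    att <- function(rgb) 0.7 * rgb + 0.3 * spec$water_rgb
    w <- spec$waterline_row
    src_rows <- which(apply(reg$silhouette, 1, any))
    for (r in src_rows) {
      r_img <- 2L * w - r
      if (r_img < 1L || r_img >= w) next
      for (part in c("limbs", "torso", "head", "cap")) {
        colr <- switch(part, limbs = spec$skin_rgb, torso = spec$swimwear_rgb,
                       head = spec$skin_rgb, cap = spec$cap_rgb)
        cols <- which(reg[[part]][r, ])
        if (length(cols))
          for (ch in 1:3) frame[r_img, cols, ch] <- att(colr)[ch]
      }
    }
  }

  frame <- paint(frame, reg$limbs, spec$skin_rgb)
  frame <- paint(frame, reg$torso, spec$swimwear_rgb)
  frame <- paint(frame, reg$head & !reg$cap, spec$skin_rgb)
  frame <- paint(frame, reg$cap, spec$cap_rgb)

  if (spec$noise_sd > 0)
    frame <- frame + rnorm(length(frame), 0, spec$noise_sd)
  frame <- floor(pmin(pmax(frame, 0), 255) + 0.5)
  storage.mode(frame) <- "integer"

  structure(list(frame = frame,
                 truth = list(silhouette_mask = reg$silhouette,
                              area_pixels = as.integer(sum(reg$silhouette))),
                 spec = spec),
            class = "pool_scene")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Render one synthetic pool scene
#'
#' Deterministic for a fixed spec (the spec's seed drives the pixel noise).
#' The ground truth counts only true silhouette pixels, never the mirrored
#' reflection.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @return An object of class \code{pool_scene}: list with \code{frame}
#'   (H x W x 3 integer array), \code{truth} (list of
#'   \code{silhouette_mask}, \code{area_pixels}) and \code{spec}.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, .render_scene_impl(spec))
}

#' @export
print.pool_scene <- function(x, ...) {
  d <- dim(x$frame)
  cat(sprintf("Synthetic pool scene %d x %d, ground-truth area %d px\n",
              d[1], d[2], x$truth$area_pixels))
  invisible(x)
}

#' Render a sequence with a stroke-like area oscillation
#'
#' Every silhouette size is modulated by 1 + A sin(2 pi f t) about fixed
#' centres, so the ground-truth area oscillates at the stroke frequency f
#' (its dominant spectral component for moderate A).
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param n_frames number of frames (>= 1).
#' @param osc_freq_hz oscillation frequency in Hz; must be below the
#'   Nyquist frequency fs/2.
#' @param osc_amplitude relative size-modulation amplitude A (default 0.10).
#' @param fs_hz frame rate in Hz (default 30).
#' @param osc_phase_rad phase offset of the modulation in radians; the
#'   frontal and lateral projections of a real stroke peak at different
#'   phases, so giving the two cameras different phases emulates their
#'   decorrelation.
#' @return An object of class \code{pool_scene_sequence}: list of
#'   \code{pool_scene}s with attributes \code{fs_hz}, \code{osc_freq_hz}.
#' @export
render_sequence <- function(spec, n_frames, osc_freq_hz = 0.476,
                            osc_amplitude = 0.10, fs_hz = 30,
                            osc_phase_rad = 0) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1L)
  if (osc_freq_hz >= fs_hz / 2)
    stop("osc_freq_hz = ", osc_freq_hz, " Hz aliases at fs = ", fs_hz,
         " Hz (Nyquist ", fs_hz / 2, " Hz)")
  if (osc_amplitude < 0) stop("osc_amplitude must be >= 0")
  scenes <- .with_seed(spec$seed, {
    out <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      t <- (i - 1) / fs_hz
      s <- 1 + osc_amplitude * sin(2 * pi * osc_freq_hz * t + osc_phase_rad)
      out[[i]] <- .render_scene_impl(spec, scale = s)
    }
    out
  })
  structure(scenes, fs_hz = fs_hz, osc_freq_hz = osc_freq_hz,
            osc_amplitude = osc_amplitude, class = "pool_scene_sequence")
}

#' Render and segment a long sequence frame by frame
#'
#' Streaming counterpart of \code{\link{render_sequence}} followed by
#' \code{\link{process_frames}}: each frame is rendered, segmented and
#' discarded, so a 60 s run needs only one frame in memory at a time. The
#' rendered frames are identical to those of \code{\link{render_sequence}}
#' with the same spec and parameters.
#'
#' @inheritParams render_sequence
#' @param config a \code{\link{segmentation_config}} applied to every frame.
#' @return list with \code{truth} and \code{estimate}, both
#'   \code{\link{area_series}} (the estimate carries per-frame warning
#'   codes).
#' @export
segment_synthetic_sequence <- function(spec, n_frames, osc_freq_hz = 0.476,
                                       osc_amplitude = 0.10, fs_hz = 30,
                                       osc_phase_rad = 0,
                                       config = frontal_config()) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1L)
  if (osc_freq_hz >= fs_hz / 2)
    stop("osc_freq_hz = ", osc_freq_hz, " Hz aliases at fs = ", fs_hz,
         " Hz (Nyquist ", fs_hz / 2, " Hz)")
  truth_area <- integer(n_frames)
  est_area <- integer(n_frames)
  warn <- character(n_frames)
  .with_seed(spec$seed, {
    for (i in seq_len(n_frames)) {
      t <- (i - 1) / fs_hz
      s <- 1 + osc_amplitude * sin(2 * pi * osc_freq_hz * t + osc_phase_rad)
      scene <- .render_scene_impl(spec, scale = s)
      truth_area[i] <- scene$truth$area_pixels
      res <- process_frame(scene$frame, config, frame_index = i - 1L)
      est_area[i] <- res$area_pixels
      warn[i] <- paste(res$warnings, collapse = ";")
    }
  })
  est <- area_series(est_area, fs_hz = fs_hz,
                     camera_label = config$camera_label)
  est$warnings <- warn
  list(truth = area_series(truth_area, fs_hz = fs_hz,
                           camera_label = config$camera_label),
       estimate = est)
}

#' Ground-truth area series of a rendered sequence
#'
#' @param scenes a \code{\link{render_sequence}} result.
#' @param camera_label label carried into the series.
#' @return an \code{\link{area_series}} of the exact silhouette areas.
#' @export
ground_truth_series <- function(scenes, camera_label = "frontal") {
  stopifnot(inherits(scenes, "pool_scene_sequence"))
  area_series(vapply(scenes, function(s) s$truth$area_pixels, integer(1)),
              fs_hz = attr(scenes, "fs_hz"), camera_label = camera_label)
}
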