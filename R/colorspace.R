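# Colour-space conversions the segmentation masks operate on.
#
# Frames are H x W x 3 numeric arrays with channel values in [0, 255]
# (R, G, B). Lab frames are H x W x 3 double arrays with channels
# L (0-100), a and b (unclipped floats, practically within [-128, 127]).

# sRGB (IEC 61966-2-1) linear-RGB -> XYZ matrix, D65 reference white.
.SRGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.D65_WHITE <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.validate_frame <- function(frame, arg = "frame") {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop(arg, " must be an H x W x 3 array of RGB values in [0, 255]")
  d <- dim(frame)
  if (d[1] < 1L || d[2] < 1L || any(d == 0L))
    stop(arg, " has an empty raster (", d[1], " x ", d[2], ")")
  rng <- range(frame)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(arg, " has channel values outside [0, 255]")
  invisible(frame)
}

#' Convert an RGB frame to CIELAB
#'
#' Standard sRGB decoding (gamma companding) followed by the XYZ and CIELAB
#' transforms with the D65 reference white
#' (X, Y, Z) = (0.95047, 1, 1.08883). L is on the 0-100 scale, so colour
#' thresholds quoted on that scale apply verbatim; use
#' \code{\link{normalize_lightness}} for the 0-255 L* scale.
#'
#' @param frame H x W x 3 numeric array, channel values in [0, 255].
#' @return H x W x 3 double array with channels L, a, b.
#' @examples
#' f <- array(c(27, 131, 135), dim = c(1, 1, 3))
#' rgb_to_lab(f)[1, 1, ]  # the chest replacement colour, roughly (50, -26, -10)
#' @export
rgb_to_lab <- function(frame) {
  .validate_frame(frame)
  d <- dim(frame)
  v <- as.numeric(frame) / 255
  # inverse sRGB companding
  lin <- v / 12.92
  hi <- v > 0.04045
  lin[hi] <- ((v[hi] + 0.055) / 1.055)^2.4
  rgb <- matrix(lin, ncol = 3L)           # N x 3, columns R, G, B
  xyz <- rgb %*% t(.SRGB2XYZ)
  xyz <- sweep(xyz, 2L, .D65_WHITE, "/")
  eps <- (6 / 29)^3
  f <- xyz / (3 * (6 / 29)^2) + 4 / 29
  hi <- xyz > eps
  f[hi] <- xyz[hi]^(1 / 3)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  array(c(L, a, b), dim = d)
}

#' Normalize the L channel to the 0-255 L* scale
#'
#' Affine map L* = L * 255 / 100, the scale on which the water-removal
#' interval 5 < L* < 160 is expressed.
#'
#' @param lab H x W x 3 Lab array from \code{\link{rgb_to_lab}}.
#' @return H x W double matrix of L* values in [0, 255].
#' @export
normalize_lightness <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("lab must be an H x W x 3 CIELAB array")
  lab[, , 1L, drop = TRUE] * 255 / 100
}

#' Convert an RGB frame to 8-bit grayscale
#'
#' ITU-R BT.601 luma weights (0.2989 R + 0.5870 G + 0.1140 B), rounded half
#' away from zero to integers in [0, 255]. Gray inputs map to themselves.
#'
#' @param frame H x W x 3 numeric array, channel values in [0, 255].
#' @return H x W integer matrix in [0, 255].
#' @export
rgb_to_gray <- function(frame) {
  .validate_frame(frame)
  y <- 0.2989 * frame[, , 1L] + 0.5870 * frame[, , 2L] + 0.1140 * frame[, , 3L]
  g <- floor(y + 0.5)  # values are non-negative, so this is half away from zero
  storage.mode(g) <- "integer"
  g
}
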