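# Steady-state resistive-force model and the Newtonian force balance used
# in active-drag analyses of swimming.

#' Drag-model parameters
#'
#' @param c_r dimensionless resistive-force coefficient (from a velocity
#'   perturbation protocol or the literature).
#' @param rho water density in kg/m^3 (default 1000).
#' @param pixel_scale_mm2 optional image scale in mm^2 per pixel (e.g. a
#'   calibrated value of about 6.23 mm^2/px), used to convert pixel areas
#'   to m^2.
#' @return An object of class \code{drag_params}.
#' @export
drag_params <- function(c_r, rho = 1000, pixel_scale_mm2 = NULL) {
  stopifnot(is.numeric(c_r), length(c_r) == 1L, is.finite(c_r))
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.null(pixel_scale_mm2) && pixel_scale_mm2 <= 0)
    stop("pixel_scale_mm2 must be > 0 when given")
  structure(list(c_r = c_r, rho = rho, pixel_scale_mm2 = pixel_scale_mm2),
            class = "drag_params")
}

#' Quadratic resistive force
#'
#' F_R = 1/2 * C_R * A * rho * v^2: the steady-state drag acting on a
#' projected area A (m^2) moving at speed v (m/s) through water of density
#' rho. Vectorized over area and velocity.
#'
#' @param params a \code{\link{drag_params}}.
#' @param area_m2 projected area in m^2 (>= 0).
#' @param velocity_mps speed in m/s.
#' @return force in newtons.
#' @export
resistive_force <- function(params, area_m2, velocity_mps) {
  stopifnot(inherits(params, "drag_params"))
  if (any(area_m2 < 0)) stop("area_m2 must be >= 0")
  0.5 * params$c_r * area_m2 * params$rho * velocity_mps^2
}

#' Convert a pixel area to square metres
#'
#' @param area_pixels pixel count (>= 0), vectorized.
#' @param pixel_scale_mm2 mm^2 per pixel (> 0).
#' @return area in m^2.
#' @export
pixels_to_m2 <- function(area_pixels, pixel_scale_mm2) {
  if (!is.numeric(pixel_scale_mm2) || pixel_scale_mm2 <= 0)
    stop("pixel_scale_mm2 must be > 0")
  area_pixels * pixel_scale_mm2 * 1e-6
}

#' Acceleration from the propulsive/resistive force balance
#'
#' m * a = F_P + F_R with F_R entered as a signed quantity (negative when
#' it opposes forward motion); when F_P = -F_R the swimmer holds constant
#' speed.
#'
#' @param mass_kg swimmer mass in kg (> 0).
#' @param f_p propulsive force in N.
#' @param f_r resistive force in N, signed.
#' @return acceleration in m/s^2.
#' @export
net_force_acceleration <- function(mass_kg, f_p, f_r) {
  if (!is.numeric(mass_kg) || mass_kg <= 0) stop("mass_kg must be > 0")
  (f_p + f_r) / mass_kg
}
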