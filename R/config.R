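# Experiment description objects: lightweight validated lists.  All
# constructors check invariants up front so downstream numerics can assume
# sane inputs.

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (positive && !allow_zero && x <= 0)
    stop_invalid("'%s' must be > 0 (got %g)", name, x)
  if (positive && allow_zero && x < 0)
    stop_invalid("'%s' must be >= 0 (got %g)", name, x)
  x
}

#' Capillary-tube experiment geometry
#'
#' Physical layout of one capillary diffusion experiment.  Defaults match
#' the standard setup: borosilicate tubes of 600 um inner diameter filled
#' with 30 mm of hydrogel and 10 mm of protein solution, imaged over a
#' 3 mm field of view starting at the protein--hydrogel interface.
#'
#' @param inner_diameter Tube inner diameter, um.
#' @param hydrogel_length Length of the hydrogel plug, mm.
#' @param reservoir_length Length of the protein reservoir, mm.
#' @param field_of_view Imaged axial extent of the gel, mm.  Must not
#'   exceed `hydrogel_length`.
#' @return An object of class `"tube_geometry"`.
#' @examples
#' tube_geometry()
#' @export
tube_geometry <- function(inner_diameter = 600, hydrogel_length = 30,
                          reservoir_length = 10, field_of_view = 3) {
  check_scalar(inner_diameter, "inner_diameter")
  check_scalar(hydrogel_length, "hydrogel_length")
  check_scalar(reservoir_length, "reservoir_length")
  check_scalar(field_of_view, "field_of_view")
  if (field_of_view > hydrogel_length)
    stop_invalid("field_of_view (%g mm) exceeds hydrogel_length (%g mm)",
                 field_of_view, hydrogel_length)
  structure(list(inner_diameter = inner_diameter,
                 hydrogel_length = hydrogel_length,
                 reservoir_length = reservoir_length,
                 field_of_view = field_of_view),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat("Capillary tube geometry\n")
  cat(sprintf("  inner diameter : %g um\n", x$inner_diameter))
  cat(sprintf("  hydrogel length: %g mm\n", x$hydrogel_length))
  cat(sprintf("  reservoir      : %g mm\n", x$reservoir_length))
  cat(sprintf("  field of view  : %g mm\n", x$field_of_view))
  invisible(x)
}

#' Image acquisition settings
#'
#' Describes how the synthetic microscope renders a capillary experiment.
#' Defaults emulate a 2 h time series: 31 frames at 4-min intervals over a
#' 3 mm field at 2.5 um/px with a 16-bit detector.  The reservoir occupies
#' `reservoir_pixels` columns at the left edge of each frame; the
#' protein--hydrogel interface sits at their right edge.
#'
#' @param pixel_size Pixel pitch, um per pixel.
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames (>= 2).
#' @param bit_depth Detector bit depth (8 or 16).
#' @param reservoir_pixels Width of the rendered reservoir region, px (>= 1).
#' @param background_level Dark background as a fraction of the reservoir
#'   intensity, in `[0, 1)`.
#' @param reservoir_fraction Fraction of detector full scale at which the
#'   reservoir renders (headroom keeps additive noise unclipped).
#' @param margin_px Dark rows rendered above and below the tube.
#' @return An object of class `"imaging_config"`.
#' @examples
#' imaging_config()
#' @export
imaging_config <- function(pixel_size = 2.5, frame_interval = 240,
                           n_frames = 31, bit_depth = 16,
                           reservoir_pixels = 200, background_level = 0.005,
                           reservoir_fraction = 0.85, margin_px = 8) {
  check_scalar(pixel_size, "pixel_size")
  check_scalar(frame_interval, "frame_interval")
  if (!is.numeric(n_frames) || n_frames < 2 || n_frames != round(n_frames))
    stop_invalid("'n_frames' must be an integer >= 2")
  if (!bit_depth %in% c(8L, 16L))
    stop_invalid("'bit_depth' must be 8 or 16")
  if (!is.numeric(reservoir_pixels) || reservoir_pixels < 1 ||
      reservoir_pixels != round(reservoir_pixels))
    stop_invalid("'reservoir_pixels' must be an integer >= 1")
  check_scalar(background_level, "background_level", allow_zero = TRUE)
  if (background_level >= 1)
    stop_invalid("'background_level' must be < 1")
  check_scalar(reservoir_fraction, "reservoir_fraction")
  if (reservoir_fraction > 1)
    stop_invalid("'reservoir_fraction' must be <= 1")
  check_scalar(margin_px, "margin_px", allow_zero = TRUE)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 bit_depth = as.integer(bit_depth),
                 reservoir_pixels = as.integer(reservoir_pixels),
                 background_level = background_level,
                 reservoir_fraction = reservoir_fraction,
                 margin_px = as.integer(margin_px)),
            class = "imaging_config")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat("Imaging configuration\n")
  cat(sprintf("  %d frames every %g s, %g um/px, %d-bit\n",
              x$n_frames, x$frame_interval, x$pixel_size, x$bit_depth))
  cat(sprintf("  reservoir region %d px, background %.3f, headroom %.2f\n",
              x$reservoir_pixels, x$background_level, x$reservoir_fraction))
  invisible(x)
}

#' Detector noise model
#'
#' Additive Gaussian read noise plus optional Poisson shot noise for the
#' synthetic renderer.  `gaussian_sigma` is the read-noise standard
#' deviation expressed as a fraction of the reservoir intensity;
#' `poisson_scale` is the expected photon count per unit normalized
#' intensity (0 disables shot noise).  The `seed` makes stacks
#' bit-reproducible.
#'
#' @param gaussian_sigma Additive noise s.d., fraction of reservoir
#'   intensity (>= 0).
#' @param poisson_scale Photons per unit normalized intensity (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `"noise_model"`.
#' @examples
#' noise_model(gaussian_sigma = 0.01, seed = 42)
#' @export
noise_model <- function(gaussian_sigma = 0.01, poisson_scale = 0, seed = 1L) {
  check_scalar(gaussian_sigma, "gaussian_sigma", allow_zero = TRUE)
  check_scalar(poisson_scale, "poisson_scale", allow_zero = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("'seed' must be a single integer")
  structure(list(gaussian_sigma = gaussian_sigma,
                 poisson_scale = poisson_scale,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Concentration-to-intensity saturation map
#'
#' Fluorescence intensity is proportional to concentration only at low
#' concentration; above roughly 25% of the reservoir concentration the
#' response flattens (self-quenching / inner-filter effects).  The map is
#' the identity below `linear_limit` and a smooth compressive law above,
#' with continuous value and slope at the knee:
#' \deqn{I(c) = a + (1-a)\,\frac{1 - e^{-\gamma u}}{\gamma}, \quad
#'       u = \frac{c - a}{1 - a}, \; c > a}
#' where \eqn{a} is `linear_limit` and \eqn{\gamma} is `compression`.
#' Larger `compression` flattens the response harder; as
#' \eqn{\gamma \to 0} the map tends to the identity.
#'
#' @param enabled Apply the nonlinearity?  When `FALSE` the map is the
#'   identity everywhere.
#' @param linear_limit Normalized concentration below which the response is
#'   strictly linear, in (0, 1].
#' @param compression Curvature of the compressive branch (> 0).
#' @return An object of class `"saturation_map"`.
#' @examples
#' sat <- saturation_map(enabled = TRUE)
#' intensity_map(c(0.1, 0.5, 1), sat)
#' @export
saturation_map <- function(enabled = FALSE, linear_limit = 0.25,
                           compression = 1) {
  if (!is.logical(enabled) || length(enabled) != 1L || is.na(enabled))
    stop_invalid("'enabled' must be TRUE or FALSE")
  check_scalar(linear_limit, "linear_limit")
  if (linear_limit > 1) stop_invalid("'linear_limit' must be in (0, 1]")
  check_scalar(compression, "compression")
  structure(list(enabled = enabled, linear_limit = linear_limit,
                 compression = compression),
            class = "saturation_map")
}

#' Finite-difference grid specification
#'
#' Space/time discretization for [solve_diffusion_fd()].  Crank-Nicolson is
#' unconditionally stable, so the only constraints are positivity and an
#' accuracy guard on the diffusion number \eqn{r = D\,\Delta t/\Delta x^2}.
#'
#' @param dx Spatial step, cm (default 10 um).
#' @param dt Time step, s.
#' @param domain_length Solved axial extent, cm; `NULL` takes the hydrogel
#'   length from the geometry.
#' @param max_diffusion_number Accuracy guard: solving errors out if
#'   \eqn{D\,\Delta t/\Delta x^2} exceeds this.
#' @return An object of class `"grid_spec"`.
#' @examples
#' grid_spec()
#' @export
grid_spec <- function(dx = 10e-4, dt = 1, domain_length = NULL,
                      max_diffusion_number = 500) {
  check_scalar(dx, "dx")
  check_scalar(dt, "dt")
  if (!is.null(domain_length)) check_scalar(domain_length, "domain_length")
  check_scalar(max_diffusion_number, "max_diffusion_number")
  structure(list(dx = dx, dt = dt, domain_length = domain_length,
                 max_diffusion_number = max_diffusion_number),
            class = "grid_spec")
}

#' Observation filtering rules for the fit
#'
#' Points near the reservoir violate the model's assumptions twice over:
#' the concentration-intensity response is nonlinear above ~25% of the
#' reservoir concentration, and positions close to the interface are most
#' sensitive to interface-location error.  The fit therefore keeps only
#' observations with normalized fluorescence `F < max_f` and distance
#' `x > min_x` from the interface.
#'
#' @param max_f Normalized intensity ceiling, in (0, 1] (default 0.25).
#' @param min_x Minimum distance from the interface, cm (default 0.05 cm
#'   = 0.5 mm).
#' @param min_points Minimum number of surviving observations (>= 10).
#' @return An object of class `"filter_spec"`.
#' @examples
#' filter_spec()
#' @export
filter_spec <- function(max_f = 0.25, min_x = 0.05, min_points = 10L) {
  check_scalar(max_f, "max_f")
  if (max_f > 1) stop_invalid("'max_f' must be in (0, 1]")
  check_scalar(min_x, "min_x", allow_zero = TRUE)
  if (!is.numeric(min_points) || min_points < 10)
    stop_invalid("'min_points' must be >= 10")
  structure(list(max_f = max_f, min_x = min_x,
                 min_points = as.integer(min_points)),
            class = "filter_spec")
}

# internal: μm→cm and mm→cm conversions kept in one place
um_to_cm <- function(x) x * 1e-4
mm_to_cm <- function(x) x * 1e-1
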