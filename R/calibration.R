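#' Rayleigh surface-wave constant
#'
#' For an unstressed, incompressible, linear elastic, isotropic half-space
#' the Young modulus and the Rayleigh surface-wave speed are related by
#' `E = rho * v^2 * 3.284`. This constant converts between arrival-time
#' measurements and skin stiffness.
#'
#' @format A single number, 3.284 (dimensionless).
#' @export
rayleigh_constant <- 3.284

#' Rayleigh wave speed of a calibration material
#'
#' Inverts the Rayleigh relation `E = rho v^2 * 3.284` to obtain the surface
#' wave speed from tensile-test stiffness and density.
#'
#' @param density Material density, kg/m^3.
#' @param young_modulus Young modulus, Pa.
#' @return Wave speed in m/s (vectorized).
#' @export
rayleigh_speed <- function(density, young_modulus) {
  if (any(density <= 0) || any(young_modulus <= 0)) {
    stop("density and Young modulus must be positive.", call. = FALSE)
  }
  sqrt(young_modulus / (rayleigh_constant * density))
}

#' RRT-to-microseconds conversion for a calibration material
#'
#' The device reports arrival times in arbitrary RRT units. Given a material
#' of known density and stiffness and its mean measured RRT, the physical
#' duration of one RRT unit is the transducer-gap transit time at the
#' material's Rayleigh speed divided by the mean RRT reading.
#'
#' @inheritParams rayleigh_speed
#' @param mean_rrt Mean measured arrival time for the material, RRT units.
#' @param gap Transducer separation in metres (protocol value 2 mm).
#' @return Microseconds per RRT unit (vectorized).
#' @export
rrt_conversion <- function(density, young_modulus, mean_rrt, gap = 0.002) {
  if (any(mean_rrt <= 0) || any(gap <= 0)) {
    stop("mean_rrt and gap must be positive.", call. = FALSE)
  }
  v <- rayleigh_speed(density, young_modulus)
  (gap / v) * 1e6 / mean_rrt
}

#' Stiffness from an arrival-time reading
#'
#' Converts an RRT arrival time to a Young modulus: the reading times the
#' material conversion gives the transit time, the transducer gap over that
#' time gives the wave speed, and the Rayleigh relation gives the stiffness.
#'
#' @param arrival_rrt Arrival time, RRT units.
#' @param conversion_us Microseconds per RRT (e.g. from [rrt_conversion()]).
#' @param density Density of the medium, kg/m^3.
#' @param gap Transducer separation in metres.
#' @return Young modulus in Pa (vectorized).
#' @export
stiffness_from_rrt <- function(arrival_rrt, conversion_us, density,
                               gap = 0.002) {
  if (any(arrival_rrt <= 0) || any(conversion_us <= 0) || any(density <= 0) ||
      any(gap <= 0)) {
    stop("all inputs must be positive.", call. = FALSE)
  }
  t_s <- arrival_rrt * conversion_us * 1e-6
  v <- gap / t_s
  density * v^2 * rayleigh_constant
}

#' Bundled calibration materials
#'
#' The three elastomers used to calibrate RRT units to physical time:
#' Techsil 25 Silicone, Polyurethane and MVQ Elastomer, with tensile-test
#' Young moduli, densities and mean RRT readings.
#'
#' @return A tibble with columns `name`, `density_kg_m3`, `young_modulus_pa`,
#'   `mean_rrt`.
#' @export
calibration_materials <- function() {
  path <- system.file("extdata", "calibration_materials.csv",
                      package = "skinaniso", mustWork = TRUE)
  readr::read_csv(path, col_types = "cddd")
}

#' Calibration table
#'
#' Computes the Rayleigh speed and the RRT-to-microsecond conversion for each
#' material, plus the mean conversion across materials (the working value
#' used to interpret skin readings; approximately 0.284 microseconds per
#' RRT for the bundled materials).
#'
#' @param materials A materials tibble, by default [calibration_materials()].
#' @param gap Transducer separation in metres.
#' @return A tibble with the input columns plus `speed_m_s` and
#'   `conversion_us`, carrying the mean conversion as attribute
#'   `"mean_conversion_us"`.
#' @export
calibration_table <- function(materials = calibration_materials(),
                              gap = 0.002) {
  out <- materials
  out$speed_m_s <- rayleigh_speed(out$density_kg_m3, out$young_modulus_pa)
  out$conversion_us <- rrt_conversion(out$density_kg_m3, out$young_modulus_pa,
                                      out$mean_rrt, gap = gap)
  attr(out, "mean_conversion_us") <- mean(out$conversion_us)
  out
}
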