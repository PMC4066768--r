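#' Physical constants and unit conventions
#'
#' All energies in the package are in kcal/mol, angles in degrees (unless a
#' function documents radians), distances in Angstrom, and rod-level stiffness
#' constants in nanometres. `kB_kcal` is the Boltzmann constant in
#' kcal mol^-1 K^-1; at the default simulation temperature of 300 K,
#' `kB_kcal * 300` is 0.59616 kcal/mol.
#'
#' @format `kB_kcal` is a length-one numeric.
#' @export
kB_kcal <- 0.0019872041

#' @rdname kB_kcal
#' @format `default_temperature` is 300 (kelvin).
#' @export
default_temperature <- 300

# canonical angle scale for non-dimensionalization: one helical turn (360 deg)
# over the canonical B-DNA repeat of 34 Angstrom, i.e. 10.588 deg per Angstrom
# of helical rise -- conventionally printed as 10.6 deg.
#' Default non-dimensionalization scales
#'
#' The conventional angle scale used to make angular and translational
#' rigid-base coordinates dimensionally comparable: 360/34 degrees
#' (approximately 10.6 degrees), paired with a length scale of 1 Angstrom.
#'
#' @return Numeric scalar, degrees.
#' @examples
#' round(default_angle_scale(), 1)  # 10.6
#' @export
default_angle_scale <- function() 360 / 34

#' @rdname default_angle_scale
#' @export
default_length_scale <- function() 1
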