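#' Non-dimensionalize a rigid-base model
#'
#' Rescales every coordinate by its scale -- distances by `length_scale`
#' (default 1 Angstrom) and angles by `angle_scale` (default 360/34, about
#' 10.6 degrees, one degree of helical twist per canonical B-DNA rise) -- so
#' that the entries of the stiffness and covariance matrices become
#' dimensionally uniform and the matrix can be analysed as a whole (e.g. via
#' [conformational_entropy]). For the diagonal scale matrix S the transforms
#' are w' = S^-1 w, C' = S^-1 C S^-1 and K' = S K S, which leaves every
#' deformation energy unchanged.
#'
#' @param model A [rigid_base_model] in native units.
#' @param length_scale Angstrom per non-dimensional unit (default 1).
#' @param angle_scale Degrees per non-dimensional unit (default 360/34).
#' @param invert Undo a previous application with the same scales.
#' @return The rescaled model; `model$scaling` records the scales.
#' @export
nondimensionalize <- function(model, length_scale = default_length_scale(),
                              angle_scale = default_angle_scale(),
                              invert = FALSE) {
  stopifnot(inherits(model, "rigid_base_model"))
  stopifnot_scalar_number(length_scale, "length_scale")
  stopifnot_scalar_number(angle_scale, "angle_scale")
  if (!invert && !is.null(model$scaling))
    stop("model is already non-dimensionalized; refusing to rescale twice", call. = FALSE)
  if (invert && is.null(model$scaling))
    stop("model is not scaled; nothing to invert", call. = FALSE)
  s <- ifelse(model$schema$unit == "degree", angle_scale, length_scale)
  if (invert) s <- 1 / s
  model$w_hat <- model$w_hat / s
  model$C <- symmetrize(model$C / outer(s, s))
  model$K <- symmetrize(model$K * outer(s, s))
  model$scaling <- if (invert) NULL else
    list(length_scale = length_scale, angle_scale = angle_scale)
  model
}
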