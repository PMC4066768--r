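#' Fit the non-local interacting-rigid-base model
#'
#' Fits a harmonic (multivariate Gaussian) model to an ensemble of rigid-base
#' coordinates. The deformation energy is
#' \deqn{E(w) = \tfrac12 (w - \hat w) \cdot K (w - \hat w)}
#' with shape vector \eqn{\hat w} equal to the coordinate means and stiffness
#' matrix \eqn{K = k_B T C^{-1}}, the thermally scaled inverse of the full
#' coordinate covariance \eqn{C}. Because the whole covariance is inverted,
#' every base can couple to every other base: the model is non-local, unlike
#' dinucleotide-step models which keep only 6 x 6 blocks.
#'
#' @param traj A [coord_trajectory] (already filtered; see
#'   [filter_snapshots]). The snapshot count must exceed the coordinate count
#'   N, otherwise the sample covariance is singular by construction.
#' @param temperature Bath temperature in kelvin (default 300).
#' @param unbiased Use the M - 1 covariance denominator instead of the
#'   maximum-likelihood M (default `FALSE`: the Gaussian moment relations
#'   equate population moments, so ML normalization is the natural choice;
#'   at the usual M of 10^4 or more the difference is negligible).
#' @return An object of class `rigid_base_model` with elements `schema`,
#'   `w_hat` (length-N shape vector, native units), `K` (N x N stiffness,
#'   kcal/mol per unit^2), `C` (covariance, unit^2), `temperature`, `M`
#'   (snapshots used) and `scaling` (`NULL` until [nondimensionalize] is
#'   applied).
#' @seealso [deformation_energy], [relax], [conformational_entropy],
#'   [force_constant], [simulate.rigid_base_model]
#' @examples
#' gt <- ground_truth_model("GCGAT")
#' tr <- simulate(gt, nsim = 2000, seed = 1)
#' m <- rigid_base_model(tr)
#' m
#' @export
rigid_base_model <- function(traj, temperature = default_temperature,
                             unbiased = FALSE) {
  schema <- schema_of(traj)
  M <- nrow(traj)
  if (M <= schema$N)
    stop(sprintf(paste0(
      "insufficient samples: M = %d snapshots for N = %d coordinates; ",
      "the sample covariance is singular unless M > N"), M, schema$N), call. = FALSE)
  X <- unclass(traj)
  w_hat <- colMeans(X)
  C <- cov_ml(X, unbiased = unbiased)
  K <- symmetrize(kB_kcal * temperature * spd_inverse(C))
  new_rigid_base_model(schema, w_hat, K, C, temperature, M = M)
}

new_rigid_base_model <- function(schema, w_hat, K, C, temperature, M = NA_integer_,
                                 scaling = NULL, class = character()) {
  dimnames(K) <- list(schema$name, schema$name)
  dimnames(C) <- list(schema$name, schema$name)
  names(w_hat) <- schema$name
  structure(list(schema = schema, w_hat = w_hat, K = K, C = C,
                 temperature = temperature, M = M, scaling = scaling),
            class = c(class, "rigid_base_model"))
}

#' @export
print.rigid_base_model <- function(x, ...) {
  s <- x$schema
  cat(sprintf("Non-local rigid-base model: %d bp, N = %d coordinates, T = %g K\n",
              s$n, s$N, x$temperature))
  if (!is.na(x$M)) cat(sprintf("  fitted from %d snapshots\n", x$M))
  if (!is.null(x$scaling))
    cat(sprintf("  non-dimensionalized (length scale %g Angstrom, angle scale %.4g degrees)\n",
                x$scaling$length_scale, x$scaling$angle_scale))
  invisible(x)
}

#' @export
summary.rigid_base_model <- function(object, ...) {
  s <- object$schema
  ent <- if (is.null(object$scaling)) NULL else conformational_entropy(object)
  out <- list(
    n = s$n, N = s$N, M = object$M, temperature = object$temperature,
    scaling = object$scaling,
    mean_diag_stiffness = mean(diag(object$K)),
    entropy = ent
  )
  class(out) <- "summary.rigid_base_model"
  out
}

#' @export
print.summary.rigid_base_model <- function(x, ...) {
  cat(sprintf("Rigid-base model: %d bp (N = %d), T = %g K", x$n, x$N, x$temperature))
  if (!is.na(x$M)) cat(sprintf(", M = %d snapshots", x$M))
  cat("\n")
  cat(sprintf("  mean diagonal stiffness: %.4g kcal/mol per unit^2\n", x$mean_diag_stiffness))
  if (!is.null(x$entropy))
    cat(sprintf("  conformational entropy per coordinate s_c: %.5g kcal/(mol K); T*s_c = %.4g kcal/mol\n",
                x$entropy$s_c, x$entropy$s_c * x$temperature))
  invisible(x)
}

#' @export
coef.rigid_base_model <- function(object, ...) object$w_hat

#' @export
vcov.rigid_base_model <- function(object, ...) object$C

#' Harmonic deformation energy of a coordinate vector
#'
#' Evaluates \eqn{E(w) = \tfrac12 (w - \hat w) \cdot K (w - \hat w)}, the
#' energy in kcal/mol required to distort the coordinates away from the shape
#' vector. `w` may be a vector or a matrix with one configuration per row.
#'
#' @param model A [rigid_base_model] (full or relaxed).
#' @param w Coordinate vector(s) in the model's units and ordering.
#' @return Energy (kcal/mol), one value per configuration; non-negative.
#' @export
deformation_energy <- function(model, w) {
  stopifnot(inherits(model, "rigid_base_model"))
  W <- if (is.matrix(w)) w else matrix(w, nrow = 1L)
  if (ncol(W) != length(model$w_hat))
    stop(sprintf("dimension mismatch: model has %d coordinates, `w` has %d",
                 length(model$w_hat), ncol(W)), call. = FALSE)
  D <- sweep(W, 2L, model$w_hat)
  e <- 0.5 * rowSums((D %*% model$K) * D)
  if (is.matrix(w)) e else e[[1]]
}

#' Residual displacements of a trajectory about the model shape
#'
#' @param object A [rigid_base_model].
#' @param traj A [coord_trajectory] over the same schema.
#' @param ... Unused.
#' @return M x N matrix of displacements `w - w_hat`.
#' @export
residuals.rigid_base_model <- function(object, traj, ...) {
  if (missing(traj)) stop("supply the trajectory whose residuals are wanted", call. = FALSE)
  sweep(unclass(traj), 2L, object$w_hat)
}

#' Diagonal stiffness profile plot
#'
#' Plots the diagonal stiffness constants of one coordinate along the duplex
#' (the stiffness of distorting that coordinate while all others are held
#' fixed), the standard sequence-resolved view of a rigid-base model.
#'
#' @param x A [rigid_base_model].
#' @param coord Coordinate name (default `"twist"`).
#' @param ... Passed to [graphics::plot].
#' @export
plot.rigid_base_model <- function(x, coord = "twist", ...) {
  idx <- coord_index(x$schema, coord)
  k <- diag(x$K)[idx]
  pos <- x$schema$index[idx]
  unit <- x$schema$unit[idx][1]
  graphics::plot(pos, k, type = "b", pch = 16,
                 xlab = if (coord %in% step_coord_names()) "step" else "base pair",
                 ylab = sprintf("diagonal stiffness (kcal/mol per %s^2)", unit),
                 main = coord, ...)
  invisible(x)
}
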