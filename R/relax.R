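#' Partially relaxed (marginal) model over a coordinate subset
#'
#' Constraining a subset A of coordinates while letting the rest relax to
#' their energy minimum yields an effective quadratic energy
#' \deqn{\tilde E(w_A) = \tfrac12 (w_A - \hat w_A) \cdot \tilde K (w_A - \hat w_A)}
#' with \eqn{\tilde K = k_B T \tilde C^{-1}}, where \eqn{\tilde C} is the
#' covariance submatrix of the constrained coordinates. Equivalently,
#' \eqn{\tilde K} is the Schur complement
#' \eqn{K_{AA} - K_{AB} K_{BB}^{-1} K_{BA}} of the full stiffness. Both
#' routes are computed and their agreement asserted; relaxation can only
#' soften, so no eigenvalue of \eqn{\tilde K} exceeds the corresponding
#' constrained (principal-submatrix) stiffness.
#'
#' The classical 6 x 6 dinucleotide-step stiffness is the special case where
#' A holds the six step coordinates of one step.
#'
#' @param model A [rigid_base_model].
#' @param subset Coordinate positions (integers into the canonical order) or
#'   coordinate names.
#' @param check_tol Relative tolerance for the covariance-vs-Schur agreement
#'   check (default 1e-8).
#' @return A `relaxed_rigid_base_model` (also a `rigid_base_model`): schema
#'   restricted to the subset, `w_hat` the subset means, `K` the relaxed
#'   stiffness; `subset` records the positions in the parent model.
#' @examples
#' m <- ground_truth_model("GCGCG")
#' step_twists <- relax(m, coord_index(m$schema, "twist"))
#' diag(step_twists$K)
#' @export
relax <- function(model, subset, check_tol = 1e-8) {
  stopifnot(inherits(model, "rigid_base_model"))
  A <- resolve_subset(model$schema, subset)
  N <- nrow(model$K)
  kBT <- kB_kcal * model$temperature
  # route 1: covariance submatrix
  K_cov <- symmetrize(kBT * spd_inverse(model$C[A, A, drop = FALSE],
                                        what = "constrained-coordinate covariance"))
  # route 2: Schur complement of the full stiffness
  B <- setdiff(seq_len(N), A)
  K_schur <- if (length(B) == 0L) {
    model$K
  } else {
    KBBinv_KBA <- solve(model$K[B, B, drop = FALSE], model$K[B, A, drop = FALSE])
    symmetrize(model$K[A, A, drop = FALSE] -
                 model$K[A, B, drop = FALSE] %*% KBBinv_KBA)
  }
  rel <- max(abs(K_cov - K_schur)) / max(abs(K_schur))
  if (rel > check_tol)
    stop(sprintf(paste0(
      "covariance-submatrix and Schur-complement relaxations disagree ",
      "(relative difference %.3g); the model is inconsistent or ill-conditioned"), rel),
      call. = FALSE)
  sub_schema <- subset_schema(model$schema, A)
  out <- new_rigid_base_model(sub_schema, model$w_hat[A], K_schur,
                              model$C[A, A, drop = FALSE], model$temperature,
                              M = model$M, scaling = model$scaling,
                              class = "relaxed_rigid_base_model")
  out$subset <- A
  out
}

resolve_subset <- function(schema, subset) {
  if (is.character(subset)) {
    A <- match(subset, schema$name)
    if (anyNA(A)) stop("unknown coordinate name(s): ",
                       paste(subset[is.na(A)], collapse = ", "), call. = FALSE)
  } else {
    A <- as.integer(subset)
    if (length(A) == 0L || anyNA(A) || any(A < 1L | A > schema$N))
      stop("subset indices must be a nonempty set within 1..N", call. = FALSE)
  }
  if (anyDuplicated(A)) stop("subset contains duplicate coordinates", call. = FALSE)
  A
}

# a reduced schema retaining the selected coordinates (order preserved)
subset_schema <- function(schema, A) {
  out <- list(n = schema$n, N = length(A), sequence = schema$sequence,
              name = schema$name[A], coord = schema$coord[A],
              index = schema$index[A], kind = schema$kind[A],
              unit = schema$unit[A], parent_N = schema$N)
  class(out) <- c("subset_schema", "coord_schema")
  out
}

#' @export
print.relaxed_rigid_base_model <- function(x, ...) {
  cat(sprintf("Partially relaxed rigid-base model: %d constrained coordinate(s), T = %g K\n",
              length(x$subset), x$temperature))
  cat("  constrained:", paste(utils::head(x$schema$name, 8), collapse = ", "),
      if (length(x$subset) > 8) "..." else "", "\n")
  invisible(x)
}

#' Single-coordinate force constant
#'
#' The force constant for imposing a displacement on one coordinate while
#' every other coordinate relaxes freely:
#' \eqn{K_a = k_B T / \mathrm{Var}(w_a)}, i.e. the 1 x 1 relaxed model of
#' that coordinate. It is always at most the corresponding diagonal entry of
#' the full stiffness (which constrains all other coordinates instead).
#'
#' @param model A [rigid_base_model].
#' @param coordinate One coordinate position or name.
#' @return Force constant, kcal/mol per unit^2.
#' @export
force_constant <- function(model, coordinate) {
  stopifnot(inherits(model, "rigid_base_model"))
  a <- resolve_subset(model$schema, coordinate)
  if (length(a) != 1L) stop("`coordinate` must name exactly one coordinate", call. = FALSE)
  v <- model$C[a, a]
  if (v <= 0) stop("zero variance for coordinate ", model$schema$name[a], call. = FALSE)
  kB_kcal * model$temperature / v
}
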