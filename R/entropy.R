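#' Conformational entropy of a harmonic ensemble
#'
#' For the N-dimensional Gaussian ensemble implied by a rigid-base model,
#' the Gibbs entropy has the closed form
#' \deqn{S_c = \tfrac12 k_B \ln[(2\pi e)^N \det C]}
#' evaluated here through the Cholesky log-determinant (the raw determinant
#' of a large covariance under- or overflows). The intensive entropy per
#' coordinate, \eqn{s_c = S_c / N}, allows oligomers of different lengths to
#' be compared; lower \eqn{s_c} means an overall stiffer molecule.
#'
#' Absolute entropies depend on the units of the coordinates, so models must
#' be [nondimensionalize]d before entropies of different models are compared.
#' With one common length scale and one common angle scale, differences of
#' \eqn{s_c} between models are invariant under rescaling.
#'
#' @param x A [rigid_base_model] or a covariance matrix.
#' @return List with `S_c` (kcal/(mol K)), `s_c` (= S_c/N) and `N`.
#' @examples
#' conformational_entropy(diag(2))  # two unit-variance coordinates
#' @export
conformational_entropy <- function(x) {
  C <- if (inherits(x, "rigid_base_model")) x$C else as.matrix(x)
  if (nrow(C) != ncol(C)) stop("covariance must be square", call. = FALSE)
  check_conditioning(C)
  N <- nrow(C)
  S_c <- 0.5 * kB_kcal * (N * log(2 * pi * exp(1)) + logdet_spd(C))
  list(S_c = S_c, s_c = S_c / N, N = N)
}
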