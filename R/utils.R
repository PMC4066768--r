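# Internal numerical helpers.

symmetrize <- function(M) (M + t(M)) / 2

# log-determinant of a symmetric positive definite matrix via Cholesky;
# never forms the raw determinant, so it cannot overflow for large N.
logdet_spd <- function(M) {
  R <- tryCatch(chol(M), error = function(e) {
    stop("matrix is not positive definite: ", conditionMessage(e), call. = FALSE)
  })
  2 * sum(log(diag(R)))
}

# Guard against (near-)singular covariances before inversion. Eigenvalues
# below rel_tol times the largest indicate directions with essentially no
# sampled fluctuation; inverting them would manufacture arbitrarily large
# stiffnesses, so we refuse and name the offending eigenvalue.
check_conditioning <- function(C, rel_tol = 1e-10, what = "covariance") {
  ev <- eigen(symmetrize(C), symmetric = TRUE, only.values = TRUE)$values
  if (ev[length(ev)] <= rel_tol * max(ev[1], .Machine$double.eps)) {
    stop(sprintf(
      "%s matrix is singular or near-singular: smallest eigenvalue %.6g (largest %.6g, relative tolerance %g)",
      what, ev[length(ev)], ev[1], rel_tol
    ), call. = FALSE)
  }
  invisible(ev)
}

# maximum-likelihood covariance (divide by M); `unbiased = TRUE` gives the
# usual M - 1 denominator.
cov_ml <- function(X, unbiased = FALSE) {
  X <- as.matrix(X)
  M <- nrow(X)
  if (M < 2L) stop("need at least 2 rows to estimate a covariance", call. = FALSE)
  C <- stats::cov(X)
  if (!unbiased) C <- C * (M - 1) / M
  symmetrize(C)
}

spd_inverse <- function(C, what = "covariance") {
  check_conditioning(C, what = what)
  symmetrize(chol2inv(chol(symmetrize(C))))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
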