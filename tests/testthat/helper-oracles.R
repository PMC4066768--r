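# Shared fixtures and independent oracles, built in code at test time.

# random symmetric positive definite matrix with a controlled condition number
random_spd <- function(N, cond = 50) {
  Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
  ev <- exp(seq(log(1), log(cond), length.out = N))
  Q %*% diag(ev, N) %*% t(Q)
}

# a hand-built rigid-base-like model over an arbitrary stiffness (kcal/mol
# units), using the first N canonical coordinates of a large-enough schema
toy_model <- function(K, w_hat = rep(0, nrow(K)), temperature = 300) {
  N <- nrow(K)
  n <- ceiling((N + 6) / 12) + 1
  schema <- dnamech:::subset_schema(coord_schema(n), seq_len(N))
  C <- kB_kcal * temperature * solve(K)
  dnamech:::new_rigid_base_model(schema, w_hat, (K + t(K)) / 2, (C + t(C)) / 2,
                                 temperature)
}

# brute-force partial relaxation: minimize the full quadratic over the free
# coordinates w_B with w_A clamped, via a numerical optimizer (independent of
# the Schur-complement algebra in relax())
brute_force_relaxed_energy <- function(model, A, wA) {
  N <- length(model$w_hat)
  B <- setdiff(seq_len(N), A)
  if (length(B) == 0L) return(deformation_energy(model, wA))
  obj <- function(wB) {
    w <- numeric(N); w[A] <- wA; w[B] <- wB
    deformation_energy(model, w)
  }
  grad <- function(wB) {
    w <- numeric(N); w[A] <- wA; w[B] <- wB
    (model$K %*% (w - model$w_hat))[B]
  }
  fit <- optim(model$w_hat[B], obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$value
}

# random well-clustered orientation frame: rotation by `spread`-bounded angle
# about a random axis, applied to a base rotation
random_frame <- function(base = diag(3), spread = 0.3) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -spread, spread)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  dna_frame(rnorm(3), base %*% R)
}

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")

expect_rel_equal <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}
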