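test_that("whitened data give K = kB T I and degenerate input errors are explicit", {
  set.seed(11)
  # two-coordinate trajectory whose ML covariance is exactly the identity
  Z <- matrix(rnorm(400), 200, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z) * (nrow(Z) - 1) / nrow(Z)))
  s <- coord_schema(2)
  # embed the exactly whitened block among otherwise iid columns
  X2 <- matrix(rnorm(200 * s$N), 200, s$N); X2[, 1:2] <- Z
  m <- rigid_base_model(coord_trajectory(X2, s))
  expect_equal(m$K[1:2, 1:2], kB_kcal * 300 * solve(m$C)[1:2, 1:2], tolerance = 1e-10)
  expect_equal(unname(m$C[1:2, 1:2]), diag(2), tolerance = 1e-10)

  # constant trajectory: conditioning error naming the eigenvalue
  Xc <- matrix(1, 50, s$N)
  expect_error(rigid_base_model(coord_trajectory(Xc, s)), "eigenvalue")
  # M <= N: insufficient samples
  expect_error(rigid_base_model(coord_trajectory(matrix(rnorm(10 * s$N), 10, s$N), s)),
               "insufficient samples")
})

test_that("estimation recovers a known 6-coordinate Gaussian stiffness", {
  set.seed(42)
  K0 <- random_spd(6, cond = 20) * 0.5
  gt <- toy_model(K0)
  tr <- simulate(gt, nsim = 1e5, seed = 7)
  m <- rigid_base_model(tr)
  expect_lt(rel_frob(m$K, gt$K), 0.05)
  # inversion consistency: K C = kB T I
  expect_lt(max(abs(m$K %*% m$C - kB_kcal * 300 * diag(6))), 1e-8 * max(abs(m$K %*% m$C)))
})

test_that("deformation energy is the closed-form quadratic with its symmetries", {
  kBT <- kB_kcal * 300
  m1 <- toy_model(matrix(kBT, 1, 1))        # K = 1 kBT/deg^2
  expect_equal(deformation_energy(m1, 2), 2 * kBT, tolerance = 1e-12)
  expect_equal(round(deformation_energy(m1, 2), 4), 1.1923)

  set.seed(5)
  K <- random_spd(8)
  m <- toy_model(K, w_hat = rnorm(8))
  expect_equal(deformation_energy(m, coef(m)), 0)
  for (i in 1:5) {
    d <- rnorm(8)
    expect_equal(deformation_energy(m, m$w_hat + d),
                 deformation_energy(m, m$w_hat - d), tolerance = 1e-12)
    expect_gte(deformation_energy(m, m$w_hat + d), 0)
  }
  expect_error(deformation_energy(m, rnorm(5)), "dimension mismatch")
})

test_that("relax agrees between covariance-submatrix and Schur paths and with brute force", {
  set.seed(21)
  for (rep in 1:5) {
    N <- sample(6:12, 1)
    m <- toy_model(random_spd(N), w_hat = rnorm(N))
    A <- sort(sample(N, 3))
    rel <- relax(m, A)   # internally asserts dual-path agreement at 1e-8
    # independent Schur computation
    B <- setdiff(seq_len(N), A)
    K_schur <- m$K[A, A] - m$K[A, B] %*% solve(m$K[B, B], m$K[B, A])
    expect_lt(rel_frob(rel$K, K_schur), 1e-10)
    # relaxation can only soften: eigenvalues bounded by the principal submatrix
    expect_true(all(eigen(m$K[A, A] - rel$K, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
    # brute-force constrained minimization oracle
    wA <- m$w_hat[A] + rnorm(3)
    expect_equal(deformation_energy(rel, wA),
                 brute_force_relaxed_energy(m, A, wA), tolerance = 1e-6)
  }
})

test_that("relax worked examples: 2x2 Schur value and the identity subset", {
  kBT <- kB_kcal * 300
  m <- toy_model(kBT * matrix(c(2, 1, 1, 2), 2))
  rel <- relax(m, 1)
  expect_equal(unname(rel$K[1, 1]) / kBT, 1.5, tolerance = 1e-12)
  all_rel <- relax(m, 1:2)
  expect_equal(unname(all_rel$K), unname(m$K), tolerance = 1e-12)
})

test_that("force constant is kB T over the variance and equals 1x1 relaxation", {
  kBT <- kB_kcal * 300
  # twist variance 25 deg^2
  C <- diag(c(25, 4))
  m <- toy_model(kBT * solve(C))
  expect_equal(force_constant(m, 1), 0.59616123 / 25, tolerance = 1e-6)
  expect_equal(round(force_constant(m, 1), 6), 0.023846)

  set.seed(33)
  for (rep in 1:4) {
    m <- toy_model(random_spd(7))
    a <- sample(7, 1)
    expect_equal(force_constant(m, a), unname(relax(m, a)$K[1, 1]), tolerance = 1e-10)
    # marginal (relaxed) never exceeds conditional (diagonal of K)
    expect_lte(force_constant(m, a), m$K[a, a] + 1e-12)
  }
})

test_that("conformational entropy: log-det path equals diagonal closed form", {
  # N = 1, unit variance
  e1 <- conformational_entropy(matrix(1, 1, 1))
  expect_equal(e1$S_c / kB_kcal, 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(round(e1$S_c / kB_kcal, 5), 1.41894)

  set.seed(9)
  sig2 <- exp(rnorm(12))
  e <- conformational_entropy(diag(sig2))
  closed <- 0.5 * kB_kcal * (12 * log(2 * pi * exp(1)) + sum(log(sig2)))
  expect_equal(e$S_c, closed, tolerance = 1e-10)
  expect_equal(e$s_c, e$S_c / 12)
  expect_error(conformational_entropy(diag(c(1, 0, 1))), "positive definite|singular")
})

test_that("entropy-per-coordinate differences are invariant under common rescaling", {
  set.seed(14)
  m1 <- ground_truth_model("GCGAT")
  m2 <- ground_truth_model("GAAAT")
  d0 <- conformational_entropy(nondimensionalize(m1))$s_c -
        conformational_entropy(nondimensionalize(m2))$s_c
  # any other single length scale + single angle scale must give the same difference
  d1 <- conformational_entropy(nondimensionalize(m1, length_scale = 2.7, angle_scale = 31))$s_c -
        conformational_entropy(nondimensionalize(m2, length_scale = 2.7, angle_scale = 31))$s_c
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("nondimensionalization round-trips, rejects double application, preserves energy", {
  m <- ground_truth_model("GCGCAT")
  nd <- nondimensionalize(m)
  expect_error(nondimensionalize(nd), "twice")
  back <- nondimensionalize(nd, invert = TRUE)
  expect_lt(rel_frob(back$K, m$K), 1e-12)
  expect_equal(back$w_hat, m$w_hat, tolerance = 1e-12)

  set.seed(3)
  s <- ifelse(m$schema$unit == "degree", default_angle_scale(), 1)
  for (i in 1:5) {
    d <- rnorm(m$schema$N)
    expect_equal(deformation_energy(nd, nd$w_hat + d / s),
                 deformation_energy(m, m$w_hat + d), tolerance = 1e-10)
  }
})

test_that("half-trajectory error: worked example, constant series, shrinkage with M", {
  out <- half_trajectory_error(mean, c(1, 1, 3, 3))
  expect_equal(out$value, 2)
  expect_equal(out$half_error, 1)

  expect_equal(half_trajectory_error(mean, rep(5, 20))$half_error, 0)

  # error shrinks with M in expectation (iid Gaussian)
  set.seed(8)
  err_at <- function(M) mean(replicate(40, half_trajectory_error(mean, rnorm(M))$half_error))
  expect_lt(err_at(400), err_at(25))

  # vector-valued statistic, component-wise errors
  X <- matrix(rnorm(80), 20, 4)
  out <- half_trajectory_error(colMeans, X)
  expect_length(out$half_error, 4)
  expect_true(all(out$half_error >= 0))
  expect_error(half_trajectory_error(mean, 1:3), "at least 4")
})

test_that("model archive and matrix export round-trip losslessly", {
  m <- ground_truth_model("GCAAT")
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  expect_equal(m2$w_hat, m$w_hat, tolerance = 1e-15)
  expect_equal(m2$K, m$K, tolerance = 1e-15)
  expect_equal(m2$temperature, m$temperature)
  expect_equal(m2$schema$name, m$schema$name)

  # relaxed models archive too
  rel <- relax(m, coord_index(m$schema, "twist"))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(rel, p2)
  rel2 <- read_model(p2)
  expect_equal(rel2$K, rel$K, tolerance = 1e-15)
  expect_equal(rel2$schema$name, rel$schema$name)

  p3 <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(m, p3, "K")
  K3 <- as.matrix(utils::read.table(p3, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(K3), unname(m$K), tolerance = 1e-6)
})
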