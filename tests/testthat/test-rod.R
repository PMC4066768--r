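test_that("total twist and contour length use half weights at boundary steps", {
  expect_equal(total_twist(c(30, 34, 36, 34, 30)), 134)
  expect_equal(contour_length(rep(3.3, 5)), 1.32)
  expect_equal(total_twist(rep(0, 6)), 0)
  # window selection and matrix input
  M <- rbind(c(30, 34, 36, 34, 30), c(30, 34, 36, 34, 30))
  expect_equal(total_twist(M, window = 2:4), c(70, 70))  # 17 + 36 + 17
  expect_error(total_twist(c(30, 34), window = 1), "at least 2")
})

test_that("fit_rod recovers means exactly and the diagonal closed form", {
  set.seed(51)
  rho <- rnorm(500, 0, 0.05); tau <- rnorm(500, 0, 0.08)
  omega <- rnorm(500, 6.0, 0.1); l <- rnorm(500, 4, 0.02)
  series <- data.frame(rho = rho, tau = tau, omega = omega, l = l)
  rod <- fit_rod(series)
  expect_equal(unname(coef(rod)), c(mean(rho), mean(tau), mean(omega)))
  expect_equal(rod$l0, mean(l))
  # diagonal closed form for twist: K_r[3,3] with the others marginalized
  vml <- function(x) mean((x - mean(x))^2)
  rel <- rod$l0 / vml(omega)
  expect_equal(twist_stiffness(rod), rel, tolerance = 0.02)
  expect_error(fit_rod(series[1:50, ]), "at least 100")
})

test_that("rod stiffness recovery from a known Gaussian", {
  K0 <- matrix(c(60, 5, 2,
                 5, 110, -3,
                 2, -3, 100), 3, 3)
  rod0 <- dnamech:::new_rod_model(c(0.05, -0.02, 6.1), K0, l0 = 4)
  draws <- simulate(rod0, nsim = 2e4, seed = 13)
  fit <- fit_rod(draws)
  expect_lt(rel_frob(fit$K_r, K0), 0.05)
  expect_equal(fit$l0, 4)
})

test_that("bending constants: worked harmonic means, isotropy, Schur dual path", {
  expect_equal(round(iso_bending_stiffness(65, 137)), 88)
  expect_equal(round(iso_bending_stiffness(49, 118)), 69)
  expect_equal(iso_bending_stiffness(80, 80), 80)

  set.seed(61)
  for (rep in 1:20) {
    K <- random_spd(3, cond = 10) * 50
    rod <- dnamech:::new_rod_model(c(0, 0, 6), K, l0 = 4)
    b <- bending_stiffness(rod)
    # a_iso between a_g and a_b
    expect_gte(b$a_iso, min(b$a_g, b$a_b) - 1e-12)
    expect_lte(b$a_iso, max(b$a_g, b$a_b) + 1e-12)
    # relaxed constants never exceed constrained counterparts
    expect_lte(b$a_g, K[1, 1] + 1e-12)
    expect_lte(b$a_b, K[2, 2] + 1e-12)
    expect_lte(twist_stiffness(rod), K[3, 3] + 1e-12)
    # twist: Schur path vs covariance-marginal path (l0 / var(omega))
    Cu <- rod$l0 * solve(K)
    expect_lt(abs(twist_stiffness(rod) - rod$l0 / Cu[3, 3]), 1e-10 * K[3, 3])
    # bending in any direction lies between a_g and a_b (off-diagonal removed
    # by eigen-bounds of the 2x2 form)
    ev <- eigen(b$K_bend, symmetric = TRUE, only.values = TRUE)$values
    for (ang in seq(0, pi, length.out = 13)) {
      u <- c(cos(ang), sin(ang))
      a_dir <- drop(u %*% b$K_bend %*% u)
      expect_gte(a_dir, min(ev) - 1e-12)
      expect_lte(a_dir, max(ev) + 1e-12)
    }
  }

  # diagonal K_r: constants are read off directly
  rodd <- dnamech:::new_rod_model(c(0, 0, 6), diag(c(60, 110, 95)), l0 = 4)
  expect_equal(twist_stiffness(rodd), 95)
  bd <- bending_stiffness(rodd)
  expect_equal(c(bd$a_g, bd$a_b), c(60, 110))
})

test_that("rod pipeline on synthetic frame trajectories recovers generating variances", {
  # straight-mean ground truth; bend/twist fluctuations propagate through
  # frame reconstruction -> mean frames -> global bend -> rod fit
  gt <- ground_truth_model("GCGCGATATGCGCG", coupling_strength = 0)
  tr <- simulate(gt, nsim = 3000, seed = 19)
  series <- rod_series(tr)
  rod <- fit_rod(series)
  expect_true(all(is.finite(unlist(rod[c("a_g", "a_b", "a_iso", "c_twist")]))))
  expect_gt(rod$a_iso, 0)
  # total-twist variance through the pipeline equals the direct coordinate sum
  s <- schema_of(tr)
  tw <- unclass(tr)[, coord_index(s, "twist")]
  omega_direct <- dnamech:::deg2rad(total_twist(tw, attr(series, "windows")$steps))
  expect_equal(stats::var(series$omega), stats::var(omega_direct), tolerance = 1e-12)
  # c_twist approximates l0 / var(omega) up to bend-twist coupling
  expect_equal(rod$c_twist, rod$l0 / stats::var(omega_direct) * (2999 / 3000),
               tolerance = 0.1)
})

test_that("rod report serializes derived constants", {
  rod <- dnamech:::new_rod_model(c(0.01, 0, 6.1), diag(c(70, 100, 110)), l0 = 3.4)
  p <- withr::local_tempfile(fileext = ".json")
  write_rod_report(rod, p, errors = list(a_iso = 1.2))
  doc <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(doc$a_iso_nm, iso_bending_stiffness(70, 100))
  expect_equal(doc$c_twist_nm, 110)
  expect_equal(doc$l0_nm, 3.4)
})
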