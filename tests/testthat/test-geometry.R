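test_that("mean_frame: identity cases, symmetry, and quaternion/SVD dual path", {
  f <- random_frame(spread = 0.2)
  m <- mean_frame(list(f, f, f))
  expect_equal(m$axes, f$axes, tolerance = 1e-10)
  expect_equal(m$origin, f$origin, tolerance = 1e-12)

  # two frames rotated +/- 20 degrees about a common axis, origins at +/-(1,0,0)
  rot_about_z <- function(a) dnamech:::rot_z(a)
  f1 <- dna_frame(c(1, 0, 0), rot_about_z(20 * pi / 180))
  f2 <- dna_frame(c(-1, 0, 0), rot_about_z(-20 * pi / 180))
  m <- mean_frame(list(f1, f2))
  expect_equal(m$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(m$axes, diag(3), tolerance = 1e-10)

  # quaternion eigen-average vs SVD projection of the summed matrices: the
  # two paths agree to machine precision for well-clustered orientations
  # (angle measured by the Frobenius metric, which is linear near zero,
  # rather than via acos of the trace, which cannot resolve below sqrt(eps))
  set.seed(17)
  ang_between <- function(spread) {
    frames <- replicate(6, random_frame(spread = spread), simplify = FALSE)
    mq <- mean_frame(frames, method = "quaternion")
    ms <- mean_frame(frames, method = "svd")
    norm(mq$axes - ms$axes, "F") / sqrt(2)
  }
  for (rep in 1:10) expect_lt(ang_between(0.5), 1e-10)

  # antipodal orientations are ambiguous
  g1 <- dna_frame(axes = diag(3))
  g2 <- dna_frame(axes = diag(c(-1, -1, 1)))   # 180 degrees about z
  expect_error(mean_frame(list(g1, g2)), "ambiguous")
})

test_that("global_bend satisfies the bend decomposition identity and conventions", {
  # parallel end z-axes: degenerate, direction flagged undefined
  b0 <- global_bend(dna_frame(), dna_frame(c(0, 0, 34)), dna_frame(c(0, 0, 17)))
  expect_equal(b0$theta, 0)
  expect_false(b0$phi_defined)
  expect_equal(c(b0$rho, b0$tau), c(0, 0))

  # bending toward the middle-frame major groove (+x) gives phi = 0:
  # the end tangents tip symmetrically in the x-z plane toward +x
  Ry <- function(a) dnamech:::rot_y(a)
  e1 <- dna_frame(axes = Ry(-0.1))
  e2 <- dna_frame(c(0, 0, 30), Ry(0.1))
  mid <- dna_frame(c(0, 0, 15))
  b <- global_bend(e1, e2, mid)
  expect_equal(b$theta, 0.2, tolerance = 1e-10)
  expect_equal(b$phi, 0, tolerance = 1e-10)
  expect_equal(b$rho, 0.2, tolerance = 1e-10)

  # decomposition arithmetic at the worked values: theta 12 deg, phi 179 deg
  th <- 12 * pi / 180; ph <- 179 * pi / 180
  expect_equal(round(180 / pi * th * cos(ph), 3), -11.998)
  expect_equal(round(180 / pi * th * sin(ph), 3), 0.209)

  # rho^2 + tau^2 = theta^2 for random geometries
  set.seed(23)
  for (rep in 1:10) {
    b <- global_bend(random_frame(spread = 0.4), random_frame(spread = 0.4),
                     random_frame(spread = 0.4))
    expect_lt(abs(b$rho^2 + b$tau^2 - b$theta^2), 1e-12)
  }
})

test_that("frame reconstruction: straight helix, roundtrip, uniform-roll closed form", {
  # canonical B-DNA: pure twist 36 deg, rise 3.4 A -> straight helix
  n_steps <- 9
  steps <- cbind(tilt = 0, roll = 0, twist = rep(36, n_steps),
                 shift = 0, slide = 0, rise = 3.4)
  fr <- frames_from_steps(steps)
  zs <- vapply(fr, function(f) f$axes[, 3], numeric(3))
  expect_true(all(abs(zs - c(0, 0, 1)) < 1e-10))
  ee <- fr[[length(fr)]]$origin - fr[[1]]$origin
  expect_equal(sqrt(sum(ee^2)), n_steps * 3.4, tolerance = 1e-10)

  # exact inverse on random step coordinates
  set.seed(31)
  for (rep in 1:8) {
    steps <- cbind(tilt = rnorm(5, 0, 4), roll = rnorm(5, 3, 5),
                   twist = rnorm(5, 34, 5), shift = rnorm(5, 0, 0.5),
                   slide = rnorm(5, -0.2, 0.5), rise = rnorm(5, 3.3, 0.3))
    rec <- steps_from_frames(frames_from_steps(steps))
    expect_lt(max(abs(rec - steps)), 1e-8)
  }

  # uniform roll, zero tilt and twist: bend angle between end z-axes equals
  # the closed form from multiplying the per-step rotation matrices directly
  roll_deg <- 4
  steps <- cbind(tilt = 0, roll = rep(roll_deg, 6), twist = 0,
                 shift = 0, slide = 0, rise = 3.3)
  fr <- frames_from_steps(steps)
  R_oracle <- Reduce(`%*%`, replicate(6, dnamech:::rot_y(roll_deg * pi / 180),
                                      simplify = FALSE))
  z_end_oracle <- R_oracle[, 3]
  bend <- acos(sum(fr[[7]]$axes[, 3] * c(0, 0, 1)))
  bend_oracle <- acos(z_end_oracle[3])
  expect_equal(bend, bend_oracle, tolerance = 1e-10)
  expect_equal(bend, 6 * roll_deg * pi / 180, tolerance = 1e-10)
})

test_that("trajectory-level frame reconstruction inverts to the input step coordinates", {
  set.seed(4)
  gt <- ground_truth_model("GCATGC")
  tr <- simulate(gt, nsim = 12, seed = 5)
  ft <- reconstruct_frames(tr)
  expect_equal(ft$n, 6)
  rec <- extract_step_coords(ft)
  s <- schema_of(tr)
  orig <- vapply(step_coord_names(), function(cc) unclass(tr)[, coord_index(s, cc)],
                 matrix(0, 12, 5))
  orig <- matrix(orig, nrow = 12)   # columns grouped by coordinate, like rec
  expect_lt(max(abs(rec - orig)), 1e-8)
})
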