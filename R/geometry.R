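# Base-pair frame reconstruction from step coordinates and its exact
# inverse. Convention (mid-step triad composition, the standard CEHS-style
# construction): with tilt t, roll r, twist w in radians, bend magnitude
# Gamma = sqrt(t^2 + r^2) and hinge phase phi' = atan2(t, r),
#   R_step = Rz(w/2 - phi') Ry(Gamma)   Rz(w/2 + phi')
#   R_mid  = Rz(w/2 - phi') Ry(Gamma/2) Rz(phi')
# frame_{i+1} = frame_i R_step and the displacement (shift, slide, rise) is
# expressed in the mid-step triad frame_i R_mid. Pure twist is rotation
# about z, pure roll about the mid-frame y, pure tilt about the mid-frame x.

rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE)
}

step_rotations <- function(tilt, roll, twist) {
  gamma <- sqrt(tilt^2 + roll^2)
  phase <- if (gamma > 0) atan2(tilt, roll) else 0
  list(
    step = rot_z(twist / 2 - phase) %*% rot_y(gamma) %*% rot_z(twist / 2 + phase),
    mid  = rot_z(twist / 2 - phase) %*% rot_y(gamma / 2) %*% rot_z(phase)
  )
}

#' Build base-pair frames from step coordinates
#'
#' Reconstructs one coordinate frame per base pair from the six step
#' coordinates of each step using the mid-step triad composition rule (see
#' the package geometry notes): tilt and roll rotate about the mid-frame x
#' and y axes, twist about z, and shift/slide/rise displace the origin along
#' the mid-frame axes. Frame 1 is the identity frame at the origin.
#' `steps_from_frames()` is the exact inverse.
#'
#' @param steps (n-1) x 6 matrix of step coordinates, columns tilt, roll,
#'   twist (degrees), shift, slide, rise (Angstrom).
#' @return `frames_from_steps()`: list of n [dna_frame]s.
#' @export
frames_from_steps <- function(steps) {
  steps <- as.matrix(steps)
  if (ncol(steps) != 6L) stop("`steps` must have 6 columns (tilt, roll, twist, shift, slide, rise)", call. = FALSE)
  n <- nrow(steps) + 1L
  frames <- vector("list", n)
  frames[[1]] <- dna_frame()
  R <- diag(3); o <- c(0, 0, 0)
  for (j in seq_len(n - 1L)) {
    rots <- step_rotations(deg2rad(steps[j, 1]), deg2rad(steps[j, 2]), deg2rad(steps[j, 3]))
    o <- o + as.vector(R %*% rots$mid %*% steps[j, 4:6])
    R <- R %*% rots$step
    frames[[j + 1L]] <- dna_frame(o, project_rotation(R))
  }
  frames
}

#' @rdname frames_from_steps
#' @param frames List of n [dna_frame]s.
#' @return `steps_from_frames()`: (n-1) x 6 matrix of step coordinates.
#' @export
steps_from_frames <- function(frames) {
  n <- length(frames)
  if (n < 2L) stop("need at least two frames", call. = FALSE)
  out <- matrix(NA_real_, n - 1L, 6L,
                dimnames = list(NULL, step_coord_names()))
  for (j in seq_len(n - 1L)) {
    f1 <- frames[[j]]; f2 <- frames[[j + 1L]]
    A <- crossprod(f1$axes, f2$axes)       # Rz(a) Ry(b) Rz(g)
    sb <- sqrt(A[1, 3]^2 + A[2, 3]^2)
    gamma <- atan2(sb, A[3, 3])
    if (sb < 1e-12) {
      # pure twist: the ZYZ split of alpha and gamma is degenerate
      twist <- atan2(A[2, 1], A[1, 1])
      phase <- 0
    } else {
      alpha <- atan2(A[2, 3], A[1, 3])
      delta <- atan2(A[3, 2], -A[3, 1])
      twist <- alpha + delta
      phase <- (delta - alpha) / 2
      # (twist, phase) and (twist - 2*pi*k, phase - pi*k) parameterize the
      # same rotation; pick the branch with twist in (-pi, pi]
      k <- round(twist / (2 * pi))
      twist <- twist - 2 * pi * k
      phase <- phase - pi * k
    }
    tilt <- gamma * sin(phase)
    roll <- gamma * cos(phase)
    mid <- rot_z(twist / 2 - phase) %*% rot_y(gamma / 2) %*% rot_z(phase)
    disp <- crossprod(f1$axes %*% mid, f2$origin - f1$origin)
    out[j, ] <- c(rad2deg(tilt), rad2deg(roll), rad2deg(twist), disp)
  }
  out
}

#' Reconstruct per-snapshot frame trajectories
#'
#' Applies [frames_from_steps] to the step coordinates of every snapshot of
#' a trajectory, yielding one base-pair frame per pair per snapshot (frame 1
#' is the identity frame; only relative geometry is meaningful).
#'
#' @param traj A [coord_trajectory].
#' @return A `frame_trajectory`: list with `origin` (M x n x 3 array,
#'   Angstrom), `axes` (M x n x 3 x 3 array) and `n`.
#' @export
reconstruct_frames <- function(traj) {
  s <- schema_of(traj)
  M <- nrow(traj)
  step_cols <- lapply(step_coord_names(), function(cc) coord_index(s, cc))
  origin <- array(NA_real_, c(M, s$n, 3))
  axes <- array(NA_real_, c(M, s$n, 3, 3))
  X <- unclass(traj)
  for (i in seq_len(M)) {
    steps <- vapply(step_cols, function(idx) X[i, idx], numeric(s$n - 1L))
    fr <- frames_from_steps(steps)
    for (p in seq_len(s$n)) {
      origin[i, p, ] <- fr[[p]]$origin
      axes[i, p, , ] <- fr[[p]]$axes
    }
  }
  structure(list(origin = origin, axes = axes, n = s$n, M = M),
            class = "frame_trajectory")
}

#' @export
print.frame_trajectory <- function(x, ...) {
  cat(sprintf("Frame trajectory: %d snapshots x %d base-pair frames\n", x$M, x$n))
  invisible(x)
}

#' @rdname reconstruct_frames
#' @param ft A `frame_trajectory`.
#' @param snapshot,pair Indices (1-based).
#' @return `get_frame()`: the requested [dna_frame].
#' @export
get_frame <- function(ft, snapshot, pair) {
  stopifnot(inherits(ft, "frame_trajectory"))
  dna_frame(ft$origin[snapshot, pair, ],
            project_rotation(ft$axes[snapshot, pair, , ]))
}

#' @rdname reconstruct_frames
#' @return `extract_step_coords()`: M x 6(n-1) matrix of step coordinates,
#'   snapshots in rows, the inverse of the per-snapshot reconstruction.
#' @export
extract_step_coords <- function(ft) {
  stopifnot(inherits(ft, "frame_trajectory"))
  out <- matrix(NA_real_, ft$M, 6L * (ft$n - 1L))
  for (i in seq_len(ft$M)) {
    frames <- lapply(seq_len(ft$n), function(p) get_frame(ft, i, p))
    out[i, ] <- as.vector(steps_from_frames(frames))
  }
  out
}
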