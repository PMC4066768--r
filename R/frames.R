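#' Base-fixed coordinate frames
#'
#' A frame is an origin (Angstrom) plus a right-handed orthonormal triad of
#' axes stored as the columns of a 3 x 3 matrix; by the standard reference
#' frame convention the x-axis points toward the major groove, the y-axis
#' along the long axis of the pair, and the z-axis along the helix.
#'
#' @param origin Numeric 3-vector, Angstrom.
#' @param axes 3 x 3 matrix with orthonormal columns (x, y, z), det +1.
#' @return Object of class `dna_frame`.
#' @export
dna_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  if (length(origin) != 3L || !all(dim(axes) == c(3L, 3L)))
    stop("a frame needs a 3-vector origin and 3 x 3 axes", call. = FALSE)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stop("frame axes are not orthonormal", call. = FALSE)
  if (det(axes) < 0)
    stop("frame axes are left-handed (det = -1)", call. = FALSE)
  structure(list(origin = origin, axes = axes), class = "dna_frame")
}

#' @export
print.dna_frame <- function(x, ...) {
  cat(sprintf("Frame at (%.3f, %.3f, %.3f) Angstrom\n",
              x$origin[1], x$origin[2], x$origin[3]))
  print(round(x$axes, 4))
  invisible(x)
}

#' Flip a frame to the reference-strand orientation
#'
#' Bases on the complementary strand carry frames whose y and z axes point
#' opposite to the reference strand; negating both (a rotation by 180 degrees
#' about x) brings all frames into a common orientation before averaging.
#'
#' @param frame A [dna_frame].
#' @return The flipped frame.
#' @export
flip_frame <- function(frame) {
  dna_frame(frame$origin, frame$axes %*% diag(c(1, -1, -1)))
}

# --- rotation <-> unit quaternion (w, x, y, z) ---------------------------

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# nearest rotation to an arbitrary 3 x 3 matrix (orthogonal Procrustes):
# SVD projection, determinant corrected to +1.
project_rotation <- function(M) {
  s <- svd(M)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

#' Average of coordinate frames
#'
#' Origins are averaged arithmetically; orientations are averaged either by
#' the quaternion eigen-average (the chordal-metric mean: the principal
#' eigenvector of the accumulated outer products of the unit quaternions,
#' the default) or by SVD projection of the summed rotation matrices onto
#' the nearest rotation. The two estimators coincide for well-clustered
#' orientations and both are kept so that each can serve as an independent
#' check of the other.
#'
#' @param frames List of [dna_frame]s (at least one).
#' @param method `"quaternion"` (default) or `"svd"`.
#' @param max_spread Maximum allowed angle (radians) between any input
#'   orientation and the average; beyond 90 degrees the average direction is
#'   ambiguous and an error is raised.
#' @return The average [dna_frame].
#' @export
mean_frame <- function(frames, method = c("quaternion", "svd"),
                       max_spread = pi / 2) {
  method <- match.arg(method)
  if (inherits(frames, "dna_frame")) frames <- list(frames)
  if (length(frames) < 1L) stop("need at least one frame", call. = FALSE)
  origin <- rowMeans(vapply(frames, function(f) f$origin, numeric(3)))
  qs <- lapply(frames, function(f) rot_to_quat(f$axes))
  if (method == "quaternion") {
    B <- matrix(0, 4, 4)
    for (q in qs) B <- B + tcrossprod(q)
    qm <- eigen(B, symmetric = TRUE)$vectors[, 1]
    R <- quat_to_rot(qm)
  } else {
    S <- Reduce(`+`, lapply(frames, function(f) f$axes))
    R <- project_rotation(S)
    qm <- rot_to_quat(R)
  }
  spread <- vapply(qs, function(q) 2 * acos(pmin(1, abs(sum(q * qm)))), numeric(1))
  if (any(spread > max_spread))
    stop(sprintf(
      "orientation spread %.1f degrees exceeds %.1f degrees: frame average is ambiguous",
      rad2deg(max(spread)), rad2deg(max_spread)), call. = FALSE)
  dna_frame(origin, R)
}

#' Global bend between two end frames
#'
#' The bend magnitude is the angle between the z-axes of the two end frames.
#' The bend direction phi is measured in the middle frame about its z-axis,
#' with phi = 0 for bending toward the major groove (middle-frame +x) and
#' phi = pi toward the minor groove; phi increases from +x toward +y. The
#' global roll and global tilt components are
#' \deqn{\rho = \vartheta\cos\varphi, \quad \tau = \vartheta\sin\varphi.}
#'
#' @param end1,end2,middle [dna_frame]s at the two ends and the centre.
#' @return List with `theta`, `phi`, `rho`, `tau` (all radians) and
#'   `phi_defined` (`FALSE` when theta is numerically zero, in which case
#'   phi is reported as 0).
#' @export
global_bend <- function(end1, end2, middle) {
  z1 <- end1$axes[, 3]; z2 <- end2$axes[, 3]
  theta <- acos(pmin(1, pmax(-1, sum(z1 * z2))))
  if (theta < 1e-12) {
    return(list(theta = 0, phi = 0, rho = 0, tau = 0, phi_defined = FALSE))
  }
  hinge <- c(z1[2] * z2[3] - z1[3] * z2[2],
             z1[3] * z2[1] - z1[1] * z2[3],
             z1[1] * z2[2] - z1[2] * z2[1])
  hinge <- hinge / sqrt(sum(hinge^2))
  zm <- middle$axes[, 3]
  # bend direction in the cross-section: rotating z1 into z2 about `hinge`
  # curves the axis toward hinge x z
  u <- c(hinge[2] * zm[3] - hinge[3] * zm[2],
         hinge[3] * zm[1] - hinge[1] * zm[3],
         hinge[1] * zm[2] - hinge[2] * zm[1])
  phi <- atan2(sum(u * middle$axes[, 2]), sum(u * middle$axes[, 1]))
  list(theta = theta, phi = phi,
       rho = theta * cos(phi), tau = theta * sin(phi), phi_defined = TRUE)
}
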