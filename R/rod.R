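#' Total twist and contour length over a step window
#'
#' The total twist between two end frames is the sum of local dinucleotide
#' twists over the window, with the two boundary steps counted at half
#' weight (the end frames sit mid-step). The contour length is the analogous
#' half-weighted sum of local rises, converted from Angstrom to nanometres.
#'
#' @param x Numeric vector (one snapshot) or matrix (snapshots in rows) of
#'   per-step twists (degrees) or rises (Angstrom) for the full molecule.
#' @param window Integer range of step indices covered (>= 2 steps);
#'   default all steps.
#' @return Total twist in degrees / contour length in nm, one value per
#'   snapshot.
#' @examples
#' total_twist(c(30, 34, 36, 34, 30))     # 134
#' contour_length(rep(3.3, 5))            # 1.32 nm
#' @export
total_twist <- function(x, window = NULL) {
  half_weighted_sum(x, window)
}

#' @rdname total_twist
#' @export
contour_length <- function(x, window = NULL) {
  half_weighted_sum(x, window) / 10   # Angstrom -> nm
}

half_weighted_sum <- function(x, window = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (is.null(window)) window <- seq_len(ncol(X))
  if (length(window) < 2L) stop("window must cover at least 2 steps", call. = FALSE)
  wts <- rep(1, length(window))
  wts[c(1L, length(window))] <- 0.5
  out <- as.vector(X[, window, drop = FALSE] %*% wts)
  if (is.matrix(x)) out else out[[1]]
}

#' Global rod coordinate series from a trajectory
#'
#' Builds the per-snapshot elastic-rod coordinates of a duplex: global roll
#' rho and global tilt tau (the bend between mean end frames resolved in the
#' mean middle frame, radians), total twist omega (radians) and contour
#' length l (nm). Mean frames at the two ends and the middle are averaged
#' over small windows of consecutive base-pair frames (default two pairs at
#' each location).
#'
#' @param traj A [coord_trajectory].
#' @param frames Optional precomputed `frame_trajectory`
#'   (from [reconstruct_frames]); reconstructed from `traj` when omitted.
#' @param end1_pairs,end2_pairs,mid_pairs Base-pair indices averaged into
#'   the end and middle frames; defaults: pairs 1:2, (n-1):n, and the two
#'   central pairs.
#' @param step_window Step range for total twist and contour length;
#'   default first(end1_pairs) .. last(end2_pairs) - 1.
#' @return A data frame of class `rod_series` with columns `rho`, `tau`,
#'   `omega` (radians), `theta`, `phi` (radians), `l` (nm).
#' @export
rod_series <- function(traj, frames = NULL,
                       end1_pairs = NULL, end2_pairs = NULL, mid_pairs = NULL,
                       step_window = NULL) {
  s <- schema_of(traj)
  n <- s$n
  end1_pairs <- end1_pairs %||% c(1L, 2L)
  end2_pairs <- end2_pairs %||% c(n - 1L, n)
  mid_pairs <- mid_pairs %||% (floor(n / 2) + c(0L, 1L))
  step_window <- step_window %||% (min(end1_pairs):(max(end2_pairs) - 1L))
  if (is.null(frames)) frames <- reconstruct_frames(traj)
  X <- unclass(traj)
  twists <- X[, coord_index(s, "twist"), drop = FALSE]
  rises <- X[, coord_index(s, "rise"), drop = FALSE]
  M <- nrow(X)
  rho <- tau <- theta <- phi <- numeric(M)
  for (i in seq_len(M)) {
    f1 <- mean_frame(lapply(end1_pairs, function(p) get_frame(frames, i, p)))
    f2 <- mean_frame(lapply(end2_pairs, function(p) get_frame(frames, i, p)))
    fm <- mean_frame(lapply(mid_pairs, function(p) get_frame(frames, i, p)))
    b <- global_bend(f1, f2, fm)
    rho[i] <- b$rho; tau[i] <- b$tau; theta[i] <- b$theta; phi[i] <- b$phi
  }
  out <- data.frame(
    rho = rho, tau = tau,
    omega = deg2rad(total_twist(twists, step_window)),
    theta = theta, phi = phi,
    l = contour_length(rises, step_window)
  )
  class(out) <- c("rod_series", "data.frame")
  attr(out, "windows") <- list(end1 = end1_pairs, end2 = end2_pairs,
                               mid = mid_pairs, steps = step_window)
  out
}

#' Fit the anisotropic elastic-rod model
#'
#' Treats the duplex as an elastic rod described by global roll, global tilt
#' and total twist, u = (rho, tau, omega), with deformation energy
#' \deqn{E_r(u) = \frac{k_B T}{2 l_0} (u - \hat u) \cdot K_r (u - \hat u)}
#' where the 3 x 3 stiffness matrix carries units of length (the
#' persistence-length analogue). Equilibrium coordinates are the sample
#' means and \eqn{K_r = l_0 \, C_u^{-1}} with \eqn{C_u} the covariance of u
#' in radians^2 and \eqn{l_0} the mean contour length.
#'
#' @param series A [rod_series] (or data frame with columns `rho`, `tau`,
#'   `omega` in radians and `l` in nm; at least 100 snapshots).
#' @param temperature Kelvin; enters only the energy scale, not `K_r`.
#' @param unbiased Covariance denominator, as in [rigid_base_model].
#' @return Object of class `rod_model`: `u_hat` (radians), `K_r` (nm), `l0`
#'   (nm), `temperature`, `M`, plus the derived constants `a_g`, `a_b`,
#'   `a_iso` (bending toward grooves / backbone / effective isotropic) and
#'   `c_twist`, all in nm.
#' @seealso [bending_stiffness], [twist_stiffness], [rod_energy]
#' @export
fit_rod <- function(series, temperature = default_temperature, unbiased = FALSE) {
  need <- c("rho", "tau", "omega", "l")
  if (!all(need %in% names(series)))
    stop("series must contain columns rho, tau, omega, l", call. = FALSE)
  if (nrow(series) < 100L)
    stop("need at least 100 snapshots to fit the rod model", call. = FALSE)
  U <- as.matrix(series[, c("rho", "tau", "omega")])
  l0 <- mean(series$l)
  Cu <- cov_ml(U, unbiased = unbiased)
  K_r <- symmetrize(l0 * spd_inverse(Cu, what = "rod coordinate covariance"))
  new_rod_model(colMeans(U), K_r, l0, temperature, M = nrow(series))
}

new_rod_model <- function(u_hat, K_r, l0, temperature = default_temperature,
                          M = NA_integer_) {
  names(u_hat) <- c("rho", "tau", "omega")
  dimnames(K_r) <- list(names(u_hat), names(u_hat))
  obj <- structure(list(u_hat = u_hat, K_r = K_r, l0 = l0,
                        temperature = temperature, M = M),
                   class = "rod_model")
  bend <- bending_stiffness(obj)
  obj$a_g <- bend$a_g; obj$a_b <- bend$a_b; obj$a_iso <- bend$a_iso
  obj$c_twist <- twist_stiffness(obj)
  obj
}

#' @export
print.rod_model <- function(x, ...) {
  cat(sprintf("Anisotropic elastic-rod model (l0 = %.3f nm%s)\n", x$l0,
              if (is.na(x$M)) "" else sprintf(", %d snapshots", x$M)))
  cat(sprintf("  equilibrium: rho = %.2f deg, tau = %.2f deg, omega = %.1f deg\n",
              rad2deg(x$u_hat[1]), rad2deg(x$u_hat[2]), rad2deg(x$u_hat[3])))
  cat(sprintf("  bending stiffness: a_g = %.1f nm (grooves), a_b = %.1f nm (backbone), a_iso = %.1f nm\n",
              x$a_g, x$a_b, x$a_iso))
  cat(sprintf("  twist stiffness:   C = %.1f nm\n", x$c_twist))
  invisible(x)
}

#' @export
coef.rod_model <- function(object, ...) object$u_hat

#' @export
vcov.rod_model <- function(object, ...) object$l0 * solve(object$K_r)

#' Bending and twist stiffness constants of a rod model
#'
#' `bending_stiffness()` considers pure bending with total twist free to
#' relax: the twist row/column of `K_r` is marginalized out (Schur
#' complement), leaving a 2 x 2 bending stiffness whose diagonal entries are
#' the constants for bending toward the grooves (`a_g`) and toward the
#' backbone (`a_b`). The effective isotropic constant is their harmonic mean,
#' `2/a_iso = 1/a_g + 1/a_b`, and always lies between them. The off-diagonal
#' coupling is returned for inspection (it is typically an order of
#' magnitude smaller than the diagonal). `twist_stiffness()` is the
#' complementary pure-twist constant with bending unconstrained: the 1 x 1
#' relaxation of `K_r` onto total twist, equal to `l0 / Var(omega)`.
#'
#' @param rod A [rod_model].
#' @return `bending_stiffness()`: list `a_g`, `a_b`, `a_iso`, `off_diagonal`,
#'   `K_bend` (nm). `twist_stiffness()`: scalar nm.
#' @export
bending_stiffness <- function(rod) {
  K <- rod$K_r
  Kb <- symmetrize(K[1:2, 1:2] - K[1:2, 3, drop = FALSE] %*%
                     (K[3, 1:2, drop = FALSE] / K[3, 3]))
  a_g <- Kb[1, 1]; a_b <- Kb[2, 2]
  list(a_g = a_g, a_b = a_b, a_iso = iso_bending_stiffness(a_g, a_b),
       off_diagonal = Kb[1, 2], K_bend = Kb)
}

#' @rdname bending_stiffness
#' @export
twist_stiffness <- function(rod) {
  K <- rod$K_r
  c_twist <- K[3, 3] - K[3, 1:2, drop = FALSE] %*%
    solve(K[1:2, 1:2], K[1:2, 3, drop = FALSE])
  c_twist <- drop(c_twist)
  if (c_twist <= 0) stop("non-positive twist stiffness; K_r is not SPD", call. = FALSE)
  c_twist
}

#' @rdname bending_stiffness
#' @param a_g,a_b Bending stiffness constants (nm).
#' @export
iso_bending_stiffness <- function(a_g, a_b) 2 / (1 / a_g + 1 / a_b)

#' Rod deformation energy
#'
#' @param rod A [rod_model].
#' @param u Coordinate vector (rho, tau, omega) in radians, or a matrix with
#'   one configuration per row.
#' @return Energy in kcal/mol.
#' @export
rod_energy <- function(rod, u) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
  if (ncol(U) != 3L) stop("u must have 3 components (rho, tau, omega)", call. = FALSE)
  D <- sweep(U, 2L, rod$u_hat)
  e <- kB_kcal * rod$temperature / (2 * rod$l0) * rowSums((D %*% rod$K_r) * D)
  if (is.matrix(u)) e else e[[1]]
}

#' Simulate rod coordinates from a rod model
#'
#' Draws iid snapshots of u = (rho, tau, omega) from the Gaussian implied by
#' the model, with covariance \eqn{l_0 K_r^{-1}}; the contour length column
#' is held at `l0`.
#'
#' @param object A [rod_model].
#' @param nsim Number of snapshots.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A [rod_series]-shaped data frame.
#' @export
simulate.rod_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  Cu <- object$l0 * solve(object$K_r)
  L <- chol(symmetrize(Cu))
  U <- matrix(stats::rnorm(nsim * 3L), nsim, 3L) %*% L
  U <- sweep(U, 2L, object$u_hat, `+`)
  out <- data.frame(rho = U[, 1], tau = U[, 2], omega = U[, 3],
                    theta = sqrt(U[, 1]^2 + U[, 2]^2),
                    phi = atan2(U[, 2], U[, 1]),
                    l = rep(object$l0, nsim))
  class(out) <- c("rod_series", "data.frame")
  out
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rod model JSON report
#'
#' Writes equilibrium coordinates (degrees), the stiffness matrix, derived
#' bending/twist constants (nm) and optional half-trajectory errors.
#'
#' @param rod A [rod_model].
#' @param path Output file.
#' @param errors Optional named list of half-trajectory errors to embed.
#' @export
write_rod_report <- function(rod, path, errors = NULL) {
  doc <- list(
    format = "dnamech-rod-model", version = 1L,
    u_hat_deg = rad2deg(unname(rod$u_hat)),
    K_r_nm = as.vector(t(rod$K_r)),
    l0_nm = rod$l0, temperature = rod$temperature,
    M = if (is.na(rod$M)) NULL else rod$M,
    a_g_nm = rod$a_g, a_b_nm = rod$a_b, a_iso_nm = rod$a_iso,
    c_twist_nm = rod$c_twist,
    phi_convention = "phi = 0 toward major groove (+x of middle frame), increasing toward +y",
    half_trajectory_errors = errors
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
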