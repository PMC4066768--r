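# Synthetic ground-truth models and trajectories. The generator emulates the
# statistical structure the inference assumes -- a stationary multivariate
# Gaussian over the rigid-base coordinates with a prescribed shape vector
# and a non-local SPD stiffness -- so that every stage of the pipeline can
# be validated end to end without molecular-dynamics data. The built-in
# parameter tables are B-DNA-like and illustrative (canonical twist near
# 34 degrees, rise near 3.3 Angstrom, more negative propeller for A.T
# pairs); they are not derived from any simulation.

# 10 unique dinucleotide step types (reverse-complement symmetric): means for
# tilt, roll, twist (deg), shift, slide, rise (Angstrom).
step_mean_table <- function() {
  m <- rbind(
    AA = c(0, 0.5, 35.5, 0, -0.3, 3.25),
    AC = c(0, 0.5, 33.0, 0, -0.4, 3.30),
    AG = c(0, 4.0, 31.5, 0, -0.2, 3.30),
    AT = c(0, -1.0, 32.0, 0, -0.6, 3.30),
    CA = c(0, 6.0, 35.0, 0, 0.2, 3.35),
    CC = c(0, 3.5, 33.5, 0, -0.2, 3.30),
    CG = c(0, 5.5, 34.5, 0, 0.3, 3.35),
    GA = c(0, 2.0, 36.0, 0, -0.1, 3.35),
    GC = c(0, 1.0, 34.5, 0, -0.1, 3.35),
    TA = c(0, 7.0, 36.5, 0, 0.2, 3.40)
  )
  colnames(m) <- step_coord_names()
  m
}

# per-step-type diagonal stiffness (kcal/mol per deg^2 or Angstrom^2);
# stiffer A-tract-like steps (AA, AT), soft TA/CA, generic otherwise.
step_stiffness_table <- function() {
  base <- c(tilt = 0.045, roll = 0.022, twist = 0.030,
            shift = 1.6, slide = 2.2, rise = 6.0)
  scale <- c(AA = 1.35, AC = 1.00, AG = 0.95, AT = 1.45, CA = 0.70,
             CC = 1.00, CG = 0.80, GA = 1.05, GC = 1.10, TA = 0.60)
  out <- outer(scale, base)
  colnames(out) <- step_coord_names()
  out
}

# intra-basepair means and diagonal stiffness per pair type.
intra_mean_table <- function() {
  m <- rbind(
    AT = c(0, -16, 1.5, 0, 0, 0.05),
    GC = c(0, -9, 0.5, 0, 0, 0.10)
  )
  colnames(m) <- intra_coord_names()
  m
}

intra_stiffness_table <- function() {
  m <- rbind(
    AT = c(buckle = 0.013, propeller = 0.018, opening = 0.045,
           shear = 1.4, stretch = 3.5, stagger = 1.2),
    GC = c(buckle = 0.015, propeller = 0.022, opening = 0.075,
           shear = 1.6, stretch = 5.0, stagger = 1.4)
  )
  m
}

revcomp_base <- c(A = "T", C = "G", G = "C", T = "A")

step_type <- function(b1, b2) {
  st <- paste0(b1, b2)
  rc <- paste0(revcomp_base[b2], revcomp_base[b1])
  if (st %in% rownames(step_mean_table())) st else rc
}

pair_type <- function(b) if (b %in% c("A", "T")) "AT" else "GC"

#' Synthetic ground-truth rigid-base model
#'
#' Assembles an exact shape vector and non-local stiffness matrix for a
#' sequence from built-in B-DNA-like dinucleotide and base-pair parameter
#' tables, then adds exponentially decaying long-range couplings between
#' step blocks (same-coordinate couplings of magnitude
#' `coupling_strength * exp(-(d-1)/coupling_decay) * sqrt(K_aa K_bb)` for
#' step separation d). The assembled matrix is checked for positive
#' definiteness; if the couplings push the smallest eigenvalue below a small
#' positive floor a uniform diagonal shift restores it (reported via a
#' message).
#'
#' @param sequence Reference-strand sequence, 5'->3', over A/C/G/T.
#' @param temperature Kelvin.
#' @param coupling_strength Relative strength of the long-range kernel in
#'   (0, 1); 0 gives an exactly block-diagonal stiffness.
#' @param coupling_decay Decay length of the kernel in base-pair steps.
#' @return A [rigid_base_model] (with `M = NA`: it is exact, not estimated).
#' @examples
#' m <- ground_truth_model("GCGAAATTTCGC")
#' m
#' @export
ground_truth_model <- function(sequence, temperature = default_temperature,
                               coupling_strength = 0.12, coupling_decay = 2) {
  schema <- coord_schema(sequence)
  if (coupling_strength < 0 || coupling_strength >= 1)
    stop("coupling_strength must be in [0, 1)", call. = FALSE)
  n <- schema$n
  bases <- strsplit(schema$sequence, "")[[1]]
  w_hat <- numeric(schema$N)
  K <- matrix(0, schema$N, schema$N)
  im <- intra_mean_table(); ik <- intra_stiffness_table()
  sm <- step_mean_table(); sk <- step_stiffness_table()
  for (p in seq_len(n)) {
    pt <- pair_type(bases[p])
    idx <- which(schema$kind == "intra" & schema$index == p)
    w_hat[idx] <- im[pt, ]
    K[cbind(idx, idx)] <- ik[pt, ]
  }
  step_types <- vapply(seq_len(n - 1L), function(j) step_type(bases[j], bases[j + 1L]),
                       character(1))
  for (j in seq_len(n - 1L)) {
    idx <- which(schema$kind == "step" & schema$index == j)
    w_hat[idx] <- sm[step_types[j], ]
    K[cbind(idx, idx)] <- sk[step_types[j], ]
  }
  if (coupling_strength > 0 && n > 2L) {
    for (j in seq_len(n - 2L)) for (k in (j + 1L):(n - 1L)) {
      d <- k - j
      g <- coupling_strength * exp(-(d - 1) / coupling_decay)
      ij <- which(schema$kind == "step" & schema$index == j)
      ikk <- which(schema$kind == "step" & schema$index == k)
      cp <- -g * sqrt(diag(K)[ij] * diag(K)[ikk])   # same-coordinate coupling
      K[cbind(ij, ikk)] <- cp
      K[cbind(ikk, ij)] <- cp
    }
  }
  K <- symmetrize(K)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 1e-6 * max(ev)
  if (min(ev) < floor_ev) {
    shift <- floor_ev - min(ev)
    if (shift > 0.5 * max(ev))
      stop("assembled stiffness is too far from positive definite", call. = FALSE)
    message(sprintf("ground_truth_model: SPD floor applied, diagonal shift %.3g", shift))
    K <- K + diag(shift, schema$N)
  }
  C <- symmetrize(kB_kcal * temperature * chol2inv(chol(K)))
  new_rigid_base_model(schema, w_hat, K, C, temperature, M = NA_integer_)
}

#' Reverse-complement coordinate permutation
#'
#' Mapping of the canonical coordinates under re-reading the duplex from the
#' complementary strand: pair i goes to pair n+1-i, step j to step n-j, and
#' the coordinates that are odd under the strand swap (buckle, shear, tilt,
#' shift) change sign. For a palindromic sequence the stiffness matrix K
#' satisfies `K = S P K P' S` with permutation P and sign matrix S.
#'
#' @param schema A [coord_schema].
#' @return List with integer `perm` and numeric `sign` vectors of length N.
#' @export
revcomp_permutation <- function(schema) {
  n <- schema$n
  odd <- c("buckle", "shear", "tilt", "shift")
  perm <- integer(schema$N)
  for (i in seq_len(schema$N)) {
    new_index <- if (schema$kind[i] == "intra") n + 1L - schema$index[i]
                 else n - schema$index[i]
    perm[i] <- which(schema$coord == schema$coord[i] & schema$index == new_index)
  }
  list(perm = perm, sign = ifelse(schema$coord %in% odd, -1, 1))
}

#' Sample coordinate snapshots from a rigid-base model
#'
#' Draws `nsim` iid snapshots from the N-dimensional Gaussian implied by the
#' model (mean `w_hat`, covariance \eqn{k_B T K^{-1}}), reproducibly for a
#' given seed.
#'
#' @param object A [rigid_base_model].
#' @param nsim Number of snapshots.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param ... Unused.
#' @return A [coord_trajectory].
#' @export
simulate.rigid_base_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  L <- chol(object$C)
  N <- length(object$w_hat)
  X <- matrix(stats::rnorm(nsim * N), nsim, N) %*% L
  X <- sweep(X, 2L, object$w_hat, `+`)
  coord_trajectory(X, object$schema)
}

#' Toy nucleosome template with 10-bp periodic roll
#'
#' Emits a template whose roll oscillates sinusoidally with the given period
#' (mimicking the rotational register of nucleosomal DNA, where roll
#' oscillates with the helical repeat) and whose twist and slide are
#' constant, optionally with Gaussian noise.
#'
#' @param L_t Template length in steps (default 147, a nucleosome's worth).
#' @param period Roll period in bp (default 10).
#' @param roll_amplitude Roll oscillation amplitude, degrees.
#' @param roll_mean,twist_mean,slide_mean Constant offsets (deg, deg,
#'   Angstrom).
#' @param noise_sd Gaussian noise SD added to all three profiles.
#' @param seed Optional seed for the noise.
#' @return A [nucleosome_template].
#' @export
make_toy_nucleosome_template <- function(L_t = 147, period = 10,
                                         roll_amplitude = 5, roll_mean = 0,
                                         twist_mean = 34.3, slide_mean = -0.2,
                                         noise_sd = 0, seed = NULL) {
  if (L_t < period) stop("L_t must be at least one period", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  s <- seq_len(L_t)
  noise <- function() if (noise_sd > 0) stats::rnorm(L_t, 0, noise_sd) else rep(0, L_t)
  nucleosome_template(
    roll = roll_mean + roll_amplitude * sin(2 * pi * s / period) + noise(),
    twist = twist_mean + noise(),
    slide = slide_mean + noise(),
    dyad = ceiling(L_t / 2)
  )
}

#' Inject broken base pairs into a synthetic H-bond series
#'
#' Builds a per-snapshot, per-pair series of maximum Watson-Crick H-bond
#' distances in which a chosen fraction of snapshots carries broken pairs
#' (distance above the 4 Angstrom filter cutoff) at the chosen pairs, and
#' all other entries sit at an intact baseline.
#'
#' @param traj A [coord_trajectory] (its snapshot count and pair count set
#'   the dimensions).
#' @param fraction Fraction of snapshots to break, in `[0, 1]`; the broken
#'   count is `round(fraction * M)`.
#' @param pairs Pair indices at which the breaks occur.
#' @param seed Optional seed for selecting the snapshots.
#' @param intact,broken Distances used for intact and broken entries
#'   (Angstrom).
#' @return List with `traj` (unchanged) and `hbonds` (M x n matrix).
#' @export
inject_broken_pairs <- function(traj, fraction, pairs, seed = NULL,
                                intact = 2.9, broken = 4.6) {
  s <- schema_of(traj)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (any(pairs < 1L | pairs > s$n)) stop("pair index out of range", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  M <- nrow(traj)
  hb <- matrix(intact, M, s$n)
  k <- round(fraction * M)
  if (k > 0) hb[sample.int(M, k), pairs] <- broken
  list(traj = traj, hbonds = hb)
}

#' Study sequences
#'
#' The seven 18-bp duplexes of the A-tract study design: a C/G-rich control
#' (from the chicken beta-globin promoter region) and its variants carrying
#' centred symmetric A_nT_n (n = 3, 4, 5) and asymmetric A_2n tracts, all in
#' a 5'-G...C-3' context.
#'
#' @return Named character vector of reference-strand sequences.
#' @export
atract_study_sequences <- function() {
  c(A3T3 = "GCCTGGAAATTTCTGTGC",
    A6 = "GCCTGGAAAAAACTGTGC",
    A4T4 = "GCCTGAAAATTTTCGTGC",
    A8 = "GCCTGAAAAAAAACGTGC",
    A5T5 = "GCCGAAAAATTTTTCTGC",
    A10 = "GCCGAAAAAAAAAACTGC",
    control = "GCCTGGCGCGCGCTGTGC")
}

#' Write a complete synthetic study
#'
#' For each requested sequence, builds the ground-truth model, samples a
#' trajectory, and writes `<name>_truth.json` and `<name>_traj.tsv` into
#' `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param M Snapshots per sequence.
#' @param seed Top-level seed; per-sequence seeds are derived from it.
#' @param sequences Named character vector (default [atract_study_sequences]).
#' @param temperature Kelvin.
#' @return Invisibly, a data frame of written files.
#' @export
simulate_study <- function(dir, M = 2000, seed = 1,
                           sequences = atract_study_sequences(),
                           temperature = default_temperature) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(sequences), function(i) {
    name <- names(sequences)[i] %||% paste0("seq", i)
    gt <- ground_truth_model(sequences[[i]], temperature = temperature)
    tr <- simulate(gt, nsim = M, seed = seed + i)
    truth_path <- file.path(dir, paste0(name, "_truth.json"))
    traj_path <- file.path(dir, paste0(name, "_traj.tsv"))
    write_model(gt, truth_path)
    write_trajectory(tr, traj_path)
    data.frame(name = name, sequence = sequences[[i]],
               truth = truth_path, trajectory = traj_path)
  })
  invisible(do.call(rbind, rows))
}
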