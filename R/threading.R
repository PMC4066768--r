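#' Nucleosome-style template profiles
#'
#' A template is a per-step geometric profile of roll, twist (degrees) and
#' slide (Angstrom) -- the three step coordinates that are strongly
#' conserved among nucleosome structures and are therefore constrained
#' during threading; everything else relaxes. Templates are plain
#' tab-delimited text with columns `step`, `roll`, `twist`, `slide` and `#`
#' comments.
#'
#' @param roll,twist,slide Numeric vectors of equal length (one value per
#'   template step).
#' @param dyad Optional step index annotating the dyad position.
#' @return Object of class `nucleosome_template` (a data frame).
#' @export
nucleosome_template <- function(roll, twist, slide, dyad = NULL) {
  L <- length(roll)
  if (length(twist) != L || length(slide) != L)
    stop("roll, twist and slide must have equal length", call. = FALSE)
  if (!all(is.finite(c(roll, twist, slide))))
    stop("template values must be finite", call. = FALSE)
  out <- data.frame(step = seq_len(L), roll = roll, twist = twist, slide = slide)
  class(out) <- c("nucleosome_template", "data.frame")
  attr(out, "dyad") <- dyad
  out
}

#' @rdname nucleosome_template
#' @param path File path.
#' @export
read_template <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("step", "roll", "twist", "slide")
  if (!all(need %in% names(df)))
    stop("template file must have columns step, roll, twist, slide", call. = FALSE)
  nucleosome_template(df$roll, df$twist, df$slide)
}

#' @rdname nucleosome_template
#' @param template A `nucleosome_template`.
#' @export
write_template <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dnamech template: roll/twist in degrees, slide in Angstrom", con)
  utils::write.table(as.data.frame(template)[, c("step", "roll", "twist", "slide")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Thread a sequence window through a template profile
#'
#' Slides a window of the fitted molecule along the template in 1-bp
#' offsets. At each offset the roll, twist and slide of every step in the
#' window are constrained to the template values while all other
#' coordinates relax; the recorded energy is that of the partially relaxed
#' model, \eqn{\tilde E(t_k) = \tfrac12 (t_k - \hat w_A) \cdot \tilde K
#' (t_k - \hat w_A)}. Because no favourable protein-DNA contacts enter,
#' the energies are upper bounds on the true deformation cost.
#'
#' @param model A [rigid_base_model] in native units.
#' @param template A [nucleosome_template] at least as long as the window.
#' @param window Step indices of the threaded window (default: all steps of
#'   the model after trimming one terminal pair at each end).
#' @return Object of class `threading_profile`: data frame with `offset`
#'   (0-based start position of the window on the template) and `energy`
#'   (kcal/mol).
#' @examples
#' m <- ground_truth_model("GCGAAAAC")
#' tpl <- make_toy_nucleosome_template(L_t = 40, roll_amplitude = 6, seed = 1)
#' pr <- thread(m, tpl)
#' profile_summary(pr)$mean
#' @export
thread <- function(model, template, window = NULL) {
  stopifnot(inherits(model, "rigid_base_model"))
  if (!is.null(model$scaling))
    stop("thread() expects a model in native units", call. = FALSE)
  s <- model$schema
  if (is.null(window)) {
    steps <- sort(unique(s$index[s$kind == "step"]))
    window <- steps[steps > 1L & steps < max(steps)]
    if (length(window) < 1L) window <- steps
  }
  L_w <- length(window)
  L_t <- nrow(template)
  if (L_t < L_w)
    stop(sprintf("template (%d steps) is shorter than the window (%d steps)", L_t, L_w), call. = FALSE)
  # constrained coordinates, ordered (roll, twist, slide) per window step
  A <- unlist(lapply(window, function(j)
    c(coord_index(s, "roll", j), coord_index(s, "twist", j), coord_index(s, "slide", j))))
  rel <- relax(model, A)
  offsets <- 0:(L_t - L_w)
  slices <- vapply(offsets, function(k) {
    rows <- k + seq_len(L_w)
    as.vector(rbind(template$roll[rows], template$twist[rows], template$slide[rows]))
  }, numeric(3L * L_w))
  energy <- deformation_energy(rel, t(slices))
  out <- data.frame(offset = offsets, energy = energy)
  class(out) <- c("threading_profile", "data.frame")
  attr(out, "window") <- window
  out
}

#' Summarize a threading profile
#'
#' Reports the mean and minimum energy, the offset of the minimum, the
#' locations of local minima (after an optional centred moving-average
#' smoothing, window 3), and the dominant spacing between profile features
#' estimated from the first positive-lag peak of the autocorrelation.
#' For an (essentially) constant profile the spacing is undefined and
#' returned as `NA`.
#'
#' @param profile A `threading_profile` (or data frame with `offset`,
#'   `energy`).
#' @param smooth Smoothing window for minima location (odd; 1 disables).
#' @return List: `mean`, `min`, `argmin` (offset), `minima` (offsets),
#'   `spacing` (offsets, `NA` if undefined).
#' @export
profile_summary <- function(profile, smooth = 3) {
  e <- profile$energy
  off <- profile$offset
  if (length(e) < 1L) stop("empty profile", call. = FALSE)
  sm <- if (smooth > 1L && length(e) >= smooth)
    stats::filter(e, rep(1 / smooth, smooth), sides = 2) else e
  sm <- as.numeric(sm)
  interior <- which(!is.na(sm))
  minima <- integer(0)
  for (i in interior) {
    if (i > 1L && i < length(sm) && !is.na(sm[i - 1]) && !is.na(sm[i + 1]) &&
        sm[i] < sm[i - 1] && sm[i] <= sm[i + 1]) minima <- c(minima, i)
  }
  list(
    mean = mean(e),
    min = min(e),
    argmin = off[which.min(e)],
    minima = off[minima],
    spacing = dominant_spacing(e)
  )
}

# dominant periodic spacing of a signal: lag of the first local maximum of
# the autocorrelation at positive lag with a meaningfully positive value.
dominant_spacing <- function(e) {
  if (length(e) < 6L || stats::sd(e) < 1e-12 * (abs(mean(e)) + 1)) return(NA_real_)
  ac <- stats::acf(e, lag.max = length(e) - 2L, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # ac[k + 1] holds lag k; find the first interior local maximum above 0.1
  for (lag in 2:(length(ac) - 2L)) {
    if (ac[lag + 1L] > ac[lag] && ac[lag + 1L] >= ac[lag + 2L] && ac[lag + 1L] > 0.1)
      return(lag)
  }
  NA_real_
}

#' @export
plot.threading_profile <- function(x, ...) {
  graphics::plot(x$offset, x$energy, type = "l",
                 xlab = "offset along template (bp)",
                 ylab = "deformation energy (kcal/mol)", ...)
  invisible(x)
}

#' @rdname thread
#' @param profile A `threading_profile`.
#' @param path Output file (tab-delimited offset/energy).
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dnamech threading profile: energy in kcal/mol, 0-based offsets", con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
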