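#' Rigid-base coordinate names
#'
#' Six intra-basepair coordinates describe the geometry of the two paired
#' bases (buckle, propeller, opening in degrees; shear, stretch, stagger in
#' Angstrom) and six step coordinates describe consecutive base pairs (tilt,
#' roll, twist in degrees; shift, slide, rise in Angstrom), following the
#' 3DNA conventions.
#'
#' @return Character vector of coordinate names.
#' @export
intra_coord_names <- function() c("buckle", "propeller", "opening", "shear", "stretch", "stagger")

#' @rdname intra_coord_names
#' @export
step_coord_names <- function() c("tilt", "roll", "twist", "shift", "slide", "rise")

coord_units <- c(
  buckle = "degree", propeller = "degree", opening = "degree",
  shear = "Angstrom", stretch = "Angstrom", stagger = "Angstrom",
  tilt = "degree", roll = "degree", twist = "degree",
  shift = "Angstrom", slide = "Angstrom", rise = "Angstrom"
)

#' Coordinate schema for an n base-pair duplex
#'
#' Fixes the canonical ordering of the N = 12n - 6 rigid-base coordinates of
#' a duplex of `n` base pairs: the six intra-basepair coordinates of pairs
#' 1..n first, then the six step coordinates of steps 1..n-1. Column names
#' take the form `<coordinate>_<index>` with 1-based pair/step indices.
#'
#' @param n Number of base pairs (>= 2), or a character string over A/C/G/T
#'   giving the reference strand 5'->3' (its length sets `n`).
#' @return An object of class `coord_schema` with elements `n`, `N`,
#'   `sequence` (possibly `NA`), and per-coordinate vectors `name`, `coord`,
#'   `index`, `kind` (`"intra"`/`"step"`) and `unit`.
#' @examples
#' s <- coord_schema(4)
#' s$N                   # 42 coordinates
#' head(s$name)
#' @export
coord_schema <- function(n) {
  sequence <- NA_character_
  if (is.character(n)) {
    sequence <- toupper(n)
    if (!grepl("^[ACGT]+$", sequence))
      stop("sequence must contain only A, C, G, T", call. = FALSE)
    n <- nchar(sequence)
  }
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  intra <- expand.grid(coord = intra_coord_names(), index = seq_len(n),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  step <- expand.grid(coord = step_coord_names(), index = seq_len(n - 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  coord <- c(intra$coord, step$coord)
  index <- c(intra$index, step$index)
  kind <- rep(c("intra", "step"), c(nrow(intra), nrow(step)))
  out <- list(
    n = n, N = 12L * n - 6L, sequence = sequence,
    name = paste0(coord, "_", index),
    coord = coord, index = as.integer(index), kind = kind,
    unit = unname(coord_units[coord])
  )
  stopifnot(length(out$name) == out$N)
  class(out) <- "coord_schema"
  out
}

#' @export
print.coord_schema <- function(x, ...) {
  cat(sprintf("Rigid-base coordinate schema: %d bp, N = %d coordinates\n", x$n, x$N))
  if (!is.na(x$sequence)) cat("  sequence:", x$sequence, "\n")
  cat(sprintf("  %d intra-basepair (pairs 1..%d), %d step (steps 1..%d)\n",
              6L * x$n, x$n, 6L * (x$n - 1L), x$n - 1L))
  invisible(x)
}

#' Locate coordinates in a schema
#'
#' `coord_index()` returns the positions, in canonical order, of the named
#' coordinate at the given pair/step indices. `trim_index()` returns the
#' positions that survive trimming `trim` pairs at each end of the duplex
#' (the trimmed pairs and their flanking steps are dropped); terminal base
#' pairs fray in simulation and are conventionally excluded from analysis.
#'
#' @param schema A [coord_schema].
#' @param coord Coordinate name, e.g. `"twist"`.
#' @param index Pair or step indices (1-based); default all.
#' @return Integer positions into the canonical coordinate vector.
#' @export
coord_index <- function(schema, coord, index = NULL) {
  stopifnot(inherits(schema, "coord_schema"))
  coord <- match.arg(coord, c(intra_coord_names(), step_coord_names()))
  hit <- schema$coord == coord
  if (!is.null(index)) hit <- hit & schema$index %in% index
  out <- which(hit)
  if (!is.null(index) && length(out) != length(index))
    stop(sprintf("index out of range for coordinate '%s'", coord), call. = FALSE)
  out
}

#' @rdname coord_index
#' @param trim Number of base pairs to drop at each end (default 1).
#' @export
trim_index <- function(schema, trim = 1L) {
  stopifnot(inherits(schema, "coord_schema"))
  trim <- as.integer(trim)
  if (trim < 0L || 2L * trim >= schema$n)
    stop("`trim` must satisfy 0 <= 2*trim < n", call. = FALSE)
  if (trim == 0L) return(seq_len(schema$N))
  keep_pairs <- (trim + 1L):(schema$n - trim)
  keep_steps <- (trim + 1L):(schema$n - 1L - trim)
  which((schema$kind == "intra" & schema$index %in% keep_pairs) |
          (schema$kind == "step" & schema$index %in% keep_steps))
}
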