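#' Rigid-base coordinate trajectory
#'
#' A trajectory is an M x N matrix of rigid-base coordinates, one row per
#' snapshot, with columns in the canonical order of a [coord_schema]
#' (angles in degrees, distances in Angstrom).
#'
#' @param values Numeric M x N matrix; column names, if present, must match
#'   the schema (any order -- columns are reordered canonically).
#' @param schema A [coord_schema]; inferred from `ncol(values)` when omitted
#'   (N = 12n - 6 must hold).
#' @param times Optional numeric snapshot times.
#' @return Object of class `coord_trajectory`: the value matrix with
#'   attributes `schema` and `times`.
#' @examples
#' s <- coord_schema(3)
#' tr <- coord_trajectory(matrix(rnorm(5 * s$N), 5), s)
#' dim(tr)
#' @export
coord_trajectory <- function(values, schema = NULL, times = NULL) {
  values <- as.matrix(values)
  if (is.null(schema)) {
    n <- (ncol(values) + 6L) / 12L
    if (n != round(n)) stop("column count is not of the form 12n - 6; supply `schema`", call. = FALSE)
    schema <- coord_schema(n)
  }
  stopifnot(inherits(schema, "coord_schema"))
  if (ncol(values) != schema$N)
    stop(sprintf("trajectory has %d columns but schema expects N = %d", ncol(values), schema$N), call. = FALSE)
  if (!is.null(colnames(values))) {
    pos <- match(schema$name, colnames(values))
    if (anyNA(pos))
      stop("column names do not match the schema: missing ",
           paste(utils::head(schema$name[is.na(pos)], 5), collapse = ", "), call. = FALSE)
    values <- values[, pos, drop = FALSE]
  }
  if (!all(is.finite(values))) stop("trajectory contains non-finite values", call. = FALSE)
  dimnames(values) <- list(NULL, schema$name)
  if (!is.null(times) && length(times) != nrow(values))
    stop("`times` length must equal the snapshot count", call. = FALSE)
  structure(values, schema = schema, times = times,
            class = c("coord_trajectory", "matrix", "array"))
}

#' @export
print.coord_trajectory <- function(x, ...) {
  s <- attr(x, "schema")
  cat(sprintf("Rigid-base coordinate trajectory: %d snapshots x %d coordinates (%d bp)\n",
              nrow(x), ncol(x), s$n))
  invisible(x)
}

#' @rdname coord_trajectory
#' @param x A `coord_trajectory`.
#' @export
schema_of <- function(x) {
  s <- attr(x, "schema")
  if (is.null(s)) stop("object carries no coordinate schema", call. = FALSE)
  s
}

# subset snapshots, keeping attributes
subset_snapshots <- function(traj, keep) {
  coord_trajectory(unclass(traj)[keep, , drop = FALSE], schema_of(traj),
                   times = attr(traj, "times")[keep])
}

#' Filter snapshots on broken Watson-Crick hydrogen bonds
#'
#' Removes every snapshot in which any *interior* base pair has a maximum
#' Watson-Crick donor-acceptor distance above `cutoff` (default 4 Angstrom).
#' Terminal pairs fray frequently and transiently; following common practice
#' they are ignored by the filter (and excluded from analysis separately via
#' [trim_index]).
#'
#' @param traj A [coord_trajectory].
#' @param hbonds M x n numeric matrix: per snapshot, per pair, the maximum
#'   H-bond donor-acceptor distance in Angstrom.
#' @param cutoff Distance above which a pair counts as broken (Angstrom).
#' @param ignore_terminal Ignore pairs 1 and n (default `TRUE`).
#' @param quiet Suppress the removal-fraction message.
#' @return The filtered `coord_trajectory`.
#' @export
filter_snapshots <- function(traj, hbonds, cutoff = 4, ignore_terminal = TRUE,
                             quiet = FALSE) {
  s <- schema_of(traj)
  hbonds <- as.matrix(hbonds)
  if (nrow(hbonds) != nrow(traj) || ncol(hbonds) != s$n)
    stop(sprintf("hbonds must be %d snapshots x %d pairs, got %d x %d",
                 nrow(traj), s$n, nrow(hbonds), ncol(hbonds)), call. = FALSE)
  pairs <- if (ignore_terminal) seq_len(s$n)[-c(1L, s$n)] else seq_len(s$n)
  broken <- rowSums(hbonds[, pairs, drop = FALSE] > cutoff) > 0
  if (!quiet)
    message(sprintf("filter_snapshots: removed %d / %d snapshots (%.2f%%)",
                    sum(broken), length(broken), 100 * mean(broken)))
  subset_snapshots(traj, !broken)
}

#' Read and write trajectory files
#'
#' The trajectory dialect is tab-delimited text: comment lines starting with
#' `#` (units and provenance), then a header row naming every coordinate as
#' `<name>_<index>` (an optional leading `time` column is allowed), then one
#' row per snapshot. Columns may appear in any order; the reader restores the
#' canonical ordering. The write/read round trip is lossless to full double
#' precision.
#'
#' @param path File path.
#' @param schema Optional [coord_schema]; when given, the file header must
#'   contain exactly its coordinates.
#' @return `read_trajectory()` returns a [coord_trajectory];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path, schema = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("trajectory file is empty or has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_time <- header[1] == "time"
  cols <- if (has_time) header[-1] else header
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_exp <- length(header)
  vals <- matrix(NA_real_, length(rows), ncol_exp)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_exp)
      stop(sprintf("row %d has %d fields, expected %d", i + 1L, length(r), ncol_exp), call. = FALSE)
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   r[bad], i, header[bad]), call. = FALSE)
    }
    vals[i, ] <- v
  }
  times <- NULL
  if (has_time) {
    times <- vals[, 1]
    vals <- vals[, -1, drop = FALSE]
  }
  colnames(vals) <- cols
  if (is.null(schema)) {
    idx <- sub("^.*_", "", cols)
    n_guess <- max(suppressWarnings(as.integer(idx)), na.rm = TRUE)
    schema <- coord_schema(n_guess)
  }
  coord_trajectory(vals, schema, times = times)
}

#' @rdname read_trajectory
#' @param traj A [coord_trajectory].
#' @export
write_trajectory <- function(traj, path) {
  s <- schema_of(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dnamech trajectory: %d bp, N = %d coordinates, %d snapshots", s$n, s$N, nrow(traj)),
    "# units: angles in degrees, distances in Angstrom",
    "# ordering: intra-basepair coordinates per pair, then step coordinates per step"
  ), con)
  times <- attr(traj, "times")
  m <- unclass(traj)
  if (!is.null(times)) {
    writeLines(paste(c("time", s$name), collapse = "\t"), con)
    body <- cbind(times, m)
  } else {
    writeLines(paste(s$name, collapse = "\t"), con)
    body <- m
  }
  writeLines(apply(body, 1L, function(r) paste(formatC(r, format = "g", digits = 17), collapse = "\t")), con)
  invisible(path)
}
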