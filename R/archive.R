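#' Model archives and matrix export
#'
#' `write_model()` serializes a [rigid_base_model] to a JSON document
#' (schema, shape vector, row-major stiffness, temperature, scaling
#' metadata) at full double precision; `read_model()` restores it so that
#' the round trip is lossless. `export_matrix()` writes the covariance or
#' stiffness matrix as tab-delimited text for interoperability.
#'
#' @param model A [rigid_base_model].
#' @param path Output file.
#' @return `read_model()` returns the model; the writers return `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rigid_base_model"))
  doc <- list(
    format = "dnamech-rigid-base-model",
    version = 1L,
    n = model$schema$n,
    sequence = if (is.na(model$schema$sequence)) NULL else model$schema$sequence,
    coordinates = model$schema$name,
    temperature = model$temperature,
    M = if (is.na(model$M)) NULL else model$M,
    scaling = model$scaling,
    w_hat = unname(model$w_hat),
    K = as.vector(t(model$K)),       # row-major
    C = as.vector(t(model$C))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dnamech-rigid-base-model"))
    stop("not a dnamech model archive: ", path, call. = FALSE)
  schema <- coord_schema(if (!is.null(doc$sequence)) doc$sequence else doc$n)
  if (!identical(schema$name, doc$coordinates)) {
    # a relaxed model: rebuild the reduced schema from the parent
    A <- match(doc$coordinates, schema$name)
    if (anyNA(A)) stop("archive coordinates do not match any schema over n = ", doc$n, call. = FALSE)
    schema <- subset_schema(schema, A)
  }
  Np <- length(doc$coordinates)
  K <- matrix(doc$K, Np, Np, byrow = TRUE)
  C <- matrix(doc$C, Np, Np, byrow = TRUE)
  scaling <- if (is.null(doc$scaling) || length(doc$scaling) == 0) NULL else doc$scaling
  new_rigid_base_model(schema, doc$w_hat, K, C, doc$temperature,
                       M = doc$M %||% NA_integer_, scaling = scaling)
}

#' @rdname write_model
#' @param which `"K"` (stiffness) or `"C"` (covariance).
#' @export
export_matrix <- function(model, path, which = c("K", "C")) {
  which <- match.arg(which)
  M <- model[[which]]
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
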