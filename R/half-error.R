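#' Half-trajectory error estimate
#'
#' A simple convergence diagnostic for statistics of a time series: the
#' statistic is evaluated on the full trajectory and on each half, and the
#' error is the mean absolute difference between the full-trajectory value
#' and the two half values. Vector-valued statistics are supported; errors
#' are reported component-wise.
#'
#' @param statistic Function of a trajectory (or matrix) returning a numeric
#'   scalar or vector.
#' @param traj A [coord_trajectory], matrix, or numeric vector; the first
#'   dimension indexes snapshots (M >= 4).
#' @param ... Passed on to `statistic`.
#' @return List with `value` (full-trajectory statistic) and `half_error`
#'   (non-negative, same shape).
#' @examples
#' half_trajectory_error(mean, c(1, 1, 3, 3))  # value 2, error 1
#' @export
half_trajectory_error <- function(statistic, traj, ...) {
  take <- function(x, idx) {
    if (inherits(x, "coord_trajectory")) subset_snapshots(x, idx)
    else if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE]
    else x[idx]
  }
  M <- if (is.null(dim(traj))) length(traj) else nrow(traj)
  if (M < 4L) stop("need at least 4 snapshots for a half-trajectory error", call. = FALSE)
  halves <- list(seq_len(M %/% 2L), (M %/% 2L + 1L):M)
  full <- statistic(traj, ...)
  hv <- lapply(halves, function(idx) {
    tryCatch(statistic(take(traj, idx), ...), error = function(e)
      stop("statistic failed on a half trajectory: ", conditionMessage(e), call. = FALSE))
  })
  err <- (abs(full - hv[[1]]) + abs(full - hv[[2]])) / 2
  list(value = full, half_error = err)
}
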