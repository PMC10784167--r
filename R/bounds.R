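#' Box constraints for the optimizers
#'
#' A set of per-dimension lower/upper limits defining the rectangular search
#' domain. All optimizer positions are kept inside these limits by projection
#' (see [clamp_to_bounds()]).
#'
#' @param lower Numeric vector of lower limits, one per dimension.
#' @param upper Numeric vector of upper limits, same length as `lower`.
#'
#' @return An object of class `fox_bounds` with elements `lower`, `upper`
#'   and `dim`.
#' @examples
#' b <- bounds(rep(-100, 10), rep(100, 10))
#' b$dim
#' @export
bounds <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  }
  if (length(lower) < 1L) {
    stop("bounds must have at least one dimension", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    bad <- which(lower >= upper)[1L]
    stop(sprintf(
      "invalid bounds: lower[%d] = %g is not below upper[%d] = %g",
      bad, lower[bad], bad, upper[bad]
    ), call. = FALSE)
  }
  structure(
    list(lower = lower, upper = upper, dim = length(lower)),
    class = "fox_bounds"
  )
}

#' @export
print.fox_bounds <- function(x, ...) {
  cat(sprintf("<fox_bounds> %d dimension(s)\n", x$dim))
  show <- min(x$dim, 6L)
  for (d in seq_len(show)) {
    cat(sprintf("  [%g, %g]\n", x$lower[d], x$upper[d]))
  }
  if (x$dim > show) cat(sprintf("  ... and %d more\n", x$dim - show))
  invisible(x)
}

#' Project a position onto the search box
#'
#' Coordinates outside the box are moved to the nearest boundary; coordinates
#' inside are unchanged.
#'
#' @param position Numeric vector (one position) or matrix (rows = agents).
#' @param bounds A [bounds()] object.
#' @return Clamped position of the same shape as the input.
#' @examples
#' clamp_to_bounds(c(-3, 0.5), bounds(c(-1, -1), c(1, 1)))
#' @export
clamp_to_bounds <- function(position, bounds) {
  stopifnot(inherits(bounds, "fox_bounds"))
  if (is.matrix(position)) {
    if (ncol(position) != bounds$dim) {
      stop("position matrix has wrong number of columns", call. = FALSE)
    }
    lo <- matrix(bounds$lower, nrow(position), bounds$dim, byrow = TRUE)
    hi <- matrix(bounds$upper, nrow(position), bounds$dim, byrow = TRUE)
    return(pmin(pmax(position, lo), hi))
  }
  if (length(position) != bounds$dim) {
    stop("position has wrong length for these bounds", call. = FALSE)
  }
  pmin(pmax(position, bounds$lower), bounds$upper)
}

# uniform sample of n positions inside the box; rows are agents
sample_in_bounds <- function(n, bounds) {
  m <- matrix(stats::runif(n * bounds$dim), n, bounds$dim)
  lo <- matrix(bounds$lower, n, bounds$dim, byrow = TRUE)
  hi <- matrix(bounds$upper, n, bounds$dim, byrow = TRUE)
  lo + m * (hi - lo)
}
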