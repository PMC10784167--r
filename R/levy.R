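#' Levy step-scale closed form
#'
#' Standard deviation of the numerator Gaussian in the Mantegna construction
#' of a heavy-tailed (Levy-stable-like) step with index `xi`:
#' \deqn{\sigma = \left[\frac{\Gamma(1+\xi)\,\sin(\pi\xi/2)}
#'   {\Gamma((1+\xi)/2)\,\xi\,2^{(\xi-1)/2}}\right]^{1/\xi}}
#' At `xi = 1` every factor reduces to 1 and `sigma == 1` exactly.
#'
#' @param xi Levy index in `(0, 2]`.
#' @return The scalar step scale `sigma > 0`.
#' @examples
#' levy_sigma(1)    # exactly 1
#' levy_sigma(1.5)  # ~0.6966
#' @export
levy_sigma <- function(xi) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0 || xi > 2) {
    stop("`xi` must be a single number in (0, 2]", call. = FALSE)
  }
  num <- gamma(1 + xi) * sin(pi * xi / 2)
  den <- gamma((1 + xi) / 2) * xi * 2^((xi - 1) / 2)
  (num / den)^(1 / xi)
}

#' Draw one Levy-flight step vector
#'
#' Each component is `w = A / |B|^(1/xi)` with `A ~ N(0, sigma^2)` and
#' `B ~ N(0, 1)`; `|B|` is floored at `1e-12` so the step is always finite.
#' For `xi = 3/2` the resulting `|w|` has a heavy tail of index about 1.5:
#' occasional very long jumps that let the exploration phase escape local
#' optima.
#'
#' @param dim Number of components to draw.
#' @param params A [levy_params()] object.
#' @return Numeric vector of length `dim`.
#' @examples
#' set.seed(1)
#' levy_step(5, levy_params(1.5))
#' @export
levy_step <- function(dim, params = levy_params()) {
  stopifnot(inherits(params, "levy_params"))
  dim <- as.integer(dim)
  if (dim < 1L) stop("`dim` must be at least 1", call. = FALSE)
  A <- stats::rnorm(dim, 0, params$sigma)
  B <- stats::rnorm(dim)
  A / pmax(abs(B), 1e-12)^(1 / params$xi)
}

# matrix of n x dim Levy steps; draw order fixed (A block, then B block)
levy_step_matrix <- function(n, dim, params) {
  A <- matrix(stats::rnorm(n * dim, 0, params$sigma), n, dim)
  B <- matrix(stats::rnorm(n * dim), n, dim)
  A / pmax(abs(B), 1e-12)^(1 / params$xi)
}
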