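#' Power-law dispersal kernel specification
#'
#' Defines the fat-tailed jump kernel \eqn{J(r) = \mu r^{-(1+\mu)}} on
#' \eqn{r \ge 1}, normalised so that \eqn{\int_1^\infty J(r)\,dr = 1}.
#' The exponent `mu` controls the heaviness of the tail: small `mu` means
#' long jumps are common (approaching panmixia as `mu -> 0`), large `mu`
#' recovers effectively short-ranged, wavelike spread.
#'
#' @param mu Kernel exponent, a positive real.  `mu > 0` is required for the
#'   kernel to be normalisable.
#' @param dim Habitat dimension, 1 or 2.
#' @return An object of class `"kernel_spec"`.
#' @examples
#' k <- kernel_spec(mu = 1.5, dim = 1)
#' sample_jump_distance(k, c(1, 0.25))
#' @export
kernel_spec <- function(mu, dim = 1L) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("mu must be a single positive number")
  dim <- as.integer(dim)
  if (!dim %in% c(1L, 2L)) stop("dim must be 1 or 2")
  structure(list(mu = as.numeric(mu), dim = dim), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Power-law jump kernel J(r) = %.3g * r^-(1+%.3g), r >= 1, d = %d\n",
              x$mu, x$mu, x$dim))
  invisible(x)
}

#' Transform uniform variates into jump distances
#'
#' Inverse-CDF sampling of the power-law kernel: a uniform variate
#' \eqn{u \in (0, 1]} maps to \eqn{r = u^{-1/\mu}}, which has density
#' \eqn{\mu r^{-(1+\mu)}} on \eqn{[1, \infty)}.  `u = 1` gives the lower
#' support edge `r = 1`; `u -> 0` gives unboundedly long jumps.
#'
#' @param kernel A [kernel_spec()].
#' @param u Numeric vector of uniform variates in `(0, 1]`.
#' @return Jump distances, same length as `u`, all `>= 1`.
#' @export
sample_jump_distance <- function(kernel, u) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u > 1))
    stop("u must lie in (0, 1]")
  u^(-1 / kernel$mu)
}

#' Sample integer jump offsets on the lattice
#'
#' Draws a jump distance from the kernel, a direction uniform on the unit
#' sphere (a fair sign in 1D, a uniform angle in 2D), and rounds each real
#' component to the nearest integer to obtain a lattice offset.  Because
#' `r >= 1`, the offset is never the zero vector: in 1D the rounded distance
#' is at least 1, and in 2D the largest component magnitude is at least
#' \eqn{r/\sqrt 2 \ge 0.707 > 0.5}.
#'
#' Uses R's random number stream (`set.seed()` controls reproducibility).
#'
#' @param kernel A [kernel_spec()].
#' @param n Number of offsets to draw.
#' @return An `n` by `dim` matrix of integer-valued offsets (stored as
#'   doubles: heavy tails can exceed integer range).
#' @export
sample_jump_offset <- function(kernel, n = 1L) {
  stopifnot(inherits(kernel, "kernel_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  r <- sample_jump_distance(kernel, 1 - runif(n))  # (0,1] variates
  if (kernel$dim == 1L) {
    off <- matrix(round(r * sample(c(-1, 1), n, replace = TRUE)), ncol = 1L)
  } else {
    theta <- runif(n, 0, 2 * pi)
    off <- cbind(round(r * cos(theta)), round(r * sin(theta)))
  }
  off
}
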