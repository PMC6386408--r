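#' Equal-clone tessellation fixture
#'
#' Builds a deterministic labelled lattice of `n_clones` equal contiguous
#' clones (1D segments, or vertical stripes in 2D), with each clone's
#' origin at its segment centre.  This is the geometry underlying the
#' equal-clone null model for subrange statistics, and a convenient
#' synthetic input for every analysis stage.
#'
#' @param L Linear range size.
#' @param n_clones Number of clones; must divide `L` exactly.
#' @param dim Habitat dimension (1 or 2).
#' @return A synthetic `"sweep_result"` (config fields `mu`, `u_tilde`,
#'   `seed` are `NA`; `synthetic = TRUE` is recorded in the config).
#' @examples
#' fx <- make_tessellation_fixture(1000, 10)
#' table(clone_masses(fx))
#' @export
make_tessellation_fixture <- function(L, n_clones, dim = 1L) {
  L <- as.integer(L); n_clones <- as.integer(n_clones)
  dim <- as.integer(dim)
  if (!dim %in% c(1L, 2L)) stop("dim must be 1 or 2")
  if (n_clones < 1L || L %% n_clones != 0L)
    stop("n_clones must divide L exactly")
  seg <- L %/% n_clones
  centres <- (seq_len(n_clones) - 1L) * seg + seg %/% 2L

  if (dim == 1L) {
    grid <- rep(seq_len(n_clones), each = seg)
    origins <- data.frame(allele = seq_len(n_clones), x = centres,
                          time = as.numeric(seq_len(n_clones)))
  } else {
    grid <- matrix(rep(rep(seq_len(n_clones), each = seg), times = L),
                   nrow = L)  # vertical stripes: allele depends on x only
    origins <- data.frame(allele = seq_len(n_clones), x = centres,
                          y = rep(L %/% 2L, n_clones),
                          time = as.numeric(seq_len(n_clones)))
  }

  structure(list(
    grid = grid,
    origins = origins,
    event_counts = c(mutations = NA_real_, migrations_successful = NA_real_,
                     migrations_failed = NA_real_),
    total_time = NA_real_,
    config = list(L = L, dim = dim, mu = NA_real_, u_tilde = NA_real_,
                  seed = NA_integer_, synthetic = TRUE)
  ), class = "sweep_result")
}

#' Sample allele frequencies from the hard-cutoff ansatz
#'
#' Draws frequencies from the normalised density proportional to
#' \eqn{x^p} on \eqn{(0, x_c]} (inverse-CDF: \eqn{x = x_c U^{1/(p+1)}}),
#' the per-allele frequency law implied by the power-law spectrum ansatz.
#' Requires `p > -1`.
#'
#' @param n Number of frequencies.
#' @param p Power-law exponent (`> -1`).
#' @param x_c Cutoff frequency in `(0, 1]`.
#' @return Frequencies in `(0, x_c]`.
#' @export
rfreq_ansatz <- function(n, p, x_c) {
  if (p <= -1) stop("p must exceed -1 for a normalisable density")
  if (x_c <= 0 || x_c > 1) stop("x_c must be in (0, 1]")
  x_c * runif(n)^(1 / (p + 1))
}

#' Clone-mass fixture drawn from a prescribed size density
#'
#' Draws `n_clones` relative clone sizes from a density (either the
#' ansatz parameters `p`, `x_c`, or an arbitrary sampler function),
#' rescales them to total `L^dim`, and rounds to integers with the
#' largest-remainder method so the masses sum to `L^dim` exactly.  Clones
#' rounded to zero mass are dropped.  Used for round-trip testing of
#' spectrum estimation and ansatz fitting without running sweeps.
#'
#' @param n_clones Number of clones to draw.
#' @param L Linear range size.
#' @param dim Habitat dimension.
#' @param p,x_c Ansatz parameters (used when `rsize` is `NULL`).
#' @param rsize Optional sampler `function(n)` returning positive relative
#'   sizes.
#' @return Integer vector of clone masses summing exactly to `L^dim`.
#' @examples
#' m <- make_spectrum_fixture(200, L = 1e5, p = 0, x_c = 0.1)
#' sum(m) == 1e5
#' @export
make_spectrum_fixture <- function(n_clones, L, dim = 1L, p = 0, x_c = 0.1,
                                  rsize = NULL) {
  n_clones <- as.integer(n_clones)
  if (n_clones < 1L) stop("n_clones must be >= 1")
  N <- as.numeric(L)^as.integer(dim)
  s <- if (is.null(rsize)) rfreq_ansatz(n_clones, p, x_c) else rsize(n_clones)
  if (any(!is.finite(s)) || any(s <= 0) || sum(s) <= 0)
    stop("degenerate size density: sampled sizes must be positive and finite")
  w <- s / sum(s) * N
  base <- floor(w)
  short <- as.integer(round(N - sum(base)))
  frac_order <- order(w - base, decreasing = TRUE)
  add <- integer(n_clones)
  if (short > 0L) add[frac_order[seq_len(short)]] <- 1L
  m <- as.integer(base + add)
  m <- m[m > 0L]
  stopifnot(sum(m) == N)
  m
}
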