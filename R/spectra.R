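#' Allele frequency spectrum of clone masses
#'
#' Estimates \eqn{f(x)}, the expected number of alleles per unit frequency
#' at population frequency `x = X / L^dim`, from one or more simulations.
#' Frequencies are histogrammed in logarithmic bins spanning
#' `[1 / L^dim, 1]` (the hard lower cutoff at one deme causes a known
#' uptick in the lowest bin, which is reported as-is), counts are divided
#' by the linear bin width, and densities are averaged across simulations.
#' The normalisation is \eqn{\int x f(x)\,dx = 1}.
#'
#' @param masses A list of per-simulation integer mass vectors (a single
#'   vector, `"sweep_result"`, `"sweep_ensemble"` or list of results is
#'   also accepted).  Each simulation's masses must sum to `L^dim`.
#' @param L Linear range size.
#' @param dim Habitat dimension.
#' @param n_bins Number of logarithmic bins (default 50).
#' @return A `"frequency_spectrum"`: data frame with bin edges `x_lo`,
#'   `x_hi`, geometric centre `x_mid`, density `f`, the mean count per
#'   simulation, and the within-bin mean frequency `x_bar`; attributes
#'   hold `L`, `dim`, `n_sims` and the ensemble-average clone mass
#'   `X_ave`.
#' @examples
#' fs <- frequency_spectrum(list(c(600, 300, 100)), L = 1000)
#' spectrum_normalization(fs)  # 1
#' @export
frequency_spectrum <- function(masses, L, dim = 1L, n_bins = 50L) {
  masses <- as_mass_list(masses)
  dim <- as.integer(dim)
  N <- as.numeric(L)^dim
  sums <- vapply(masses, sum, 1.0)
  if (any(sums != N))
    stop("each simulation's clone masses must sum to L^dim")

  edges <- exp(seq(log(1 / N), log(1), length.out = n_bins + 1L))
  edges[1L] <- 1 / N; edges[n_bins + 1L] <- 1 + 1e-12  # top bin closed
  widths <- diff(edges)

  binned <- vapply(masses, function(m) {
    x <- m[m > 0] / N
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    cbind(tabulate(b, nbins = n_bins),
          vapply(seq_len(n_bins), function(i) sum(x[b == i]), 1.0))
  }, matrix(0, n_bins, 2L))
  binned <- array(binned, c(n_bins, 2L, length(masses)))
  mean_counts <- rowMeans(matrix(binned[, 1L, ], nrow = n_bins))
  sum_x <- rowSums(matrix(binned[, 2L, ], nrow = n_bins))

  structure(data.frame(x_lo = edges[seq_len(n_bins)],
                       x_hi = edges[-1L],
                       x_mid = sqrt(edges[seq_len(n_bins)] * edges[-1L]),
                       f = mean_counts / widths,
                       count = mean_counts,
                       x_bar = ifelse(mean_counts > 0,
                                      sum_x / (mean_counts * length(masses)),
                                      NA_real_)),
            class = c("frequency_spectrum", "data.frame"),
            L = as.numeric(L), habitat_dim = dim, n_sims = length(masses),
            X_ave = mean(vapply(masses, function(m) mean(m[m > 0]), 1.0)))
}

# normalise the many accepted input shapes to a list of mass vectors
as_mass_list <- function(x) {
  if (inherits(x, "sweep_result")) return(list(clone_masses(x)))
  if (inherits(x, "sweep_ensemble") ||
      (is.list(x) && length(x) && inherits(x[[1L]], "sweep_result")))
    return(lapply(x, clone_masses))
  if (is.numeric(x)) return(list(x))
  if (is.list(x) && all(vapply(x, is.numeric, TRUE))) return(x)
  stop("cannot interpret input as clone-mass lists")
}

#' Integral checks on an estimated spectrum
#'
#' `spectrum_normalization()` evaluates \eqn{\int x f(x) dx} using the
#' recorded within-bin mean frequencies, so a correctly binned spectrum
#' integrates to 1 up to floating-point error.
#' `p_hard_spectrum()` evaluates \eqn{\int x^j f(x) dx}, the monoallelic
#' sampling probability computed from the binned spectrum (a cross-check
#' of [p_hard_global()]).
#'
#' @param spectrum A `"frequency_spectrum"`.
#' @param j Sample size (`>= 2`), may be a vector.
#' @return A numeric scalar (or vector over `j`).
#' @export
spectrum_normalization <- function(spectrum) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  w <- spectrum$x_hi - spectrum$x_lo
  ok <- is.finite(spectrum$x_bar)
  sum(spectrum$f[ok] * w[ok] * spectrum$x_bar[ok])
}

#' @rdname spectrum_normalization
#' @export
p_hard_spectrum <- function(spectrum, j) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  if (any(j < 2)) stop("sample size j must be >= 2")
  w <- spectrum$x_hi - spectrum$x_lo
  lr <- log(spectrum$x_hi / spectrum$x_lo)
  vapply(j, function(jj)
    sum(spectrum$f * w * (spectrum$x_hi^jj - spectrum$x_lo^jj) / (jj * lr)),
    1.0)
}

#' Rescale a frequency spectrum by the average clone mass
#'
#' Under self-similarity of sweep patterns, the dependence of \eqn{f(x)}
#' on mutation rate and range size is carried entirely by the ratio
#' `L^dim / X_ave`: plotting \eqn{(X_{ave}/L^d)^2 f(x)} against
#' \eqn{s = L^d x / X_{ave}} collapses spectra for the same kernel at
#' different mutation rates onto one curve.  The change of variables
#' preserves the normalisation: \eqn{\int s\,g(s)\,ds = 1}.
#'
#' @param spectrum A `"frequency_spectrum"`.
#' @param X_ave Average clone mass; defaults to the spectrum's estimate.
#' @return A `"rescaled_spectrum"` data frame with columns `s_lo`, `s_hi`,
#'   `s_mid`, `g` and `count`.
#' @export
rescale_spectrum <- function(spectrum, X_ave = NULL) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  if (is.null(X_ave)) X_ave <- attr(spectrum, "X_ave")
  if (!is.numeric(X_ave) || X_ave <= 0) stop("X_ave must be positive")
  N <- attr(spectrum, "L")^attr(spectrum, "habitat_dim")
  k <- N / X_ave
  structure(data.frame(s_lo = k * spectrum$x_lo,
                       s_hi = k * spectrum$x_hi,
                       s_mid = k * spectrum$x_mid,
                       g = spectrum$f / k^2,
                       count = spectrum$count),
            class = c("rescaled_spectrum", "data.frame"),
            X_ave = X_ave, L = attr(spectrum, "L"),
            habitat_dim = attr(spectrum, "habitat_dim"),
            n_sims = attr(spectrum, "n_sims"))
}

#' Fit the hard-cutoff power-law ansatz to a spectrum
#'
#' Approximates a (rescaled) frequency spectrum by
#' \eqn{f(x) = \frac{p+2}{x_c^{p+2}} x^p} for \eqn{x < x_c} and 0 beyond:
#' a power law with exponent `p` (restricted to \eqn{[-1, 1]} by the
#' panmictic and wavelike limiting spectra \eqn{f_\infty \sim x^{-1}} and
#' \eqn{f_w \sim x}) truncated at a cutoff frequency `x_c`.  The cutoff is
#' located where the numerical second derivative of the log-log curve
#' first drops below -4 (no crossing: the top of the support, flagged);
#' the exponent is the least-squares log-log slope over bins between the
#' 5th percentile of the populated support and `x_c / 3`, a window that
#' avoids both the lowest-bin artifact and the cutoff shoulder.
#'
#' @param spectrum A `"rescaled_spectrum"` (fit in scaled frequency `s`)
#'   or a `"frequency_spectrum"` (fit in raw frequency `x`).
#' @param d2_threshold Second-derivative threshold locating the cutoff.
#' @return An `"ansatz_fit"`: list with `p` (clamped to `[-1, 1]`),
#'   `p_raw`, `x_c`, the fit window, number of window bins, and
#'   `cutoff_found`.
#' @export
fit_ansatz <- function(spectrum, d2_threshold = -4) {
  if (inherits(spectrum, "rescaled_spectrum")) {
    x <- spectrum$s_mid; y <- spectrum$g
  } else if (inherits(spectrum, "frequency_spectrum")) {
    x <- spectrum$x_mid; y <- spectrum$f
  } else stop("need a frequency_spectrum or rescaled_spectrum")
  cnt <- spectrum$count
  pop <- which(is.finite(y) & y > 0)
  if (length(pop) < 10L) stop("need at least 10 populated bins")
  lx <- log(x[pop]); ly <- log(y[pop])

  # cutoff: first scaled frequency where d2(log f)/d(log x)^2 < threshold,
  # evaluated on a count-weighted smoothing spline (raw second differences
  # of sparse log-binned histograms are dominated by shot noise)
  x_c <- NA_real_; found <- FALSE
  sm <- tryCatch(
    stats::smooth.spline(lx, ly, w = pmax(cnt[pop], 0.5),
                         df = max(5L, min(10L, length(pop) - 2L))),
    error = function(e) NULL)
  if (!is.null(sm)) {
    grid <- seq(min(lx), max(lx), length.out = 200L)
    d2 <- stats::predict(sm, grid, deriv = 2L)$y
    # the cutoff shoulder is the point of steepest downward log-log
    # curvature; it counts as a cutoff only if the curvature passes the
    # threshold (isolated noise dips elsewhere stay above it after the
    # count-weighted smoothing)
    i_min <- which.min(d2)
    if (is.finite(d2[i_min]) && d2[i_min] < d2_threshold) {
      x_c <- exp(grid[i_min]); found <- TRUE
    }
  }
  if (!found) x_c <- max(x[pop])

  win_lo <- exp(quantile(lx, 0.05, names = FALSE))
  win <- pop[x[pop] >= win_lo & x[pop] <= x_c / 3]
  if (length(win) < 3L)  # narrow support: extend the window to the cutoff
    win <- pop[x[pop] >= win_lo & x[pop] <= x_c]
  if (length(win) < 2L) stop("too few bins below the cutoff to fit a slope")
  fit <- lm(log(y[win]) ~ log(x[win]))
  p_raw <- unname(coef(fit)[2L])

  structure(list(p = max(-1, min(1, p_raw)), p_raw = p_raw, x_c = x_c,
                 window = range(x[win]), n_window = length(win),
                 cutoff_found = found),
            class = "ansatz_fit")
}

#' @export
print.ansatz_fit <- function(x, ...) {
  cat(sprintf("Power-law ansatz fit: p = %.3f (raw %.3f), x_c = %.4g%s\n",
              x$p, x$p_raw, x$x_c,
              if (x$cutoff_found) "" else " [no cutoff found; top of support]"))
  cat(sprintf("  slope window [%.3g, %.3g], %d bins\n",
              x$window[1L], x$window[2L], x$n_window))
  invisible(x)
}

#' Probability of a monoallelic global sample
#'
#' The probability that a random sample of `j` individuals drawn with
#' replacement from the whole range contains a single allele (a "hard"
#' sweep signal): per simulation \eqn{\sum_i x_i^j} over allele
#' frequencies, averaged across simulations.  Identical to
#' \eqn{\int x^j f(x) dx} up to binning (see [p_hard_spectrum()]).
#'
#' @inheritParams frequency_spectrum
#' @param j Sample size (`>= 2`), may be a vector.
#' @return Probability (or vector over `j`).
#' @export
p_hard_global <- function(masses, L, dim = 1L, j = 2L) {
  masses <- as_mass_list(masses)
  if (any(j < 2)) stop("sample size j must be >= 2")
  N <- as.numeric(L)^as.integer(dim)
  vapply(j, function(jj)
    mean(vapply(masses, function(m) sum((m[m > 0] / N)^jj), 1.0)), 1.0)
}

#' Scale a hard-sweep probability by the equal-clone expectation
#'
#' Divides `P_hard(j)` by \eqn{(X_{ave}/L^d)^{j-1}}, the value expected if
#' all clones had identical mass `X_ave`.  Ratios above 1 quantify how
#' much the breadth of the clone-size distribution, beyond the average
#' size, favours monoallelic samples.
#'
#' @param p_hard Probability value(s) from [p_hard_global()].
#' @param X_ave Average clone mass.
#' @param L,dim Range geometry.
#' @param j Sample size(s) matching `p_hard`.
#' @return Scaled value(s).
#' @export
p_hard_scaled <- function(p_hard, X_ave, L, dim = 1L, j) {
  N <- as.numeric(L)^as.integer(dim)
  p_hard / (X_ave / N)^(j - 1)
}

#' Ewens monoallelic sampling probability
#'
#' In the panmictic (infinite-alleles) limit the probability that a sample
#' of size `j` is monoallelic is \eqn{\prod_{i=1}^{j-1} i/(\theta + i)}
#' from Ewens sampling theory, with scaled mutation rate `theta`.
#'
#' @param theta Scaled mutation rate (`> 0`).
#' @param j Sample size (`>= 2`), may be a vector.
#' @return Probability (or vector over `j`).
#' @examples
#' ewens_p_hard(1, 2:3)  # 1/2, 1/3
#' @export
ewens_p_hard <- function(theta, j) {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")
  if (any(j < 2) || any(j != round(j))) stop("j must be an integer >= 2")
  vapply(j, function(jj) {
    i <- seq_len(jj - 1L)
    prod(i / (theta + i))
  }, 1.0)
}

# shared sliding-window scan over a periodic 1D lattice: returns the mean
# homoallelicity sum(n_a^2)/L_s^2 and the mean distinct-allele count over
# the requested window starts (0-based)
subrange_scan <- function(grid, L_s, starts) {
  L <- length(grid)
  n_alleles <- max(grid)
  idx0 <- seq_len(L_s)
  hom <- num <- numeric(length(starts))
  o <- order(starts)
  starts <- starts[o]
  tab <- tabulate(grid[idx0], nbins = n_alleles)
  sumsq <- sum(as.numeric(tab)^2)  # double: counts^2 can exceed integer range
  ndist <- sum(tab > 0L)
  at <- 0L  # current window start
  for (k in seq_along(starts)) {
    s <- starts[k]
    while (at < s) {
      out <- grid[at + 1L]
      inn <- grid[(at + L_s) %% L + 1L]
      if (out != inn) {
        sumsq <- sumsq + 2L * tab[inn] + 1L - 2L * tab[out] + 1L
        tab[out] <- tab[out] - 1L
        tab[inn] <- tab[inn] + 1L
        if (tab[out] == 0L) ndist <- ndist - 1L
        if (tab[inn] == 1L) ndist <- ndist + 1L
      }
      at <- at + 1L
    }
    hom[k] <- sumsq / L_s^2
    num[k] <- ndist
  }
  list(homoallelicity = mean(hom), n_distinct = mean(num))
}

resolve_windows <- function(L, L_s, n_windows) {
  if (is.null(n_windows)) 0:(L - 1L)
  else sample.int(L, min(n_windows, L)) - 1L
}

#' Subrange homoallelicity
#'
#' The probability `P_hard_s(2)` that two individuals drawn (with
#' replacement) from a contiguous subrange of linear size `L_s` carry the
#' same allele: \eqn{\sum_a (n_a/L_s)^2} over allele counts inside the
#' window, averaged over window placements and simulations.  High values
#' mean the window sits inside a single clone's core; overlapping haloes
#' from long-range dispersal suppress it.
#'
#' @param x A `"sweep_result"`, list/ensemble of them, or a 1D integer
#'   lattice of allele labels.
#' @param L_s Subrange size, `1 <= L_s <= L`.
#' @param n_windows Number of uniformly placed windows per lattice;
#'   `NULL` (default) scans every placement exhaustively.  Random
#'   placements use R's random stream.
#' @return The averaged homoallelicity.
#' @seealso [null_equal_clones()] for the equal-clone null expectation,
#'   [subrange_allele_count()].
#' @export
subrange_homoallelicity <- function(x, L_s, n_windows = NULL) {
  grids <- as_grid_list(x)
  L <- length(grids[[1L]])
  L_s <- as.integer(L_s)
  if (L_s < 1L || L_s > L) stop("L_s must be in [1, L]")
  mean(vapply(grids, function(g)
    subrange_scan(g, L_s, resolve_windows(L, L_s, n_windows))$homoallelicity,
    1.0))
}

#' Mean number of distinct alleles in a subrange
#'
#' The average count `n_c_s` of distinct allele labels inside contiguous
#' windows of size `L_s`, over window placements and simulations.  For
#' windows larger than twice the typical clone extent the count follows
#' `L_s / (2 <r_eq>)`; smaller windows pick up extra alleles from
#' encroaching haloes.
#'
#' @inheritParams subrange_homoallelicity
#' @return The averaged distinct-allele count.
#' @export
subrange_allele_count <- function(x, L_s, n_windows = NULL) {
  grids <- as_grid_list(x)
  L <- length(grids[[1L]])
  L_s <- as.integer(L_s)
  if (L_s < 1L || L_s > L) stop("L_s must be in [1, L]")
  mean(vapply(grids, function(g)
    subrange_scan(g, L_s, resolve_windows(L, L_s, n_windows))$n_distinct,
    1.0))
}

as_grid_list <- function(x) {
  grab <- function(r) {
    if (r$config$dim != 1L)
      stop("subrange statistics are implemented for 1D lattices")
    as.integer(r$grid)
  }
  if (inherits(x, "sweep_result")) return(list(grab(x)))
  if (is.list(x) && length(x) && inherits(x[[1L]], "sweep_result"))
    return(lapply(x, grab))
  if (is.numeric(x)) return(list(as.integer(x)))
  stop("cannot interpret input as 1D lattice(s)")
}

#' Equal-clone null model for subrange homoallelicity
#'
#' If the range is tessellated into perfectly contiguous clones of equal
#' size `X_ave`, window geometry alone dictates the pair homoallelicity as
#' a function of `x = L_s / X_ave`:
#' \eqn{1 - x/3} for `x < 1` and \eqn{1/x - 1/(3x^2)} for `x >= 1`
#' (continuous at `x = 1`, both branches giving 2/3).
#'
#' @param x Ratio of subrange size to clone size (`> 0`), may be a vector.
#' @return The null homoallelicity.
#' @export
null_equal_clones <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive")
  ifelse(x < 1, 1 - x / 3, 1 / x - 1 / (3 * x^2))
}
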