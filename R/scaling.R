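#' @keywords internal
growth_regime <- function(mu, dim) {
  if (mu < dim) "stretched"
  else if (mu == dim) "marginal"
  else if (mu < dim + 1) "power"
  else if (mu == dim + 1) "marginal_upper"
  else "linear"
}

#' Asymptotic growth law for the core radius
#'
#' Constructs a `"growth_law"` from the long-time asymptotic form of
#' \eqn{\ell(t)} appropriate to the kernel regime, with free magnitude
#' factors `A` (length) and `B` (time):
#' \tabular{ll}{
#'   `mu < dim` \tab \eqn{\ell = A\exp(B_\mu (t/B)^\eta)},
#'     \eqn{\eta = \log[4d/(d+\mu)]/\log 2 > 1},
#'     \eqn{B_\mu = 2d\log 2/(\mu-d)^2} \cr
#'   `mu == dim` \tab \eqn{\ell = A\exp(c\,\log^2(t/B))} (marginal; `c` free) \cr
#'   `dim < mu < dim+1` \tab \eqn{\ell = A\,(t/B)^{1/(\mu-d)}} \cr
#'   `mu == dim+1` \tab \eqn{\ell = A\,(t/B)\log(t/B)} (1D) \cr
#'   `mu > dim+1` \tab \eqn{\ell = A\,(t/B)} (wavelike) \cr
#' }
#' All forms are strictly increasing on their domain and carry an exact
#' inverse, so they can be used directly in [solve_t_star()] and
#' [halo_core_ratio()].
#'
#' @param mu Kernel exponent.
#' @param dim Habitat dimension (1 or 2).
#' @param A,B Length and time magnitude factors.
#' @param c Marginal-regime coefficient (only used when `mu == dim`).
#' @return An object of class `"growth_law"` with elements `ell` and
#'   `ell_inv` (vectorised functions), the regime, and its parameters.
#' @examples
#' law <- growth_law_asymptotic(mu = 1.5, dim = 1)  # ell(t) = t^2
#' law$ell(3)
#' law$ell_inv(9)
#' @export
growth_law_asymptotic <- function(mu, dim = 1L, A = 1, B = 1, c = 1) {
  dim <- as.integer(dim)
  kernel_spec(mu, dim)
  if (A <= 0 || B <= 0) stop("A and B must be positive")
  regime <- growth_regime(mu, dim)
  d <- dim

  if (regime == "linear") {
    ell <- function(t) A * (t / B)
    ell_inv <- function(l) B * (l / A)
    dom <- c(0, Inf); rng <- c(0, Inf)
    pars <- list(A = A, B = B)
  } else if (regime == "power") {
    ex <- 1 / (mu - d)
    ell <- function(t) A * (t / B)^ex
    ell_inv <- function(l) B * (l / A)^(1 / ex)
    dom <- c(0, Inf); rng <- c(0, Inf)
    pars <- list(A = A, B = B, exponent = ex)
  } else if (regime == "marginal_upper") {
    if (d != 1L) stop("the t*log(t) marginal form is one-dimensional")
    ell <- function(t) {
      x <- t / B
      ifelse(x > 1, A * x * log(x), NA_real_)
    }
    ell_inv <- function(l) {
      y <- l / A
      # solve x log x = y:  x = y / W(y)
      B * ifelse(y > 0, y / vapply(y, pracma::lambertWp, 1.0), NA_real_)
    }
    dom <- c(B, Inf); rng <- c(0, Inf)
    pars <- list(A = A, B = B)
  } else if (regime == "stretched") {
    # eta > 1 exactly when mu < d (stretched-exponential acceleration)
    eta <- log(4 * d / (d + mu)) / log(2)
    B_mu <- 2 * d * log(2) / (mu - d)^2
    ell <- function(t) A * exp(B_mu * (t / B)^eta)
    ell_inv <- function(l) {
      z <- log(l / A) / B_mu
      ifelse(z > 0, B * z^(1 / eta), NA_real_)
    }
    dom <- c(0, Inf); rng <- c(A, Inf)
    pars <- list(A = A, B = B, eta = eta, B_mu = B_mu)
  } else {  # marginal, mu == dim
    if (c <= 0) stop("marginal coefficient c must be positive")
    ell <- function(t) {
      x <- t / B
      ifelse(x >= 1, A * exp(c * log(x)^2), NA_real_)
    }
    ell_inv <- function(l) {
      z <- log(l / A) / c
      ifelse(z >= 0, B * exp(sqrt(z)), NA_real_)
    }
    dom <- c(B, Inf); rng <- c(A, Inf)  # restricted to the increasing branch
    pars <- list(A = A, B = B, c = c)
  }

  structure(list(type = "asymptotic", regime = regime, mu = mu, dim = d,
                 params = pars, ell = ell, ell_inv = ell_inv,
                 t_range = dom, ell_range = rng),
            class = "growth_law")
}

#' Tabulated growth law from an estimated ell(t) curve
#'
#' Wraps an [estimate_ell()] curve in a strictly monotone log-log
#' interpolant (Hyman-filtered cubic spline), the canonical representation
#' of \eqn{\ell(t)} used by the scaling theory.  Evaluation outside the
#' tabulated domain signals an error rather than extrapolating: simulate
#' longer, or fit an asymptotic form with [fit_growth_form()] if
#' extrapolation is genuinely wanted.
#'
#' @param curve An `"ell_curve"`, or a data frame with columns `t` and
#'   `ell` (positive, jointly increasing after deduplication).
#' @param mu Kernel exponent (defaults to the curve's attribute if present).
#' @param dim Habitat dimension (defaults to the curve's attribute).
#' @return A `"growth_law"` of type `"tabulated"`.
#' @export
growth_law_tabulated <- function(curve, mu = attr(curve, "mu"),
                                 dim = attr(curve, "habitat_dim")) {
  stopifnot(is.data.frame(curve), all(c("t", "ell") %in% names(curve)))
  if (is.null(dim)) dim <- 1L
  df <- curve[is.finite(curve$t) & is.finite(curve$ell) &
                curve$t > 0 & curve$ell > 0, c("t", "ell")]
  df <- df[order(df$t), ]
  # enforce strict monotonicity: running max, then drop flat steps
  df$ell <- cummax(df$ell)
  keep <- c(TRUE, diff(df$ell) > 0) & c(TRUE, diff(df$t) > 0)
  df <- df[keep, ]
  if (nrow(df) < 4L) stop("need at least 4 strictly increasing points")

  lt <- log(df$t); ll <- log(df$ell)
  fwd <- stats::splinefun(lt, ll, method = "hyman")
  bwd <- stats::splinefun(ll, lt, method = "hyman")
  t_range <- range(df$t); ell_range <- range(df$ell)

  ell <- function(t) {
    bad <- t < t_range[1L] | t > t_range[2L]
    if (any(bad, na.rm = TRUE))
      stop(sprintf("t outside tabulated domain [%.4g, %.4g]; simulate longer",
                   t_range[1L], t_range[2L]))
    exp(fwd(log(t)))
  }
  ell_inv <- function(l) {
    bad <- l < ell_range[1L] | l > ell_range[2L]
    if (any(bad, na.rm = TRUE))
      stop(sprintf("ell outside tabulated range [%.4g, %.4g]; simulate longer",
                   ell_range[1L], ell_range[2L]))
    exp(bwd(log(l)))
  }

  structure(list(type = "tabulated", regime = if (!is.null(mu))
    growth_regime(mu, as.integer(dim)) else NA_character_,
    mu = mu, dim = as.integer(dim), params = list(n_points = nrow(df)),
    ell = ell, ell_inv = ell_inv,
    t_range = t_range, ell_range = ell_range),
    class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf("Growth law (%s, regime %s): mu = %s, d = %d\n",
              x$type, x$regime, format(x$mu), x$dim))
  if (length(x$params))
    cat("  ", paste(names(x$params), vapply(x$params, format, ""),
                    sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  domain t in [%.4g, %.4g], ell in [%.4g, %.4g]\n",
              x$t_range[1L], x$t_range[2L], x$ell_range[1L], x$ell_range[2L]))
  invisible(x)
}

#' Characteristic time from mutation-expansion balance
#'
#' Solves \eqn{\tilde u\, t\, \omega_d\, \ell^d(t) = 1} for the unique
#' characteristic time \eqn{t^*}: the time over which exactly one new
#' mutation is expected in the space-time region swept out by a growing
#' core.  The left side is strictly increasing in `t`, so the root is
#' bracketed by geometric expansion and refined in log-time to a relative
#' tolerance of 1e-9.
#'
#' @param law A `"growth_law"`.
#' @param u_tilde Rescaled mutation rate (positive).
#' @param dim Habitat dimension; defaults to the law's dimension.
#' @return The characteristic time `t_star`.
#' @examples
#' solve_t_star(growth_law_asymptotic(4, 1), u_tilde = 0.5)  # ell = t: t* = 1
#' @export
solve_t_star <- function(law, u_tilde, dim = law$dim) {
  stopifnot(inherits(law, "growth_law"))
  if (u_tilde <= 0) stop("u_tilde must be positive")
  d <- as.integer(dim)
  om <- omega_d(d)
  g <- function(t) u_tilde * t * om * law$ell(t)^d - 1

  lo <- max(law$t_range[1L], .Machine$double.xmin)
  hi <- law$t_range[2L]
  if (is.finite(hi)) {
    if (g(hi) < 0)
      stop("t* lies beyond the tabulated domain; extend the ell curve (simulate longer)")
    if (lo > 0 && g(lo) > 0)
      stop("t* lies below the tabulated domain; simulate with finer early-time resolution")
  } else {
    # geometric bracket expansion on an unbounded analytic law; NA guards
    # cover forms whose increasing branch starts at t = B
    lo <- if (lo > 0 && is.finite(lo)) lo * (1 + 1e-12) else 1e-12
    while ({v <- g(lo); is.finite(v) && v > 0}) lo <- lo / 8
    hi <- max(2 * lo, 1)
    while ({v <- g(hi); is.finite(v) && v < 0}) hi <- hi * 8
  }
  r <- uniroot(function(s) g(exp(s)), lower = log(lo), upper = log(hi),
               tol = 1e-12)
  exp(r$root)
}

#' Characteristic length scales of a spatial soft sweep
#'
#' Computes the scale set from mutation-expansion balance: the
#' characteristic time \eqn{t^*} (see [solve_t_star()]), the core extent
#' \eqn{\chi = \ell(t^*)}, the satellite-cluster extent
#' \eqn{\psi = \ell(2 t^*)} (satellites merging with a core at time `t`
#' stem from key jumps near time `t/2`, so a core grown for `t*` has seeded
#' satellites out to \eqn{\ell(2t^*)}), and the outer limit of rare jumps
#' \eqn{\zeta = \tilde u^{-1/\mu}} (the distance beyond which the net
#' number of jumps out of a typical clone during the sweep falls below 1).
#'
#' @inheritParams solve_t_star
#' @param mu Kernel exponent for \eqn{\zeta}; defaults to the law's.
#' @return A `"scale_set"`: list with `t_star`, `chi`, `psi`, `zeta`,
#'   `u_tilde`, `mu`, `dim`, `omega_d`.
#' @examples
#' characteristic_scales(growth_law_asymptotic(1.5, 1), u_tilde = 1e-3)
#' @export
characteristic_scales <- function(law, u_tilde, dim = law$dim, mu = law$mu) {
  t_star <- solve_t_star(law, u_tilde, dim)
  chi <- law$ell(t_star)
  psi <- law$ell(2 * t_star)
  zeta <- if (is.null(mu)) NA_real_ else u_tilde^(-1 / mu)
  structure(list(t_star = t_star, chi = chi, psi = psi, zeta = zeta,
                 u_tilde = u_tilde, mu = mu, dim = as.integer(dim),
                 omega_d = omega_d(as.integer(dim))),
            class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf("Characteristic scales (mu = %s, d = %d, u_tilde = %g):\n",
              format(x$mu), x$dim, x$u_tilde))
  cat(sprintf("  t* = %.6g   chi = %.6g   psi = %.6g   zeta = %.6g\n",
              x$t_star, x$chi, x$psi, x$zeta))
  invisible(x)
}

#' Closed-form asymptotic characteristic core extent
#'
#' Evaluates \eqn{\chi_{as}}, the characteristic core extent obtained by
#' solving the mutation-expansion balance analytically with the long-time
#' asymptotic \eqn{\ell(t)} (magnitude factors `A = B = 1`):
#' \describe{
#'   \item{`mu > dim+1`}{\eqn{(\tilde u \omega_d)^{-1/(d+1)}}}
#'   \item{`dim < mu < dim+1`}{\eqn{(\tilde u \omega_d)^{-1/\mu}}}
#'   \item{`mu == dim+1` (1D)}{\eqn{\chi = \tfrac12\sqrt{2 z/(\tilde u \omega_d)}}
#'     with \eqn{z = W(2/(\tilde u \omega_d))}}
#'   \item{`mu < dim`}{\eqn{\chi = (\xi/W(\xi))^{1/(\eta d)}} with
#'     \eqn{\xi = \eta d B_\mu (\tilde u \omega_d)^{-\eta}}}
#'   \item{`mu == dim`}{from the quadratic in \eqn{\log t^*} implied by
#'     \eqn{\ell = \exp(c\log^2 t)}; requires the marginal coefficient `c`}
#' }
#' `W` is the principal branch of the Lambert W function (all arguments
#' used are positive).
#'
#' @param mu Kernel exponent (positive).
#' @param dim Habitat dimension.
#' @param u_tilde Rescaled mutation rate.
#' @param c Marginal coefficient, used only when `mu == dim`.
#' @return The asymptotic characteristic extent \eqn{\chi_{as}}.
#' @examples
#' chi_asymptotic(4, 1, 7e-7)    # approx 845.2
#' chi_asymptotic(1.5, 1, 1e-3)  # approx 63.0
#' @export
chi_asymptotic <- function(mu, dim = 1L, u_tilde, c = 1) {
  dim <- as.integer(dim)
  kernel_spec(mu, dim)
  if (any(u_tilde <= 0)) stop("u_tilde must be positive")
  d <- dim
  om <- omega_d(d)
  regime <- growth_regime(mu, d)
  z0 <- u_tilde * om

  if (regime == "linear") {
    z0^(-1 / (d + 1))
  } else if (regime == "power") {
    z0^(-1 / mu)
  } else if (regime == "marginal_upper") {
    if (d != 1L) stop("mu == dim + 1 closed form implemented for d = 1")
    w <- vapply(2 / z0, pracma::lambertWp, 1.0)
    0.5 * sqrt(2 * w / z0)
  } else if (regime == "stretched") {
    # eta > 1 exactly when mu < d (stretched-exponential acceleration)
    eta <- log(4 * d / (d + mu)) / log(2)
    B_mu <- 2 * d * log(2) / (mu - d)^2
    xi <- eta * d * B_mu * z0^(-eta)
    w <- vapply(xi, pracma::lambertWp, 1.0)
    (xi / w)^(1 / (eta * d))
  } else {  # marginal
    if (c <= 0) stop("marginal coefficient c must be positive")
    lz <- -log(z0)  # positive for u_tilde * omega_d < 1
    if (any(lz <= 0)) stop("marginal closed form requires u_tilde * omega_d < 1")
    y <- (-1 + sqrt(1 + 4 * d * c * lz)) / (2 * d * c)  # y = log t*
    exp(c * y^2)
  }
}

#' Halo-to-core extent map
#'
#' For a clone whose high-occupancy core has linear extent `l`, satellites
#' of significant size are expected out to
#' \eqn{l' = \ell(2\,\ell^{-1}(l))}: the core reached size `l` at time
#' \eqn{\ell^{-1}(l)}, and key jumps seed satellites out to the extent the
#' core would reach in twice that time.  For power-law growth this gives a
#' size-independent ratio \eqn{l'/l = 2^{1/(\mu - d)}}; for
#' stretched-exponential growth the ratio itself grows with `l`.
#'
#' @param law A `"growth_law"`.
#' @param l Core extent(s), within the law's range.
#' @return The expected halo extent `l'`.
#' @export
halo_core_ratio <- function(law, l) {
  stopifnot(inherits(law, "growth_law"))
  law$ell(2 * law$ell_inv(l))
}

#' Expected number of mutational origins in a range
#'
#' Multiplying the mutation-expansion balance by the number of demes shows
#' that the expected number of independent origins scales as
#' \eqn{L^d \tilde u t^* = L^d/(\omega_d \chi^d)}.  Values below 1 indicate
#' the hard-sweep regime \eqn{L \ll \chi}.
#'
#' @param L Linear range size.
#' @param dim Habitat dimension.
#' @param scales A `"scale_set"` from [characteristic_scales()], or a
#'   numeric characteristic extent \eqn{\chi}.
#' @return Expected count of mutational origins.
#' @export
expected_allele_count <- function(L, dim = 1L, scales) {
  dim <- as.integer(dim)
  chi <- if (inherits(scales, "scale_set")) scales$chi else as.numeric(scales)
  if (any(chi <= 0)) stop("chi must be positive")
  L^dim / (omega_d(dim) * chi^dim)
}
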