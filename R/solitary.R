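#' Simulate the growth of a solitary clone
#'
#' Runs the sweep engine with no recurrent mutation (`u_tilde = 0`) and a
#' single seeded mutant at the origin, recording the clone mass `M(t)` at
#' every successful colonisation.  This is the measurement underlying the
#' core-growth function \eqn{\ell(t)}.
#'
#' The lattice should be large enough that the clone never approaches the
#' wrap scale before the stop condition; a warning flag is set when the
#' final mass exceeds `(0.4 L)^dim` (finite-size contamination).
#'
#' @param L,mu,dim,seed,deterministic_time,max_events As in [run_sweep()].
#' @param stop_mass Stop once the clone reaches this mass.
#' @param t_max Stop once time exceeds this value.
#' @return A `"growth_trace"`: data frame with columns `t` and `M`
#'   (non-decreasing, `M(0) = 1`), with the configuration and the
#'   finite-size warning flag as attributes.
#' @examples
#' tr <- run_solitary(L = 5000, mu = 1.5, stop_mass = 200, seed = 1)
#' tail(tr, 3)
#' @export
run_solitary <- function(L, mu, dim = 1L, stop_mass = Inf, t_max = Inf,
                         seed = NULL, deterministic_time = FALSE,
                         max_events = 1e10) {
  L <- as.integer(L)
  dim <- as.integer(dim)
  kernel_spec(mu, dim)
  if (!is.finite(stop_mass) && !is.finite(t_max) && L > 0)
    stop_mass <- L^dim  # engine stops at full lattice anyway
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  raw <- cpp_run_solitary(L, dim, mu, as.double(seed),
                          as.double(stop_mass), as.double(t_max),
                          deterministic_time, as.double(max_events))
  if (raw$wrap_warning)
    warning(sprintf(
      "clone mass %g exceeds the wrap guard (0.4*L)^d = %g; ell(t) may be contaminated by finite-size effects",
      raw$final_mass, (0.4 * L)^dim))

  structure(data.frame(t = raw$times, M = raw$masses),
            class = c("growth_trace", "data.frame"),
            config = list(L = L, dim = dim, mu = mu,
                          seed = as.integer(seed),
                          stop_mass = stop_mass, t_max = t_max),
            wrap_warning = raw$wrap_warning)
}

#' Estimate the core-growth function ell(t)
#'
#' \eqn{\ell(t)} is defined as the expected mass-equivalent radius of a
#' solitary clone, \eqn{E[(M(t)/\omega_d)^{1/d}]} with \eqn{\omega_1 = 2},
#' \eqn{\omega_2 = \pi}.  Each trace is step-interpolated (mass is
#' piecewise constant between colonisations) on a common time grid and the
#' transformed masses are averaged across traces.
#'
#' @param traces A list of `"growth_trace"` objects (a single trace is
#'   accepted), all with the same dimension.
#' @param time_grid Optional increasing vector of evaluation times.  The
#'   default is 200 log-spaced points from the earliest colonisation to the
#'   end of the shortest trace.  A grid extending beyond the shortest trace
#'   is truncated with a warning.
#' @return An `"ell_curve"`: data frame with columns `t`, `ell` and `se`
#'   (standard error across traces), with `dim` and `n_reps` attributes.
#' @examples
#' trs <- lapply(1:5, function(s) run_solitary(5000, 1.5, stop_mass = 100, seed = s))
#' ec <- estimate_ell(trs)
#' head(ec, 3)
#' @export
estimate_ell <- function(traces, time_grid = NULL) {
  if (inherits(traces, "growth_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "growth_trace")))
  dims <- vapply(traces, function(tr) attr(tr, "config")$dim, 1L)
  if (length(unique(dims)) != 1L) stop("traces mix dimensions")
  d <- dims[1L]
  om <- omega_d(d)

  t_end <- min(vapply(traces, function(tr) max(tr$t), 1.0))
  if (is.null(time_grid)) {
    t_start <- min(vapply(traces, function(tr)
      if (nrow(tr) > 1L) tr$t[2L] else max(tr$t), 1.0))
    if (t_start <= 0 || t_start >= t_end) t_start <- t_end / 1e3
    time_grid <- exp(seq(log(t_start), log(t_end), length.out = 200L))
  } else {
    time_grid <- sort(as.numeric(time_grid))
    if (max(time_grid) > t_end) {
      warning("time grid extends beyond the shortest trace; truncating")
      time_grid <- time_grid[time_grid <= t_end]
    }
  }
  if (!length(time_grid)) stop("empty time grid")

  vals <- vapply(traces, function(tr) {
    M <- tr$M[findInterval(time_grid, tr$t)]
    (M / om)^(1 / d)
  }, numeric(length(time_grid)))
  vals <- matrix(vals, nrow = length(time_grid))

  ell <- rowMeans(vals)
  se <- if (ncol(vals) > 1L) apply(vals, 1L, sd) / sqrt(ncol(vals)) else
    rep(NA_real_, length(time_grid))

  structure(data.frame(t = time_grid, ell = ell, se = se),
            class = c("ell_curve", "data.frame"),
            habitat_dim = d, n_reps = length(traces),
            mu = attr(traces[[1L]], "config")$mu)
}

#' Fit an asymptotic growth form to an ell(t) curve
#'
#' Fits the regime-appropriate long-time form of \eqn{\ell(t)} with free
#' length and time magnitude factors `A` and `B`:
#' \describe{
#'   \item{`mu > dim + 1`}{linear, \eqn{\ell = A t} (wavelike fronts).}
#'   \item{`dim < mu < dim + 1`}{power law, \eqn{\ell = A t^{1/(\mu - d)}}.}
#'   \item{`mu == dim + 1`}{marginal upper boundary,
#'     \eqn{\ell = A (t/B)\log(t/B)} (1D).}
#'   \item{`mu < dim`}{stretched exponential,
#'     \eqn{\ell = A \exp(B_\mu (t/B)^\eta)} with
#'     \eqn{\eta = \log[4d/(d+\mu)]/\log 2} and
#'     \eqn{B_\mu = 2 d \log(2)/(\mu - d)^2}; `A` and the effective
#'     coefficient of \eqn{t^\eta} are estimated by linear regression of
#'     \eqn{\log\ell} on \eqn{t^\eta}, and `B` absorbs the difference from
#'     the nominal \eqn{B_\mu}.}
#'   \item{`mu == dim`}{marginal, \eqn{\ell = A \exp(c \log^2 t)} with `c`
#'     free; qualitative shape only.}
#' }
#' Power-law and linear regimes also report the freely fitted log-log
#' exponent as a regime diagnostic.
#'
#' @param ell An `"ell_curve"` from [estimate_ell()], or any data frame
#'   with columns `t` and `ell`.
#' @param mu Kernel exponent the curve was generated under.
#' @param dim Habitat dimension.
#' @param t_min Optional lower time cut for the fit window (asymptotic
#'   forms hold at late times); default uses the upper half of the curve in
#'   log-time.
#' @return A `"growth_law"` object (see [growth_law_asymptotic()]) with a
#'   `diagnostics` attribute (free exponent, R^2, residual sum of squares).
#' @export
fit_growth_form <- function(ell, mu, dim = 1L, t_min = NULL) {
  stopifnot(is.data.frame(ell), all(c("t", "ell") %in% names(ell)))
  dim <- as.integer(dim)
  kernel_spec(mu, dim)
  df <- ell[is.finite(ell$t) & is.finite(ell$ell) & ell$t > 0 & ell$ell > 0, ]
  if (nrow(df) < 3L) stop("too few usable points in ell curve")
  if (diff(range(log10(df$ell))) < 2)
    warning("ell values cover less than 2 decades; fitted factors may be poorly constrained")
  if (is.null(t_min))
    t_min <- exp(stats::median(log(df$t)))
  fitdf <- df[df$t >= t_min, ]
  if (nrow(fitdf) < 3L) fitdf <- df

  regime <- growth_regime(mu, dim)
  lt <- log(fitdf$t); ll <- log(fitdf$ell)
  diag <- list()

  if (regime == "linear") {
    A <- exp(mean(ll - lt))
    free <- lm(ll ~ lt)
    law <- growth_law_asymptotic(mu, dim, A = A, B = 1)
    diag <- list(exponent_free = unname(coef(free)[2L]),
                 r_squared = summary(free)$r.squared)
  } else if (regime == "power") {
    ex <- 1 / (mu - dim)
    A <- exp(mean(ll - ex * lt))
    free <- lm(ll ~ lt)
    law <- growth_law_asymptotic(mu, dim, A = A, B = 1)
    diag <- list(exponent_free = unname(coef(free)[2L]),
                 exponent_theory = ex,
                 r_squared = summary(free)$r.squared)
  } else if (regime == "stretched") {
    eta <- log(4 * dim / (dim + mu)) / log(2)
    fit <- lm(ll ~ I(fitdf$t^eta))
    A <- exp(unname(coef(fit)[1L]))
    b <- unname(coef(fit)[2L])
    if (b <= 0) stop("non-increasing stretched-exponential fit; regime mismatch?")
    B_mu <- 2 * dim * log(2) / (mu - dim)^2
    B <- (B_mu / b)^(1 / eta)
    law <- growth_law_asymptotic(mu, dim, A = A, B = B)
    diag <- list(coef_t_eta = b, eta = eta,
                 r_squared = summary(fit)$r.squared)
  } else if (regime == "marginal") {
    keep <- fitdf$t > 1
    if (sum(keep) < 3L) stop("marginal fit needs points with t > 1")
    fit <- lm(log(fitdf$ell[keep]) ~ I(log(fitdf$t[keep])^2))
    A <- exp(unname(coef(fit)[1L]))
    cc <- unname(coef(fit)[2L])
    law <- growth_law_asymptotic(mu, dim, A = A, B = 1, c = cc)
    diag <- list(c = cc, r_squared = summary(fit)$r.squared)
  } else {  # marginal_upper, mu = dim + 1
    obj <- function(logB) {
      B <- exp(logB)
      x <- fitdf$t / B
      ok <- x > 1
      if (sum(ok) < 3L) return(Inf)
      resid <- ll[ok] - (log(x[ok]) + log(log(x[ok])))
      sum((resid - mean(resid))^2)
    }
    opt <- stats::optimize(obj, interval = log(c(min(fitdf$t) / 10, max(fitdf$t) / 2)))
    B <- exp(opt$minimum)
    x <- fitdf$t / B
    ok <- x > 1
    A <- exp(mean(ll[ok] - log(x[ok] * log(x[ok]))))
    law <- growth_law_asymptotic(mu, dim, A = A, B = B)
    diag <- list(rss = opt$objective)
  }
  attr(law, "diagnostics") <- diag
  law
}
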