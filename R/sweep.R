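#' Simulate one spatial soft sweep to completion
#'
#' Runs the reduced deme-level model on a periodic lattice of `L^dim` demes,
#' all initially wildtype, until every deme has fixed a mutant allele.  Each
#' discrete event is a mutation of a wildtype deme (relative weight
#' `u_tilde` per wildtype deme) or an attempted migration out of a mutant
#' deme (weight 1 per mutant deme).  A migration draws a jump offset from
#' the power-law kernel with exponent `mu`; the target deme adopts the
#' source's allele only if it is still wildtype (allelic exclusion).  Time
#' is measured in expected dispersal attempts per mutant deme and advances
#' by an exponentially distributed increment with mean `1/R` per event,
#' where `R = n_mut + u_tilde * n_wt` (set `deterministic_time = TRUE` for
#' fixed increments `1/R`, useful for variance-reduced growth curves).
#'
#' Allele labels are consecutive integers `1, 2, ...` in order of the
#' originating mutation.  Failed migrations (occupied target) consume a time
#' increment and are counted, which matters for correct time accounting
#' near sweep completion.
#'
#' @param L Linear range size (positive integer).
#' @param mu Kernel exponent (positive).
#' @param u_tilde Rescaled mutation rate \eqn{\tilde u} (mutations per deme
#'   per dispersal attempt), positive.
#' @param dim Habitat dimension, 1 or 2.
#' @param seed Integer seed for the simulation's own random stream.  `NULL`
#'   draws a seed from R's stream and records it.
#' @param deterministic_time Use fixed `1/R` time increments instead of
#'   exponential ones.
#' @param record_fill_times Record the fixation time of every deme.
#' @param snapshot_times Optional increasing numeric vector of times at
#'   which to store a copy of the lattice.
#' @param max_events Resource guard: abort with a diagnostic if the event
#'   count exceeds this ceiling.
#' @return An object of class `"sweep_result"`: a list with elements
#'   `grid` (integer lattice of allele identities; a vector in 1D, an
#'   `L x L` matrix in 2D), `origins` (data frame with one row per allele:
#'   label, origin deme coordinates, origin time), `event_counts`
#'   (mutations, successful and failed migrations), `total_time`,
#'   `fill_times` (if requested), `snapshots`, and `config`.
#' @examples
#' res <- run_sweep(L = 500, mu = 1.5, u_tilde = 1e-2, seed = 1)
#' res
#' length(clone_masses(res))
#' @seealso [run_sweep_ensemble()], [extract_clones()], [clone_masses()]
#' @export
run_sweep <- function(L, mu, u_tilde, dim = 1L, seed = NULL,
                      deterministic_time = FALSE,
                      record_fill_times = FALSE,
                      snapshot_times = NULL,
                      max_events = 1e10) {
  L <- as.integer(L)
  dim <- as.integer(dim)
  if (L < 1L) stop("L must be >= 1")
  if (!is.numeric(u_tilde) || u_tilde <= 0) stop("u_tilde must be positive")
  kernel_spec(mu, dim)  # validates mu/dim
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  snap <- if (is.null(snapshot_times)) numeric(0) else
    sort(as.numeric(snapshot_times))

  raw <- cpp_run_sweep(L, dim, mu, u_tilde, as.double(seed),
                       deterministic_time, record_fill_times,
                       as.double(max_events), snap)

  origins <- data.frame(allele = seq_along(raw$origin_deme),
                        deme_to_coords(raw$origin_deme, L, dim),
                        time = raw$origin_time)
  grid <- raw$grid
  if (dim == 2L) grid <- matrix(grid, nrow = L)

  structure(list(
    grid = grid,
    origins = origins,
    event_counts = c(mutations = raw$n_mutations,
                     migrations_successful = raw$n_mig_success,
                     migrations_failed = raw$n_mig_fail),
    total_time = raw$total_time,
    n_events = raw$n_events,
    fill_times = if (record_fill_times) raw$fill_times else NULL,
    snapshots = if (length(snap)) raw$snapshots else NULL,
    snapshot_times = if (length(snap)) raw$snapshot_times else NULL,
    config = list(L = L, dim = dim, mu = mu, u_tilde = u_tilde,
                  seed = as.integer(seed),
                  deterministic_time = deterministic_time)
  ), class = "sweep_result")
}

# map flat 0-based deme indices to 0-based coordinate columns
deme_to_coords <- function(idx, L, dim) {
  if (dim == 1L) data.frame(x = idx)
  else data.frame(x = idx %% L, y = idx %/% L)
}

#' @export
print.sweep_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Spatial soft sweep: L = %d (d = %d), mu = %g, u_tilde = %g, seed = %s\n",
              cfg$L, cfg$dim, cfg$mu, cfg$u_tilde,
              if (is.na(cfg$seed)) "NA" else format(cfg$seed)))
  cat(sprintf("  %d distinct alleles across %d demes; total time %.4g\n",
              nrow(x$origins), length(x$grid), x$total_time))
  if (!is.null(x$event_counts) && !any(is.na(x$event_counts)))
    cat(sprintf("  events: %.4g mutations, %.4g successful / %.4g failed migrations\n",
                x$event_counts[["mutations"]],
                x$event_counts[["migrations_successful"]],
                x$event_counts[["migrations_failed"]]))
  invisible(x)
}

#' @export
summary.sweep_result <- function(object, ...) {
  ct <- extract_clones(object)
  cat(sprintf("%d clones; mass: mean %.4g, median %.4g, max %.4g\n",
              nrow(ct), mean(ct$X), stats::median(ct$X), max(ct$X)))
  invisible(ct)
}

#' Clone masses of a completed sweep
#'
#' Number of demes carrying each allele, indexed by allele label.  Masses
#' always sum to `L^dim`.
#'
#' @param result A `"sweep_result"`.
#' @return Integer vector of masses, one per allele.
#' @export
clone_masses <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  tabulate(as.integer(result$grid), nbins = nrow(result$origins))
}

#' Number of distinct alleles in a completed sweep
#' @param result A `"sweep_result"`.
#' @return Integer count of mutational origins.
#' @export
allele_count <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  nrow(result$origins)
}

#' Simulate an ensemble of independent sweeps
#'
#' Runs `n_reps` independent replicates with distinct seeds.  Results are
#' order-stable: replicate `i` always uses `seeds[i]`.
#'
#' @param n_reps Number of replicates (`>= 1`).
#' @param L,mu,u_tilde,dim,... Passed to [run_sweep()].
#' @param seeds Optional integer vector of length `n_reps`; must be unique.
#'   `NULL` draws distinct seeds from R's stream.
#' @return An object of class `"sweep_ensemble"`: a list of
#'   `"sweep_result"` objects with the shared configuration attached.
#' @examples
#' ens <- run_sweep_ensemble(3, L = 300, mu = 2, u_tilde = 1e-2, seeds = 1:3)
#' mean_clone_mass(ens)
#' @export
run_sweep_ensemble <- function(n_reps, L, mu, u_tilde, dim = 1L,
                               seeds = NULL, ...) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (is.null(seeds)) seeds <- sample.int(.Machine$integer.max, n_reps)
  if (length(seeds) != n_reps) stop("seeds must have length n_reps")
  if (anyDuplicated(seeds)) stop("seeds must be unique")
  runs <- lapply(seeds, function(s)
    run_sweep(L = L, mu = mu, u_tilde = u_tilde, dim = dim, seed = s, ...))
  structure(runs, class = "sweep_ensemble",
            config = list(L = as.integer(L), dim = as.integer(dim),
                          mu = mu, u_tilde = u_tilde,
                          seeds = as.integer(seeds)))
}

#' @export
print.sweep_ensemble <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Sweep ensemble: %d replicates, L = %d (d = %d), mu = %g, u_tilde = %g\n",
              length(x), cfg$L, cfg$dim, cfg$mu, cfg$u_tilde))
  cat(sprintf("  mean clone mass <X> = %.4g; allele counts %s\n",
              mean_clone_mass(x),
              paste(range(vapply(x, allele_count, 1L)), collapse = "-")))
  invisible(x)
}

#' Ensemble-averaged clone mass
#'
#' The range average of clone mass within one simulation is
#' `L^dim / n_alleles`; the ensemble average `<X>` averages this across
#' replicates, matching how averaged final-state quantities are reported.
#'
#' @param x A `"sweep_ensemble"` or a list of `"sweep_result"`s.
#' @return The ensemble mean clone mass.
#' @export
mean_clone_mass <- function(x) {
  stopifnot(is.list(x), length(x) >= 1L)
  vals <- vapply(x, function(r) {
    stopifnot(inherits(r, "sweep_result"))
    length(r$grid) / nrow(r$origins)
  }, numeric(1))
  mean(vals)
}
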