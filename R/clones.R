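#' Per-clone geometry of a completed sweep
#'
#' Groups the final lattice into clones (one per allele) and computes, for
#' each: the mass `X` (number of demes), the mass-equivalent radius
#' `r_eq = (X / omega_d)^(1/dim)` (radius of a ball holding the clone's
#' mass), and the extent `r_max` — in 1D half the largest periodic
#' separation between any pair of member demes (capped at `L/2`), in 2D the
#' eighth-root of the mean eighth power of member distances from the
#' periodic centroid.
#'
#' @param result A `"sweep_result"` (or tessellation fixture).
#' @return A `"clone_table"`: data frame with one row per allele (columns
#'   `allele`, origin coordinates, `time`, `X`, `r_eq`, `r_max`), ordered
#'   by allele label, with `L` and `dim` attributes.  Masses sum to
#'   `L^dim` exactly.
#' @examples
#' ct <- extract_clones(run_sweep(500, mu = 2, u_tilde = 1e-2, seed = 1))
#' head(ct)
#' @export
extract_clones <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  L <- result$config$L
  d <- result$config$dim
  grid <- as.integer(result$grid)
  n_alleles <- nrow(result$origins)
  X <- tabulate(grid, nbins = n_alleles)
  if (any(X == 0L))
    stop("corrupt result: allele(s) ", paste(which(X == 0L), collapse = ", "),
         " present in origins but absent from the grid")
  if (sum(X) != length(grid)) stop("corrupt result: clone masses do not sum to L^dim")

  members <- split(seq_along(grid) - 1L, grid)  # 0-based, ascending
  r_max <- if (d == 1L) {
    vapply(members, clone_extent_1d, 1.0, L = L)
  } else {
    vapply(members, function(m)
      clone_extent_2d(cbind(m %% L, m %/% L), L), 1.0)
  }

  out <- data.frame(result$origins,
                    X = X,
                    r_eq = (X / omega_d(d))^(1 / d),
                    r_max = r_max)
  structure(out, class = c("clone_table", "data.frame"), L = L, habitat_dim = d)
}

#' Clone extent in one dimension
#'
#' Half the separation of the furthest-apart pair of member demes on a
#' periodic ring: equivalently `(L - g)/2` where `g` is the largest
#' circular gap between consecutive members, capped at `L/2`.  A single
#' deme has extent 0.
#'
#' @param members 0-based member positions (any order).
#' @param L Ring size.
#' @return The extent `r_max`.
#' @export
clone_extent_1d <- function(members, L) {
  if (!length(members)) stop("empty member set")
  if (length(members) == 1L) return(0)
  m <- sort(as.numeric(members))
  g <- max(diff(m), L - (m[length(m)] - m[1L]))
  min((L - g) / 2, L / 2)
}

#' Clone extent in two dimensions
#'
#' The eighth-root of the mean eighth power of member distances from the
#' clone centroid (a high central moment weights the farthest members, so
#' the statistic tracks the outermost satellites).  The centroid is
#' computed with periodic-aware circular means per coordinate and member
#' displacements use the minimal image.
#'
#' @param members Two-column matrix of 0-based `(x, y)` positions.
#' @param L Lattice side.
#' @return The extent `r_max8`.
#' @export
clone_extent_2d <- function(members, L) {
  members <- rbind(members)
  if (!nrow(members)) stop("empty member set")
  if (nrow(members) == 1L) return(0)
  centroid <- apply(members, 2L, function(p) {
    th <- 2 * pi * p / L
    (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * L) %% L
  })
  dd <- sweep(members, 2L, centroid)
  dd <- (dd + L / 2) %% L - L / 2  # minimal image
  r <- sqrt(rowSums(dd^2))
  mean(r^8)^(1 / 8)
}

# Occupied-shell counts for one 1D clone: distances of members from the
# clone's own origin (minimal image), the number occupied at each integer
# distance, and the shell size (2 demes at origin +/- r, 1 at r = L/2 for
# even L).
clone_shells_1d <- function(members, origin, L) {
  dist <- abs(members - origin)
  dist <- pmin(dist, L - dist)
  dist <- dist[dist > 0]
  if (!length(dist))
    return(data.frame(r = integer(0), occupied = integer(0), shell = integer(0)))
  occ <- tabulate(dist, nbins = floor(L / 2))
  r <- which(occ > 0L)
  shell <- ifelse(L %% 2L == 0L & r == L / 2L, 1L, 2L)
  data.frame(r = r, occupied = occ[r], shell = shell)
}

#' Occupancy shells of a single 1D clone
#'
#' The occupancy \eqn{\rho(r)} of a clone is the fraction of the shell at
#' integer distance `r` from its point of origin (the two demes at
#' origin +/- r on the periodic ring) occupied by that clone.  The
#' unscaled occupancy obeys the exact mass identity
#' `2 * sum_r rho(r) + 1 = X` (for odd `L`, or with the `r = L/2` shell of
#' size 1 accounted for when `L` is even).
#'
#' @param members 0-based member positions of the clone.
#' @param origin 0-based position of the originating mutation (must be a
#'   member).
#' @param L Ring size.
#' @return Data frame with columns `r`, `occupied`, `shell`, `rho` for
#'   every occupied shell (empty shells have `rho = 0`).
#' @export
clone_occupancy <- function(members, origin, L) {
  if (!length(members)) stop("empty member set")
  if (!origin %in% members) stop("origin deme is not a member of the clone")
  sh <- clone_shells_1d(as.numeric(members), as.numeric(origin), L)
  sh$rho <- sh$occupied / sh$shell
  sh
}

#' Ensemble-averaged radial occupancy profile
#'
#' For every clone above a mass threshold, the occupancy
#' \eqn{\rho(r)} (probability that a deme at distance `r` from the clone's
#' point of origin belongs to the clone) is computed on integer shells,
#' the distance is rescaled by the clone's mass-equivalent radius
#' `r_eq`, and profiles are binned in `r / r_eq`.  Clones are averaged
#' within each simulation (range average) and the per-simulation profiles
#' are then averaged across simulations (ensemble average).  Compact
#' contiguous clones are supported entirely in `r / r_eq <= 2`; discontiguous
#' haloes produce a tail that decays as `r^-(mu + d)`.
#'
#' @param x A `"sweep_result"`, a list of them, or a `"sweep_ensemble"`.
#' @param min_mass Only clones with mass `X > min_mass` contribute.
#' @param bin_width Bin width in scaled distance `r / r_eq`.
#' @param max_scaled Upper end of the scaled-distance support.
#' @return An `"occupancy_profile"`: data frame with bin edges and centre,
#'   mean occupancy `rho`, and the number of clones contributing to each
#'   bin; attributes record the threshold and binning.
#' @export
occupancy_profile <- function(x, min_mass = 100, bin_width = 0.1,
                              max_scaled = 50) {
  sims <- if (inherits(x, "sweep_result")) list(x) else x
  stopifnot(length(sims) >= 1L,
            all(vapply(sims, inherits, TRUE, "sweep_result")))
  if (sims[[1L]]$config$dim != 1L)
    stop("occupancy profiles are implemented for 1D lattices")

  n_bins <- ceiling(max_scaled / bin_width)
  edges_lo <- (seq_len(n_bins) - 1L) * bin_width
  edges_hi <- edges_lo + bin_width

  sim_rho <- matrix(NA_real_, length(sims), n_bins)
  sim_nclones <- numeric(n_bins)

  for (si in seq_along(sims)) {
    res <- sims[[si]]
    L <- res$config$L
    grid <- as.integer(res$grid)
    n_alleles <- nrow(res$origins)
    X <- tabulate(grid, nbins = n_alleles)
    sel <- which(X > min_mass)
    if (!length(sel)) next
    members <- split(seq_along(grid) - 1L, grid)
    rmax_shell <- floor(L / 2)

    acc <- matrix(0, length(sel), n_bins)  # per-clone binned rho (NA = out of support)
    acc[] <- NA_real_
    for (ci in seq_along(sel)) {
      a <- sel[ci]
      r_eq <- X[a] / 2  # (X / omega_1)^(1/1)
      sh <- clone_shells_1d(as.numeric(members[[a]]),
                            res$origins$x[a], L)
      ib <- floor(sh$r / r_eq / bin_width) + 1L
      keep <- ib <= n_bins
      occ_bin <- numeric(n_bins)
      if (any(keep)) {
        rho <- sh$occupied[keep] / sh$shell[keep]
        s <- rowsum(rho, ib[keep])  # rownames are sorted unique bin indices
        occ_bin[as.integer(rownames(s))] <- s[, 1L]
      }
      # number of integer shells per bin, measurable within [1, L/2]
      lo_r <- pmax(ceiling(edges_lo * r_eq), 1)
      hi_r <- pmin(ceiling(edges_hi * r_eq) - 1, rmax_shell)
      n_shell <- pmax(hi_r - lo_r + 1, 0)
      vals <- ifelse(n_shell > 0, occ_bin / pmax(n_shell, 1L), NA_real_)
      acc[ci, ] <- vals
    }
    sim_rho[si, ] <- colMeans(acc, na.rm = TRUE)
    sim_nclones <- sim_nclones + colSums(!is.na(acc))
  }

  rho <- colMeans(sim_rho, na.rm = TRUE)
  rho[is.nan(rho)] <- NA_real_
  structure(data.frame(lo = edges_lo, hi = edges_hi,
                       center = (edges_lo + edges_hi) / 2,
                       rho = rho, n_clones = sim_nclones),
            class = c("occupancy_profile", "data.frame"),
            min_mass = min_mass, bin_width = bin_width,
            n_sims = length(sims))
}

#' Core occupancy of an averaged profile
#'
#' The fraction of the ensemble-averaged occupancy lying within
#' `0 < r/r_eq < 2`, the maximal range measurable for a contiguous 1D
#' domain.  Values near 1 indicate compact clones with negligible haloes;
#' the fraction drops as long-range dispersal fragments clones.  Integrals
#' use the trapezoidal rule on bin centres.
#'
#' @param profile An `"occupancy_profile"`.
#' @return A fraction in `[0, 1]`.
#' @export
core_occupancy <- function(profile) {
  stopifnot(inherits(profile, "occupancy_profile"))
  ok <- is.finite(profile$rho)
  x <- profile$center[ok]; y <- profile$rho[ok]
  if (length(x) < 2L || sum(y) == 0)
    stop("profile has no measurable occupancy")
  total <- pracma::trapz(x, y)
  if (total <= 0) stop("profile integrates to zero")
  core <- x <= 2
  if (sum(core) < 2L) return(0)
  pracma::trapz(x[core], y[core]) / total
}
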