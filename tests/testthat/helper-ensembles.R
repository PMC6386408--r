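# Shared simulation ensembles, built on first use and reused across test
# files.  Seeds are fixed so every test run exercises identical study
# conditions; seed bases are spaced so no two ensembles overlap.
sim_cache <- new.env(parent = emptyenv())

cached_ensemble <- function(mu, u_tilde, L, n, seed_base) {
  key <- sprintf("mu%g_u%g_L%g_n%d_s%d", mu, u_tilde, L, n, seed_base)
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- run_sweep_ensemble(
      n, L = L, mu = mu, u_tilde = u_tilde,
      seeds = seed_base + seq_len(n) - 1L)
  sim_cache[[key]]
}

# the standard conditions used throughout the suite
ens_mass_u3 <- function(mu)  # mean-clone-mass conditions at u_tilde = 1e-3
  switch(as.character(mu),
         "0.4" = cached_ensemble(0.4, 1e-3, 1e5, 20, 100L),
         "0.6" = cached_ensemble(0.6, 1e-3, 1e5, 20, 2200L),
         "1"   = cached_ensemble(1.0, 1e-3, 1e5, 20, 200L),
         "1.6" = cached_ensemble(1.6, 1e-3, 1e5, 20, 300L),
         "4"   = cached_ensemble(4.0, 1e-3, 1e5, 10, 2400L),
         stop("no cached conditions for mu = ", mu))

ens_lowmut_16 <- function() cached_ensemble(1.6, 1e-6, 1e5, 20, 400L)
ens_lowmut_4  <- function() cached_ensemble(4.0, 1e-6, 3e4, 10, 500L)
ens_tenallele <- function() cached_ensemble(2.5, 7e-7, 16384, 100, 600L)

ens_extent <- function(mu)   # clone-extent conditions at u_tilde = 1e-4
  switch(as.character(mu),
         "3"   = cached_ensemble(3.0, 1e-4, 1e5, 10, 700L),
         "1.5" = cached_ensemble(1.5, 1e-4, 1e5, 10, 800L),
         "0.8" = cached_ensemble(0.8, 1e-4, 1e5, 10, 900L),
         "0.5" = cached_ensemble(0.5, 1e-4, 1e5, 10, 1000L),
         "1"   = cached_ensemble(1.0, 1e-4, 1e5, 20, 1100L),
         stop("no cached conditions for mu = ", mu))

cached_clone_tables <- function(ens) {
  key <- paste0("ct_", digest_config(ens))
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- lapply(ens, extract_clones)
  sim_cache[[key]]
}

digest_config <- function(ens) {
  cfg <- attr(ens, "config")
  sprintf("mu%g_u%g_L%g_s%d", cfg$mu, cfg$u_tilde, cfg$L, cfg$seeds[1L])
}

# ensemble averages as reported for final-state quantities: range average
# within each simulation, then across simulations
extent_ratio <- function(ens) {
  cts <- cached_clone_tables(ens)
  mean(vapply(cts, function(ct) mean(ct$r_max), 1.0)) /
    mean(vapply(cts, function(ct) mean(ct$r_eq), 1.0))
}

mean_r_eq <- function(ens) {
  cts <- cached_clone_tables(ens)
  mean(vapply(cts, function(ct) mean(ct$r_eq), 1.0))
}

mean_r_max <- function(ens) {
  cts <- cached_clone_tables(ens)
  mean(vapply(cts, function(ct) mean(ct$r_max), 1.0))
}
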