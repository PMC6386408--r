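# independent 1D extent oracle: the clone's angular span (ring length minus
# its largest empty arc), halved and capped at L/2
extent_oracle_1d <- function(members, L) {
  m <- sort(members)
  if (length(m) == 1L) return(0)
  gaps <- diff(c(m, m[1L] + L))
  min((L - max(gaps)) / 2, L / 2)
}

test_that("clone extraction reproduces degenerate lattices exactly", {
  res <- run_sweep(100, mu = 1, u_tilde = 1e9, seed = 4)  # all demes unique
  ct <- extract_clones(res)
  expect_equal(nrow(ct), 100L)
  expect_true(all(ct$X == 1L))
  expect_true(all(ct$r_max == 0))

  fx <- make_tessellation_fixture(1000, 1)                # one clone
  ct <- extract_clones(fx)
  expect_equal(ct$X, 1000L)

  fx <- make_tessellation_fixture(1000, 10)               # 10 equal segments
  ct <- extract_clones(fx)
  expect_equal(ct$X, rep(100L, 10))
  expect_equal(ct$r_eq, rep(50, 10))
  expect_equal(ct$r_max, rep(49.5, 10))                   # span 99, halved
})

test_that("clone extraction flags corrupted results", {
  fx <- make_tessellation_fixture(100, 4)
  fx$grid[fx$grid == 4L] <- 1L   # allele 4 vanishes from the grid
  expect_error(extract_clones(fx), "corrupt")
})

test_that("1D extents equal half the periodic span", {
  expect_equal(clone_extent_1d(7, 100), 0)
  expect_equal(clone_extent_1d(c(0, 50), 100), 25)       # L/4
  expect_equal(clone_extent_1d(0:9, 100), 4.5)           # block of 10
  expect_error(clone_extent_1d(integer(0), 100), "empty")
  # wrap-aware: a block straddling the origin
  expect_equal(clone_extent_1d(c(95:99, 0:4), 100), 4.5)
  set.seed(42)
  for (i in 1:20) {
    L <- sample(50:500, 1)
    m <- sample(0:(L - 1), sample(2:30, 1))
    expect_equal(clone_extent_1d(m, L), extent_oracle_1d(m, L))
  }
})

test_that("2D extents use the eighth central moment with periodic centroids", {
  expect_equal(clone_extent_2d(cbind(3, 4), 100), 0)
  # two demes 2a apart: centroid midway, r_max8 = a
  expect_equal(clone_extent_2d(rbind(c(10, 10), c(10, 16)), 100), 3)
  # ring of 4 demes at distance a from the centroid
  a <- 5
  ring <- rbind(c(50 + a, 50), c(50 - a, 50), c(50, 50 + a), c(50, 50 - a))
  expect_equal(clone_extent_2d(ring, 100), a)
  # periodic wrap: points straddling the boundary stay compact
  expect_equal(clone_extent_2d(rbind(c(99, 0), c(1, 0)), 100), 1)
  expect_error(clone_extent_2d(matrix(0, 0, 2), 100), "empty")
})

test_that("single-clone occupancy matches contiguous-domain geometry", {
  # asymmetric contiguous clone on [origin - r1, origin + r2]:
  # rho = 1 up to r1, 1/2 up to r2, 0 beyond
  occ <- clone_occupancy(45:65, origin = 50, L = 1000)
  expect_equal(occ$rho[occ$r <= 5], rep(1, 5))
  expect_equal(occ$rho[occ$r > 5 & occ$r <= 15], rep(0.5, 10))
  expect_equal(max(occ$r), 15)
  expect_error(clone_occupancy(45:65, origin = 44, L = 1000), "not a member")
})

test_that("occupancy shells integrate back to the clone mass", {
  res <- run_sweep(3000, mu = 0.8, u_tilde = 1e-3, seed = 17)
  ct <- extract_clones(res)
  members <- split(seq_along(res$grid) - 1L, as.integer(res$grid))
  for (a in seq_len(nrow(ct))) {
    occ <- clone_occupancy(members[[a]], ct$x[a], 3000)
    expect_true(all(occ$rho >= 0 & occ$rho <= 1))
    expect_identical(sum(occ$occupied) + 1L, ct$X[a])  # exact mass identity
  }
})

test_that("compact tessellations have unit core occupancy and bounded support", {
  fx <- make_tessellation_fixture(10000, 20)
  prof <- occupancy_profile(fx, min_mass = 100)
  # contiguous symmetric clones live entirely within r/r_eq <= 2
  expect_true(all(prof$rho[prof$center > 2] == 0 |
                    !is.finite(prof$rho[prof$center > 2])))
  expect_gt(core_occupancy(prof), 0.99)
})

test_that("core occupancy integrates profile mass fractions", {
  # synthetic profile with half its integral inside r/r_eq <= 2
  centers <- seq(0.05, 4.45, by = 0.1)
  rho <- as.numeric(centers <= 2 | centers >= 2.5)
  prof <- structure(data.frame(lo = centers - 0.05, hi = centers + 0.05,
                               center = centers, rho = rho,
                               n_clones = 1),
                    class = c("occupancy_profile", "data.frame"))
  expect_equal(core_occupancy(prof), 0.5, tolerance = 0.05)
})

test_that("occupancy tails decay as r^-(mu+d) for broad kernels", {
  for (mu in c(0.5, 1)) {
    prof <- occupancy_profile(ens_extent(mu), min_mass = 100)
    sel <- prof$center >= 3 & prof$center <= 20 &
      is.finite(prof$rho) & prof$rho > 0
    slope <- unname(coef(lm(log(prof$rho[sel]) ~ log(prof$center[sel])))[2L])
    expect_lt(abs(slope + (mu + 1)), 0.3)
  }
})

test_that("core occupancy is near one for wavelike kernels and falls with mu", {
  co <- vapply(c("3", "1.5", "0.8"), function(m)
    core_occupancy(occupancy_profile(ens_extent(as.numeric(m)),
                                     min_mass = 100)), 1.0)
  expect_gte(co[["3"]], 0.95)
  expect_true(co[["3"]] > co[["1.5"]] && co[["1.5"]] > co[["0.8"]])
})

test_that("rescaled occupancy profiles collapse across mutation rates", {
  pa <- occupancy_profile(ens_mass_u3(1), min_mass = 50)
  pb <- occupancy_profile(ens_extent(1), min_mass = 50)
  ok <- is.finite(pa$rho) & is.finite(pb$rho) &
    pa$n_clones >= 20 & pb$n_clones >= 20
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(pa$rho[ok] - pb$rho[ok])), 0.1)
})
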