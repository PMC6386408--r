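test_that("degenerate clone configurations give the expected spectra", {
  fs <- frequency_spectrum(list(1000L), L = 1000)     # one clone at x = 1
  expect_equal(sum(fs$count), 1)
  expect_equal(fs$count[nrow(fs)], 1)                 # all mass in top bin
  expect_equal(spectrum_normalization(fs), 1, tolerance = 0.01)

  fs <- frequency_spectrum(list(rep(1L, 1000)), L = 1000)  # all singletons
  expect_equal(fs$count[1L], 1000)
  expect_equal(sum(fs$count[-1L]), 0)
  expect_equal(spectrum_normalization(fs), 1, tolerance = 0.01)

  expect_error(frequency_spectrum(list(c(10, 10)), L = 1000), "sum to")
})

test_that("estimated spectra integrate to one within binning tolerance", {
  for (mu in c("0.6", "1", "1.6", "4")) {
    fs <- frequency_spectrum(ens_mass_u3(as.numeric(mu)), L = 1e5)
    expect_equal(spectrum_normalization(fs), 1, tolerance = 0.01)
  }
})

test_that("rescaling is the identity at X_ave = L^d and preserves normalization", {
  fs <- frequency_spectrum(ens_mass_u3(1), L = 1e5)
  rs <- rescale_spectrum(fs, X_ave = 1e5)
  expect_equal(rs$s_mid, fs$x_mid)
  expect_equal(rs$g, fs$f)
  # with the estimated X_ave the rescaled curve still integrates to 1
  rs <- rescale_spectrum(fs)
  w <- rs$s_hi - rs$s_lo
  sbar <- w / log(rs$s_hi / rs$s_lo)
  expect_equal(sum(rs$g * w * sbar), 1, tolerance = 0.01)
})

test_that("spectra for one kernel collapse across mutation rates", {
  rs1 <- rescale_spectrum(frequency_spectrum(ens_mass_u3(1), L = 1e5))
  rs2 <- rescale_spectrum(frequency_spectrum(ens_extent(1), L = 1e5))
  f1 <- approxfun(log10(rs1$s_mid), log10(rs1$g))
  # common support, restricted to bins with >= 10 alleles per simulation
  # set on average in both ensembles
  sel <- rs2$count >= 10 & rs2$g > 0
  near <- vapply(log10(rs2$s_mid[sel]), function(z) {
    i <- which.min(abs(log10(rs1$s_mid) - z)); rs1$count[i]
  }, 1.0)
  dv <- abs(f1(log10(rs2$s_mid[sel][near >= 10])) -
              log10(rs2$g[sel][near >= 10]))
  dv <- dv[is.finite(dv)]
  expect_gte(length(dv), 5)
  expect_lt(max(dv), 0.2)
})

test_that("ansatz fits round-trip generated spectra", {
  # draw counts chosen so the expected total frequency is 1:
  # n = (p+2)/((p+1) x_c)
  set.seed(7)
  masses <- lapply(1:100, function(i)
    make_spectrum_fixture(20, L = 1e5, p = 0, x_c = 0.1))
  a <- fit_ansatz(frequency_spectrum(masses, L = 1e5))
  expect_true(a$cutoff_found)
  expect_lt(abs(a$p_raw - 0), 0.1)
  expect_lt(abs(log(a$x_c / 0.1)), log(1.5))

  set.seed(8)
  masses <- lapply(1:100, function(i)
    make_spectrum_fixture(15, L = 1e5, p = -0.5, x_c = 0.2))
  a <- fit_ansatz(frequency_spectrum(masses, L = 1e5))
  expect_lt(abs(a$p_raw + 0.5), 0.1)
  expect_lt(abs(log(a$x_c / 0.2)), log(1.5))
})

test_that("fitted exponents order with the kernel and are positive for wavelike spread", {
  ps <- vapply(c("0.6", "1", "1.6"), function(m)
    fit_ansatz(rescale_spectrum(frequency_spectrum(
      ens_mass_u3(as.numeric(m)), L = 1e5)))$p_raw, 1.0)
  expect_true(all(diff(ps) > 0))        # spectra flatten as mu grows
  expect_true(all(ps >= -1.2 & ps <= 1.2))
  a4 <- fit_ansatz(rescale_spectrum(frequency_spectrum(ens_lowmut_4(),
                                                       L = 3e4)))
  expect_gt(a4$p_raw, 0)                # rising spectrum, f ~ x^p with p > 0
  expect_gt(a4$p_raw, max(ps))
})

test_that("cutoff and exponent satisfy the mean-size identity", {
  # normalising the hard-cutoff ansatz ties the scaled cutoff to the
  # exponent: s_c = (p+2)/(p+1); checked within a factor 2 away from the
  # singular limit p -> -1
  for (mu in c(1, 1.6, 4)) {
    a <- fit_ansatz(rescale_spectrum(frequency_spectrum(
      ens_mass_u3(mu), L = 1e5)))
    id <- (a$p_raw + 2) / (a$p_raw + 1)
    expect_gt(id, 0)
    expect_lt(abs(log(a$x_c / id)), log(2))
  }
})

test_that("monoallelic sampling probabilities follow the moment identities", {
  expect_equal(p_hard_global(list(c(1000L)), 1000, j = c(2, 5)), c(1, 1))
  expect_equal(p_hard_global(list(c(500L, 500L)), 1000, j = 2), 0.5)
  expect_error(p_hard_global(list(1000L), 1000, j = 1), ">= 2")

  # closed form for the ansatz: P_hard(j) = (p+2)/(p+j+1) x_c^(j-1),
  # cross-checked against numerical quadrature of x^j f(x)
  for (p in c(-0.5, 0, 1)) {
    for (j in c(2, 3, 5)) {
      closed <- (p + 2) / (p + j + 1) * 0.1^(j - 1)
      quad <- integrate(function(x) x^j * (p + 2) / 0.1^(p + 2) * x^p,
                        0, 0.1, rel.tol = 1e-10)$value
      expect_equal(closed, quad, tolerance = 1e-8)
    }
  }

  ens <- ens_mass_u3(1)
  ph <- p_hard_global(ens, 1e5, j = 2:6)
  expect_true(all(diff(ph) < 0))        # non-increasing in sample size
  fs <- frequency_spectrum(ens, L = 1e5)
  for (j in 2:3)                        # binned spectrum agrees with lists
    expect_equal(p_hard_spectrum(fs, j), p_hard_global(ens, 1e5, j = j),
                 tolerance = 0.1)
})

test_that("equal-clone scaling normalises P_hard to one", {
  masses <- rep(100L, 10)               # 10 equal clones
  for (j in c(2, 3, 5)) {
    ph <- p_hard_global(list(masses), 1000, j = j)
    expect_equal(p_hard_scaled(ph, X_ave = 100, L = 1000, j = j), 1)
  }
  # j = 2 is the Simpson-index identity
  m <- c(600L, 300L, 100L)
  ph2 <- p_hard_global(list(m), 1000, j = 2)
  expect_equal(p_hard_scaled(ph2, mean(m), 1000, j = 2),
               1000 * sum((m / 1000)^2) / mean(m))
})

test_that("broader kernels keep more homozygosity than their mean size implies", {
  X06 <- mean_clone_mass(ens_mass_u3(0.6)); X16 <- mean_clone_mass(ens_mass_u3(1.6))
  s06 <- p_hard_scaled(p_hard_global(ens_mass_u3(0.6), 1e5, j = 3), X06, 1e5, j = 3)
  s16 <- p_hard_scaled(p_hard_global(ens_mass_u3(1.6), 1e5, j = 3), X16, 1e5, j = 3)
  expect_gt(s06, s16)
})

test_that("the Ewens monoallelic probability matches exact enumeration", {
  expect_equal(ewens_p_hard(1, 2), 0.5)
  expect_equal(ewens_p_hard(1, 3), 1 / 3)
  expect_equal(ewens_p_hard(1e-9, 2), 1, tolerance = 1e-8)  # theta -> 0
  for (j in 2:5)
    expect_equal(ewens_p_hard(1, j), crp_monoallelic(1, j), tolerance = 1e-12)
  expect_equal(ewens_p_hard(2.5, 4), crp_monoallelic(2.5, 4), tolerance = 1e-12)
  expect_error(ewens_p_hard(0, 2), "positive")
  expect_error(ewens_p_hard(1, 1), ">= 2")
})

test_that("subrange scans agree with direct window enumeration", {
  brute <- function(grid, L_s) {
    L <- length(grid)
    hom <- num <- numeric(L)
    for (s in 0:(L - 1)) {
      w <- grid[(s + seq_len(L_s) - 1L) %% L + 1L]
      tb <- table(w)
      hom[s + 1L] <- sum((tb / L_s)^2)
      num[s + 1L] <- length(tb)
    }
    c(mean(hom), mean(num))
  }
  res <- run_sweep(400, mu = 0.8, u_tilde = 5e-3, seed = 23)
  for (L_s in c(7, 60)) {
    bb <- brute(as.integer(res$grid), L_s)
    expect_equal(subrange_homoallelicity(res, L_s), bb[1L], tolerance = 1e-12)
    expect_equal(subrange_allele_count(res, L_s), bb[2L], tolerance = 1e-12)
  }
  fx <- make_tessellation_fixture(300, 6)
  bb <- brute(as.integer(fx$grid), 40)
  expect_equal(subrange_homoallelicity(fx, 40), bb[1L], tolerance = 1e-12)
})

test_that("windowed diversity hits its geometric limits", {
  one <- make_tessellation_fixture(500, 1)       # window inside a single core
  expect_equal(subrange_homoallelicity(one, 50), 1)
  two <- rep(1:2, each = 50)                     # window covering two equal clones
  expect_equal(subrange_homoallelicity(two, 100), 0.5)
  res <- run_sweep(1000, mu = 1, u_tilde = 1e-2, seed = 31)
  expect_equal(subrange_allele_count(res, 1000), allele_count(res))
  expect_equal(subrange_allele_count(res, 1), 1)
})

test_that("equal-clone tessellations follow the geometric null formula", {
  expect_equal(null_equal_clones(1e-9), 1, tolerance = 1e-8)
  expect_equal(null_equal_clones(1 - 1e-12), 2 / 3, tolerance = 1e-6)
  expect_equal(null_equal_clones(1), 2 / 3)       # continuity at x = 1
  expect_equal(null_equal_clones(2), 5 / 12)
  expect_error(null_equal_clones(0), "positive")

  fx <- make_tessellation_fixture(1000, 10)       # X_ave = 100
  for (L_s in c(50, 100, 200, 400)) {
    h <- subrange_homoallelicity(fx, L_s)         # exhaustive placement
    expect_lt(abs(h - null_equal_clones(L_s / 100)) /
                null_equal_clones(L_s / 100), 0.02)
  }
  # window much longer than a clone crosses ~ L_s/X_ave boundaries
  expect_equal(subrange_allele_count(fx, 350), 350 / 100 + 1, tolerance = 0.01)
})

test_that("subrange allele counts track the core density for compact clones", {
  ens <- ens_extent(3)
  r_eq <- mean_r_eq(ens); r_max <- mean_r_max(ens)
  for (L_s in c(2000, 5000)) {
    expect_gt(L_s / r_max, 2)                     # halo-free regime
    ncs <- subrange_allele_count(ens, L_s)
    expect_lt(abs(ncs - L_s / (2 * r_eq)) / (L_s / (2 * r_eq)), 0.2)
  }
})

test_that("kernel breadth inverts diversity between global and local samples", {
  glob <- vapply(c("0.6", "1", "4"), function(m)
    p_hard_global(ens_mass_u3(as.numeric(m)), 1e5, j = 2), 1.0)
  set.seed(91)
  loc <- vapply(c("0.6", "1", "4"), function(m)
    subrange_homoallelicity(ens_mass_u3(as.numeric(m)), 10,
                            n_windows = 300), 1.0)
  # globally, broad kernels look harder; in small windows the order flips
  expect_true(all(diff(glob) < 0))
  expect_true(all(diff(loc) > 0))
})
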