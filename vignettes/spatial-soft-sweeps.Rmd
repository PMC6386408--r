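---
title: "Modelling spatial soft sweeps with long-range dispersal"
author: "softsweeps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial soft sweeps with long-range dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softsweeps)
```

## The model

`softsweeps` simulates parallel adaptation in a spatially extended
population in which several independently arisen copies of an equally
beneficial allele spread at the same time — a *soft sweep*.  The habitat is
a periodic lattice of `L^d` demes (d = 1 or 2).  Under strong selection and
weak per-deme mutation and migration, the within-deme dynamics collapse to
a single rule, *allelic exclusion*: the first beneficial allele to
establish in a deme fixes there and excludes every later arrival.  Each
deme therefore carries one label — wildtype, or the k-th mutant allele to
have arisen.

Three quantities define a run:

* `L` — the linear range size (in demes);
* `mu` — the exponent of the fat-tailed dispersal kernel
  `J(r) = mu * r^-(1+mu)` on `r >= 1`.  Small `mu` makes long jumps common
  (the population approaches panmixia as `mu -> 0`); `mu > d + 1`
  reproduces wavelike, constant-speed spread;
* `u_tilde` — the rescaled mutation rate: mutation events per wildtype
  deme per dispersal attempt.  Time is measured in expected dispersal
  attempts per mutant deme, so `u_tilde` is the only rate in the model.
  The underlying individual-level parameters (selection coefficient, deme
  size, migration rate) enter only through this ratio and are deliberately
  not represented.

Each discrete event either mutates a uniformly chosen wildtype deme
(category weight `u_tilde * n_wt`) or attempts a migration from a
uniformly chosen mutant deme (weight `n_mut`).  A migration draws a
distance `r = u^(-1/mu)` from a uniform variate, a direction uniform on
the unit sphere, rounds each component to the nearest integer, and wraps
periodically; the target converts only if it is still wildtype.  Failed
migrations still advance the clock, which matters near sweep completion
when almost all targets are occupied.  By default each event advances time
by an exponential increment with mean `1/R`, `R = n_mut + u_tilde * n_wt`;
`deterministic_time = TRUE` uses fixed `1/R` increments, a variance-reduced
option we use when estimating growth curves.  A run ends when no wildtype
deme remains; by construction this state is absorbing, and a configurable
event ceiling (`max_events`) guards against runaway configurations.

Jumps are never truncated: a distance drawn far beyond `L` simply wraps.
Jumps longer than `L/2` therefore alias across the boundary, the honest
behaviour of a periodic habitat with no imposed cutoff.  Very rare
distances beyond 2^53 exceed exact double-precision rounding; they are
reduced modulo `L` deterministically, and at that magnitude the landing
deme is effectively uniform anyway.

```{r quick-run}
res <- run_sweep(L = 5000, mu = 1.3, u_tilde = 1e-3, seed = 1)
res
head(extract_clones(res), 3)
```

## Solitary-clone growth and the core-growth function

The geometry of a sweep is controlled by how a *single* clone would grow
unobstructed.  `run_solitary()` seeds one mutant in an otherwise wildtype
lattice (`u_tilde = 0`) and records the mass `M(t)` at every
colonisation.  The core-growth function is defined as the expected
mass-equivalent radius

> `ell(t) = E[(M(t)/omega_d)^(1/d)]`, with `omega_1 = 2`, `omega_2 = pi`,

estimated by `estimate_ell()` on a log-spaced time grid with
step-interpolation of each trace.  We treat this *tabulated* curve, wrapped
in a monotone log-log spline by `growth_law_tabulated()`, as the canonical
`ell(t)`: it is exactly the defined object, whereas closed forms are
asymptotic.  Evaluating a tabulated law outside its domain is an error
("simulate longer"), never a silent extrapolation; extrapolation is
available only through an explicitly fitted asymptotic form.

`fit_growth_form()` fits the regime-appropriate asymptotic shape with free
length and time factors `A` and `B`:

| regime          | asymptotic `ell(t)`          |
|-----------------|------------------------------|
| `mu > d + 1`    | `A t` (wavelike front)       |
| `d < mu < d+1`  | `A t^(1/(mu-d))`             |
| `mu = d + 1`    | `A (t/B) log(t/B)` (1D)      |
| `mu = d`        | `A exp(c log^2 t)`, `c` free |
| `mu < d`        | `A exp(B_mu (t/B)^eta)`      |

with `eta = log[4d/(d+mu)]/log 2` and `B_mu = 2d log(2)/(mu-d)^2`.  The
exponent `eta` exceeds 1 exactly when `mu < d` and tends to 1 at the
marginal point, which is the defining property of the
stretched-exponential regime; the prefactor `B_mu` is approximate, so `B`
is always refitted rather than trusted.  Near `mu = d` the asymptotics
converge extremely slowly; the marginal `log^2 t` form is fitted with `c`
free and we make no accuracy claim there beyond qualitative shape.

## Characteristic scales from mutation-expansion balance

With recurrent mutation, a growing core is eventually obstructed.  The
characteristic time `t*` balances growth against mutant influx: exactly
one new mutation is expected in the space-time volume swept by one core,

> `u_tilde * t* * omega_d * ell(t*)^d = 1`.

`solve_t_star()` brackets the (unique, by monotonicity) root geometrically
and refines it in log-time with `uniroot` at a relative tolerance of
1e-9.  From `t*` follow the scale set computed by
`characteristic_scales()`:

* `chi = ell(t*)` — the core extent, which sets the average clone mass
  `X_ave ~ omega_d * chi^d` and hence the expected number of origins
  `L^d/(omega_d chi^d)` (`expected_allele_count()`);
* `psi = ell(2 t*)` — the satellite extent: a satellite merging with a
  core at time `t` stems from a key jump near `t/2`, so a core grown for
  `t*` has seeded satellites out to `ell(2 t*)`;
* `zeta = u_tilde^(-1/mu)` — the outer limit of rare jumps, the distance
  beyond which fewer than one jump leaves a typical clone during `t*`.

`chi_asymptotic()` gives closed forms for `chi` per regime, derived by
solving the balance equation with the asymptotic `ell(t)` (Lambert-W
expressions, principal branch, in the stretched and `mu = d + 1` regimes);
tests require solver and closed form to agree to better than 0.1%.  The
magnitude factors relating `<X>` to `chi^d` (about 1.5–1.65 in the
reference simulations) are empirical and are not predicted by the package.

## Clone geometry and occupancy profiles

`extract_clones()` reduces a final lattice to per-clone measures: mass
`X`, mass-equivalent radius `r_eq = (X/omega_d)^(1/d)`, and extent
`r_max` — in 1D half the periodic span (largest circular gap subtracted
from `L`, halved, capped at `L/2`), in 2D the eighth-root of the mean
eighth power of distances from the periodic circular-mean centroid.  The
eighth-moment reading of the 2D extent is this package's convention; the
2D branch is exercised by tests but all quantitative claims are 1D.

`occupancy_profile()` measures `rho(r)`, the probability that a deme at
distance `r` from a clone's originating mutation belongs to the clone,
on integer shells rescaled by `r_eq` (bin width 0.1, support to 50 scaled
radii by default, clones with `X > 100`).  Compact contiguous clones are
confined to `r/r_eq <= 2`; long-range dispersal produces a halo tail
decaying as `r^-(d+mu)`.  `core_occupancy()` summarises the fraction of
occupancy inside `r/r_eq < 2` (trapezoidal integration on bin centres).
When we regress the tail slope in tests we use the window
`3 <= r/r_eq <= 20`: beyond the core shoulder, but inside the range where
desk-scale ensembles still populate bins well.

## Frequency spectra and sampling statistics

`frequency_spectrum()` estimates `f(x)`, the expected number of alleles
per unit frequency, on 50 logarithmic bins from the hard lower cutoff
`1/L^d` to 1, normalised so `integral x f(x) dx = 1`.  The lowest bin
shows a known uptick from the discrete cutoff; it is reported, not
corrected.  Each bin records its empirical mean frequency, so the first
moment (the normalisation check) is exact; higher moments from the binned
spectrum use the within-bin expectation under a log-uniform density,
which keeps their binning bias to a few percent at 50 bins (midpoint
evaluation is visibly worse).

`rescale_spectrum()` applies the self-similarity collapse: plotting
`(X_ave/L^d)^2 f(x)` against `s = L^d x / X_ave` superimposes spectra at
different mutation rates for the same kernel.  `fit_ansatz()` then
summarises a curve by the hard-cutoff power law `f ~ x^p` up to `x_c`:
the cutoff is placed at the steepest downward log-log curvature, accepted
when the second derivative passes the reference threshold of -4 (the
derivative is taken on a count-weighted smoothing spline; raw second
differences of sparse log-binned histograms are shot-noise dominated),
and `p` is the least-squares slope between the 5th percentile of the
populated support and `x_c/3`, a window that avoids both the lowest-bin
artifact and the cutoff shoulder.  Normalising the ansatz ties the scaled
cutoff to the exponent, `s_c = (p+2)/(p+1)`; the relation becomes singular
as `p -> -1` (the panmictic limit), where the cutoff is no longer
identified by the mean.

Sampling statistics are computed with replacement, consistent with the
moment form `P_hard(j) = integral x^j f(x) dx`:

* `p_hard_global()` — probability a global sample of size `j` is
  monoallelic (per-simulation `sum x_i^j`, ensemble averaged);
  `p_hard_scaled()` divides by the equal-clone expectation
  `(X_ave/L^d)^(j-1)`;
* `ewens_p_hard()` — the panmictic Ewens limit
  `prod_{i<j} i/(theta+i)`; `theta` is an explicit user parameter because
  its mapping onto `u_tilde L^d` involves model reductions the package
  does not carry;
* `subrange_homoallelicity()` / `subrange_allele_count()` — local
  diversity in contiguous windows of size `L_s`, averaged either over an
  exhaustive sliding scan (the default; an incremental update makes this
  O(L) per lattice) or over randomly placed windows;
  `null_equal_clones()` provides the geometric null for a tessellation of
  equal clones, with the argument `x = L_s/X_ave` (in 1D,
  `X_ave = 2 <r_eq>`).

## Synthetic data

Two generators make every analysis stage testable without running long
sweeps.  `make_tessellation_fixture()` builds the deterministic
equal-clone tessellation underlying the subrange null model.
`make_spectrum_fixture()` draws clone masses from a prescribed size
density — by default the hard-cutoff ansatz via inverse-CDF sampling
(`rfreq_ansatz()`) — rescaled and rounded by largest remainder to sum to
`L^d` exactly.  These fixtures emulate the *final-state* geometry of
sweeps, not the dynamics: they contain no haloes, no spatial correlation
between clone size and position, and no origin-time ordering, so tests
built on them validate the estimators, while claims about sweep behaviour
always rest on simulated ensembles.

## Study conditions and problem sizes

The package's tests and the acceptance script rerun the reference
conditions at desk scale: mean clone masses at `mu = {0.4, 1, 1.6}`,
`u_tilde = 1e-3` and at `{1.6, 4}`, `u_tilde = 1e-6`; allele counts at
`L = 16384`, `mu = 2.5`, `u_tilde = 7e-7`; extent ratios at
`u_tilde = 1e-4`.  Where the reference used ranges of 1e6–1e7 demes we
use `L = 1e5` (1e5 and 3e4 for the `u_tilde = 1e-6` conditions, keeping
roughly 25–100 expected origins): the mean clone mass is set by
mutation-expansion balance and is range-independent once `L >> chi`,
which the same tests verify via the scaling collapse.  Ensembles use
10–100 fixed seeds depending on the per-run cost; the compiled event loop
sustains roughly 1e7 events per second, so the full suite stays within
minutes on one CPU.

## Numerical choices and degenerate inputs

* Random streams: the engine uses its own 64-bit Mersenne Twister per
  replicate, seeded explicitly and recorded in outputs; R-level samplers
  (`sample_jump_offset()`, window placement, fixtures) draw from R's
  stream under `set.seed()`.  Ensemble seeds must be unique or the call
  errors.
* Periodic arithmetic: jump components are rounded first, then reduced
  modulo `L` in floating point with an exact floor-based reduction, so
  arbitrarily long jumps wrap without overflow.
* `u = 1` maps to the shortest jump `r = 1`; uniform variates are drawn
  in `(0, 1]` so `r` is never infinite.
* Degenerate sweeps: `L = 1` completes after one mutation;
  `u_tilde -> Inf` yields all-singleton lattices; both are tested limits.
* `estimate_ell()` accepts any number of traces (standard errors require
  at least two); grids beyond the shortest trace are truncated with a
  warning.
* Ties and caps: `r_max` is capped at `L/2`, the maximum measurable
  extent under periodic boundaries; the `r = L/2` occupancy shell has
  size 1 when `L` is even.

## Limitations

Within-deme dynamics (drift, the selection coefficient, deme size), back
mutation, and fitness differences among mutant alleles are outside the
reduced model; time is reported in rescaled units only, since converting
to generations needs parameters the reduction removed.  The 2D engine is
functional and tested for invariants, but occupancy profiles and subrange
statistics are implemented for 1D, where all quantitative reference
comparisons live.  Exact limiting spectra for the wavelike and panmictic
extremes are not implemented; the package exposes their small-frequency
behaviour only through the ansatz exponent bounds `p` in `[-1, 1]` and
the Ewens sampling limit.
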