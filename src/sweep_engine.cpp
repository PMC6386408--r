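// Event loop for the reduced deme-level soft-sweep model.
//
// State is a flat integer lattice (0 = wildtype, k >= 1 = k-th allele in
// order of originating mutation).  Each discrete event is either a mutation
// of a wildtype deme (relative weight u_tilde per WT deme) or an attempted
// migration out of a mutant deme (weight 1 per mutant deme).  Jump distances
// follow J(r) = mu * r^-(1+mu) on r >= 1, sampled as r = u^(-1/mu); the
// direction is uniform on the unit sphere; components are rounded to the
// nearest integer and wrapped periodically.  Time is advanced per event by
// an increment with mean 1/R, R = n_mut + u_tilde * n_wt (exponential by
// default, deterministic optionally), so one time unit is the expected
// interval between dispersal attempts per mutant deme.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Engine {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;

  explicit Engine(uint64_t seed) : rng(seed), unif(0.0, 1.0) {}

  // uniform in (0, 1]: avoids r = Inf at u = 0
  double u01_open0() { return 1.0 - unif(rng); }
  double u01() { return unif(rng); }
  int pick(int n) {  // uniform integer in [0, n)
    std::uniform_int_distribution<int> d(0, n - 1);
    return d(rng);
  }
  double rexp1() {  // unit-mean exponential
    return -std::log(u01_open0());
  }
};

// Reduce an integer-valued double mod L without fmod: exact for |s| < 2^53
// (both s and q*L are exactly representable integers; an off-by-one in the
// rounded quotient is repaired by the adjustment loop).  Beyond 2^53 the
// reduction is still deterministic and effectively uniform, which is all a
// periodically wrapped jump of that magnitude requires.
inline double reduce_mod(double s, double L) {
  double q = std::floor(s / L);
  double m = s - q * L;
  while (m < 0) m += L;
  while (m >= L) m -= L;
  return m;
}

// Periodic wrap of a (possibly astronomically large) real step.  The step is
// rounded to the nearest integer first, then reduced mod L while still a
// double, so no overflow occurs even for jumps of order u^(-1/mu) at tiny u.
inline int wrap_step(int src, double step, int L) {
  double m = reduce_mod(std::nearbyint(step), (double)L);
  int k = src + (int)m;
  if (k >= L) k -= L;
  return k;
}

inline int jump_target_1d(Engine &e, int src, double mu, int L) {
  double r = std::pow(e.u01_open0(), -1.0 / mu);
  double step = (e.u01() < 0.5) ? -r : r;
  return wrap_step(src, step, L);
}

inline int jump_target_2d(Engine &e, int src, double mu, int L) {
  double r = std::pow(e.u01_open0(), -1.0 / mu);
  double theta = 2.0 * M_PI * e.u01();
  int x = src % L, y = src / L;
  int xt = wrap_step(x, r * std::cos(theta), L);
  int yt = wrap_step(y, r * std::sin(theta), L);
  return xt + L * yt;
}

}  // namespace

// Full sweep: all demes start wildtype; run until none remains.
// [[Rcpp::export]]
List cpp_run_sweep(int L, int dim, double mu, double u_tilde,
                   double seed, bool deterministic_time,
                   bool record_fill_times, double max_events,
                   NumericVector snapshot_times) {
  if (L < 1) stop("L must be >= 1");
  if (dim != 1 && dim != 2) stop("dim must be 1 or 2");
  if (mu <= 0) stop("mu must be positive");
  if (u_tilde <= 0) stop("u_tilde must be positive");

  const R_xlen_t N = (dim == 1) ? (R_xlen_t)L : (R_xlen_t)L * L;
  Engine eng((uint64_t)seed);

  IntegerVector grid((R_xlen_t)N);           // 0 = wildtype
  std::vector<int> wt_list(N), wt_pos(N);    // swap-and-pop category list
  for (R_xlen_t i = 0; i < N; ++i) { wt_list[i] = i; wt_pos[i] = i; }
  std::vector<int> mut_list;
  mut_list.reserve(N);

  std::vector<int> origin_deme;
  std::vector<double> origin_time;
  NumericVector fill_times(record_fill_times ? N : 0);

  int n_wt = (int)N, n_mut = 0;
  double t = 0.0, events = 0.0;
  double n_mutations = 0.0, n_mig_ok = 0.0, n_mig_fail = 0.0;

  int n_snap = snapshot_times.size(), next_snap = 0;
  List snaps(n_snap);
  NumericVector snap_t_actual(n_snap);

  auto remove_wt = [&](int deme) {
    int i = wt_pos[deme], last = wt_list[n_wt - 1];
    wt_list[i] = last; wt_pos[last] = i;
    wt_pos[deme] = -1; --n_wt;
  };

  while (n_wt > 0) {
    if (++events > max_events)
      stop("event ceiling exceeded (%.3g events, %d wildtype demes left); "
           "raise max_events", events, n_wt);
    if (((long long)events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();

    double R = n_mut + u_tilde * n_wt;
    t += (deterministic_time ? 1.0 : eng.rexp1()) / R;

    while (next_snap < n_snap && t >= snapshot_times[next_snap]) {
      snaps[next_snap] = clone(grid);
      snap_t_actual[next_snap] = t;
      ++next_snap;
    }

    bool mutation = (n_mut == 0) ||
      (eng.u01() < u_tilde * n_wt / R);
    if (mutation) {
      int deme = wt_list[eng.pick(n_wt)];
      grid[deme] = (int)origin_deme.size() + 1;
      origin_deme.push_back(deme);
      origin_time.push_back(t);
      remove_wt(deme);
      mut_list.push_back(deme);
      ++n_mut; ++n_mutations;
      if (record_fill_times) fill_times[deme] = t;
    } else {
      int src = mut_list[eng.pick(n_mut)];
      int tgt = (dim == 1) ? jump_target_1d(eng, src, mu, L)
                           : jump_target_2d(eng, src, mu, L);
      if (grid[tgt] == 0) {
        grid[tgt] = grid[src];
        remove_wt(tgt);
        mut_list.push_back(tgt);
        ++n_mut; ++n_mig_ok;
        if (record_fill_times) fill_times[tgt] = t;
      } else {
        ++n_mig_fail;
      }
    }
  }

  while (next_snap < n_snap) {  // sweep finished before late snapshot times
    snaps[next_snap] = clone(grid);
    snap_t_actual[next_snap] = t;
    ++next_snap;
  }

  return List::create(
    _["grid"] = grid,
    _["origin_deme"] = IntegerVector(origin_deme.begin(), origin_deme.end()),
    _["origin_time"] = NumericVector(origin_time.begin(), origin_time.end()),
    _["total_time"] = t,
    _["n_events"] = events,
    _["n_mutations"] = n_mutations,
    _["n_mig_success"] = n_mig_ok,
    _["n_mig_fail"] = n_mig_fail,
    _["fill_times"] = fill_times,
    _["snapshots"] = snaps,
    _["snapshot_times"] = snap_t_actual);
}

// Solitary clone: one seeded mutant at the origin, u_tilde = 0; record
// (t, M) at every successful colonization until a stop condition.
// [[Rcpp::export]]
List cpp_run_solitary(int L, int dim, double mu, double seed,
                      double stop_mass, double t_max,
                      bool deterministic_time, double max_events) {
  if (L < 1) stop("L must be >= 1");
  if (dim != 1 && dim != 2) stop("dim must be 1 or 2");
  if (mu <= 0) stop("mu must be positive");

  const R_xlen_t N = (dim == 1) ? (R_xlen_t)L : (R_xlen_t)L * L;
  Engine eng((uint64_t)seed);

  std::vector<char> occ(N, 0);
  std::vector<int> mut_list;
  mut_list.reserve((size_t)std::min((double)N, stop_mass + 16));
  int origin = 0;  // coordinate 0 (or (0,0)); periodic lattice is homogeneous
  occ[origin] = 1;
  mut_list.push_back(origin);

  std::vector<double> times;
  std::vector<double> masses;
  times.push_back(0.0); masses.push_back(1.0);

  double t = 0.0, events = 0.0;
  int n_mut = 1;
  double wrap_mass = std::pow(0.4 * L, dim);
  bool wrap_warn = false;

  while (n_mut < (double)N && n_mut < stop_mass && t < t_max) {
    if (++events > max_events)
      stop("event ceiling exceeded (%.3g events at mass %d)", events, n_mut);
    if (((long long)events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();

    t += (deterministic_time ? 1.0 : eng.rexp1()) / n_mut;
    int src = mut_list[eng.pick(n_mut)];
    int tgt = (dim == 1) ? jump_target_1d(eng, src, mu, L)
                         : jump_target_2d(eng, src, mu, L);
    if (!occ[tgt]) {
      occ[tgt] = 1;
      mut_list.push_back(tgt);
      ++n_mut;
      times.push_back(t);
      masses.push_back((double)n_mut);
      if (!wrap_warn && n_mut > wrap_mass) wrap_warn = true;
    }
  }

  return List::create(
    _["times"] = NumericVector(times.begin(), times.end()),
    _["masses"] = NumericVector(masses.begin(), masses.end()),
    _["total_time"] = t,
    _["n_events"] = events,
    _["final_mass"] = (double)n_mut,
    _["wrap_warning"] = wrap_warn);
}

// Jump-offset sampler sharing the engine's code path (used for kernel
// distribution checks at volume).  Returned as doubles: offsets can exceed
// integer range for heavy tails.
// [[Rcpp::export]]
NumericMatrix cpp_sample_offsets(int n, double mu, int dim, double seed) {
  if (mu <= 0) stop("mu must be positive");
  if (dim != 1 && dim != 2) stop("dim must be 1 or 2");
  Engine eng((uint64_t)seed);
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i) {
    double r = std::pow(eng.u01_open0(), -1.0 / mu);
    if (dim == 1) {
      out(i, 0) = std::nearbyint((eng.u01() < 0.5) ? -r : r);
    } else {
      double theta = 2.0 * M_PI * eng.u01();
      out(i, 0) = std::nearbyint(r * std::cos(theta));
      out(i, 1) = std::nearbyint(r * std::sin(theta));
    }
  }
  return out;
}
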