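#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the pure-birth / birth-death / two-strain
// community jump processes. All functions draw from R's RNG stream, so
// set.seed() on the R side makes every result reproducible.

// Jump times of one pure-birth trajectory. `B` holds the rates
// B_{N0}, ..., B_{K-1}; simulation stops at absorption or at t_max.
// [[Rcpp::export]]
NumericVector cpp_pure_birth_jumps(NumericVector B, double t_max) {
  int S = B.size();
  std::vector<double> jumps;
  jumps.reserve(S);
  double t = 0.0;
  for (int i = 0; i < S; ++i) {
    if (B[i] <= 0.0) break;
    t += R::rexp(1.0 / B[i]);
    if (t > t_max) break;
    jumps.push_back(t);
  }
  return wrap(jumps);
}

// Population sizes (as counts above N0) of `reps` pure-birth replicates
// evaluated on a sorted time grid.
// [[Rcpp::export]]
IntegerMatrix cpp_pure_birth_ensemble(NumericVector B, NumericVector times,
                                      int reps) {
  int S = B.size(), T = times.size();
  IntegerMatrix counts(reps, T);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    int i = 0;  // births so far
    int j = 0;  // grid pointer
    while (j < T) {
      double tnext = R_PosInf;
      if (i < S && B[i] > 0.0) tnext = t + R::rexp(1.0 / B[i]);
      while (j < T && times[j] < tnext) {
        counts(r, j) = i;
        ++j;
      }
      if (!R_FINITE(tnext)) break;
      t = tnext;
      ++i;
    }
    for (; j < T; ++j) counts(r, j) = i;
  }
  return counts;
}

// One birth-death trajectory. `B` holds total birth rates for sizes 0..K
// (B[0] = 0; B[K] = 0 for density-limited models); deaths occur at rate d*N.
// Size 0 is absorbing; K is not when d > 0. Returns event times and sizes.
// [[Rcpp::export]]
List cpp_birth_death_traj(NumericVector B, double d, int N0, double t_max) {
  int K = B.size() - 1;
  std::vector<double> times;
  std::vector<int> sizes;
  double t = 0.0;
  int N = N0;
  while (true) {
    double rb = (N <= K) ? B[N] : 0.0;
    double rd = d * N;
    double rate = rb + rd;
    if (rate <= 0.0) break;  // N = 0, or N = K with d = 0
    t += R::rexp(1.0 / rate);
    if (t > t_max) break;
    N += (R::unif_rand() * rate < rb) ? 1 : -1;
    times.push_back(t);
    sizes.push_back(N);
    if (N == 0) break;
  }
  return List::create(_["times"] = wrap(times), _["sizes"] = wrap(sizes));
}

// Sizes of `reps` birth-death replicates on a sorted grid, plus a flag for
// extinction (absorption at 0) within the grid horizon.
// [[Rcpp::export]]
List cpp_birth_death_ensemble(NumericVector B, double d, int N0,
                              NumericVector times, int reps) {
  int K = B.size() - 1, T = times.size();
  IntegerMatrix sizes(reps, T);
  LogicalVector extinct(reps);
  double t_max = times[T - 1];
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    int N = N0, j = 0;
    while (true) {
      double rb = (N <= K) ? B[N] : 0.0;
      double rd = d * N;
      double rate = rb + rd;
      double tnext = (rate > 0.0) ? t + R::rexp(1.0 / rate) : R_PosInf;
      while (j < T && times[j] < tnext) sizes(r, j++) = N;
      if (tnext > t_max || !R_FINITE(tnext)) break;
      t = tnext;
      N += (R::unif_rand() * rate < rb) ? 1 : -1;
      if (N == 0) { extinct[r] = true; }
    }
    for (; j < T; ++j) sizes(r, j) = N;
  }
  return List::create(_["sizes"] = sizes, _["extinct"] = extinct);
}

static inline void community_grow(const NumericVector& g, double bW, double bM,
                                  int& N, int& n, double t_max) {
  // grow a two-strain community from state (N, n) for a duration t_max
  double t = 0.0;
  while (true) {
    double rm = bM * g[N] * n;
    double rw = bW * g[N] * (N - n);
    double rate = rm + rw;
    if (rate <= 0.0) break;  // N = K (g = 0) or empty
    t += R::rexp(1.0 / rate);
    if (t > t_max) break;
    if (R::unif_rand() * rate < rm) ++n;
    ++N;
  }
}

// One community trajectory: g holds the per-capita density factor g(N) for
// N = 0..K; strains share g but have their own intrinsic rates.
// [[Rcpp::export]]
List cpp_community_traj(NumericVector g, double bW, double bM,
                        int N0, int n0, double t_max) {
  std::vector<double> times;
  std::vector<int> Ns, ns;
  double t = 0.0;
  int N = N0, n = n0;
  while (true) {
    double rm = bM * g[N] * n;
    double rw = bW * g[N] * (N - n);
    double rate = rm + rw;
    if (rate <= 0.0) break;
    t += R::rexp(1.0 / rate);
    if (t > t_max) break;
    if (R::unif_rand() * rate < rm) ++n;
    ++N;
    times.push_back(t);
    Ns.push_back(N);
    ns.push_back(n);
  }
  return List::create(_["times"] = wrap(times), _["sizes"] = wrap(Ns),
                      _["mutants"] = wrap(ns));
}

// Community ensemble on a sorted grid: total size and mutant count.
// [[Rcpp::export]]
List cpp_community_ensemble(NumericVector g, double bW, double bM,
                            int N0, int n0, NumericVector times, int reps) {
  int T = times.size();
  IntegerMatrix Nmat(reps, T), nmat(reps, T);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    int N = N0, n = n0, j = 0;
    while (true) {
      double rm = bM * g[N] * n;
      double rw = bW * g[N] * (N - n);
      double rate = rm + rw;
      double tnext = (rate > 0.0) ? t + R::rexp(1.0 / rate) : R_PosInf;
      while (j < T && times[j] < tnext) {
        Nmat(r, j) = N;
        nmat(r, j) = n;
        ++j;
      }
      if (j >= T || !R_FINITE(tnext)) break;
      t = tnext;
      if (R::unif_rand() * rate < rm) ++n;
      ++N;
    }
    for (; j < T; ++j) { Nmat(r, j) = N; nmat(r, j) = n; }
  }
  return List::create(_["sizes"] = Nmat, _["mutants"] = nmat);
}

// Serial-passage replicates: grow for tau, then binomial bottleneck back to
// N0 individuals, until the mutant count hits 0 (loss) or N0 (fixation).
// Returns +(cycles+1) on fixation, -(cycles+1) on loss, NA if max_cycles
// was exceeded before absorption.
// [[Rcpp::export]]
IntegerVector cpp_serial_passage(NumericVector g, double bW, double bM,
                                 int N0, int n0, double tau, int reps,
                                 int max_cycles) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    int n = n0;
    int cycles = 0;
    int res = NA_INTEGER;
    while (cycles < max_cycles) {
      if (n == 0) { res = -(cycles + 1); break; }
      if (n == N0) { res = cycles + 1; break; }
      int N = N0, nn = n;
      community_grow(g, bW, bM, N, nn, tau);
      n = (int) R::rbinom((double) N0, (double) nn / (double) N);
      ++cycles;
    }
    out[r] = res;
  }
  return out;
}
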