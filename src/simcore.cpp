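// Mass-action simulation core: propensity evaluation, ODE right-hand side,
// and stochastic simulation (Gillespie direct method, optional tau-leaping).
//
// Reactions are at most bimolecular. Each reaction j is encoded by two
// reactant slots r1[j], r2[j] (0-based species index, -1 = empty slot;
// r1 == r2 encodes a homodimerization 2A -> ...). The stoichiometric change
// is column j of the (species x reactions) matrix S.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double propensity_one(const double* x, double k, int a, int b,
                                    bool stochastic) {
  if (k == 0.0) return 0.0;
  if (a < 0) return k;                 // zeroth order (source)
  if (b < 0) return k * x[a];          // unimolecular
  if (a == b) {                        // homodimerization
    double n = x[a];
    return stochastic ? k * n * (n - 1.0) / 2.0 : k * n * n / 2.0;
  }
  return k * x[a] * x[b];              // heterobimolecular
}

// [[Rcpp::export(name = ".cpp_propensities")]]
NumericVector cpp_propensities(NumericVector state, NumericVector k,
                               IntegerVector r1, IntegerVector r2,
                               bool stochastic) {
  const int m = k.size();
  NumericVector a(m);
  const double* x = state.begin();
  for (int j = 0; j < m; ++j)
    a[j] = propensity_one(x, k[j], r1[j], r2[j], stochastic);
  return a;
}

// ODE right-hand side dx/dt = S %*% rates(x); deterministic rate convention.
// [[Rcpp::export(name = ".cpp_deriv")]]
NumericVector cpp_deriv(NumericVector state, NumericVector k,
                        IntegerVector r1, IntegerVector r2,
                        IntegerMatrix S) {
  const int n = S.nrow(), m = S.ncol();
  NumericVector dx(n);
  // negative transients from the integrator are clipped to 0 for rate
  // evaluation so bimolecular terms cannot turn into spurious sources
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = state[i] > 0.0 ? state[i] : 0.0;
  for (int j = 0; j < m; ++j) {
    double a = propensity_one(x.data(), k[j], r1[j], r2[j], false);
    if (a == 0.0) continue;
    for (int i = 0; i < n; ++i) {
      int s = S(i, j);
      if (s != 0) dx[i] += s * a;
    }
  }
  return dx;
}

// splitmix64: derive well-separated per-cell seeds from (master, counter)
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".cpp_stream_seed")]]
double cpp_stream_seed(double master, double counter) {
  uint64_t s = splitmix64(((uint64_t)master << 20) ^ (uint64_t)counter);
  // keep the R-facing value in [0, 2^31) so it is a valid R integer seed
  return (double)(s % 2147483647ULL);
}

// Exact direct-method SSA sampled onto an output grid (last-event hold).
// [[Rcpp::export(name = ".cpp_ssa_direct")]]
NumericMatrix cpp_ssa_direct(NumericVector init, NumericVector k,
                             IntegerVector r1, IntegerVector r2,
                             IntegerMatrix S, NumericVector times,
                             double seed) {
  const int n = S.nrow(), m = S.ncol(), nt = times.size();
  std::mt19937_64 rng(splitmix64((uint64_t)seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(m);
  NumericMatrix out(nt, n);
  double t = times[0];
  int it = 0;
  // record initial state
  for (int i = 0; i < n; ++i) out(0, i) = x[i];
  it = 1;

  while (it < nt) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      a[j] = propensity_one(x.data(), k[j], r1[j], r2[j], true);
      a0 += a[j];
    }
    if (a0 <= 0.0) { // absorbing: hold state to end of grid
      for (; it < nt; ++it)
        for (int i = 0; i < n; ++i) out(it, i) = x[i];
      break;
    }
    double u1 = U(rng);
    double tau = -std::log(u1 > 0.0 ? u1 : 1e-300) / a0;
    double tnext = t + tau;
    while (it < nt && times[it] < tnext) {
      for (int i = 0; i < n; ++i) out(it, i) = x[i];
      ++it;
    }
    if (it >= nt) break;
    t = tnext;
    double u2 = U(rng) * a0, c = 0.0;
    int jfire = m - 1;
    for (int j = 0; j < m; ++j) {
      c += a[j];
      if (u2 <= c) { jfire = j; break; }
    }
    for (int i = 0; i < n; ++i) {
      int s = S(i, jfire);
      if (s != 0) x[i] += s;
    }
  }
  return out;
}

// Adaptive tau-leaping (Cao et al. step-size selection, non-negativity by
// tau halving, exact SSA fallback when tau would be smaller than a few
// direct steps). Approximate; validated against the direct method in tests.
// [[Rcpp::export(name = ".cpp_ssa_tau")]]
NumericMatrix cpp_ssa_tau(NumericVector init, NumericVector k,
                          IntegerVector r1, IntegerVector r2,
                          IntegerMatrix S, NumericVector times,
                          double seed, double epsilon) {
  const int n = S.nrow(), m = S.ncol(), nt = times.size();
  std::mt19937_64 rng(splitmix64((uint64_t)seed) ^ 0xA5A5A5A5ULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(m);
  NumericMatrix out(nt, n);
  for (int i = 0; i < n; ++i) out(0, i) = x[i];
  double t = times[0];
  int it = 1;
  const double t_end = times[nt - 1];

  while (t < t_end && it < nt) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      a[j] = propensity_one(x.data(), k[j], r1[j], r2[j], true);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;

    // step-size selection: limit expected relative change per species
    double tau = t_end - t;
    for (int i = 0; i < n; ++i) {
      double mu = 0.0, s2 = 0.0;
      for (int j = 0; j < m; ++j) {
        int s = S(i, j);
        if (s != 0 && a[j] > 0.0) { mu += s * a[j]; s2 += (double)s * s * a[j]; }
      }
      if (s2 == 0.0) continue;
      double xi = x[i] > 1.0 ? x[i] : 1.0;
      double bound = epsilon * xi;
      if (bound < 1.0) bound = 1.0;
      double t1 = mu != 0.0 ? bound / std::fabs(mu) : tau;
      double t2 = bound * bound / s2;
      if (t1 < tau) tau = t1;
      if (t2 < tau) tau = t2;
    }

    if (tau < 10.0 / a0) {
      // regime where leaping gains nothing: take ~100 exact steps
      for (int step = 0; step < 100 && t < t_end; ++step) {
        a0 = 0.0;
        for (int j = 0; j < m; ++j) {
          a[j] = propensity_one(x.data(), k[j], r1[j], r2[j], true);
          a0 += a[j];
        }
        if (a0 <= 0.0) { t = t_end; break; }
        double u1 = U(rng);
        t += -std::log(u1 > 0.0 ? u1 : 1e-300) / a0;
        while (it < nt && times[it] < t) {
          for (int i = 0; i < n; ++i) out(it, i) = x[i];
          ++it;
        }
        if (t >= t_end) break;
        double u2 = U(rng) * a0, c = 0.0;
        int jf = m - 1;
        for (int j = 0; j < m; ++j) { c += a[j]; if (u2 <= c) { jf = j; break; } }
        for (int i = 0; i < n; ++i) { int s = S(i, jf); if (s != 0) x[i] += s; }
      }
      continue;
    }

    // attempt leap, halving tau until no species goes negative
    for (;;) {
      std::vector<double> xn(x);
      bool ok = true;
      for (int j = 0; j < m; ++j) {
        if (a[j] <= 0.0) continue;
        std::poisson_distribution<long> P(a[j] * tau);
        long nj = P(rng);
        if (nj == 0) continue;
        for (int i = 0; i < n; ++i) {
          int s = S(i, j);
          if (s != 0) xn[i] += (double)s * nj;
        }
      }
      for (int i = 0; i < n; ++i) if (xn[i] < 0.0) { ok = false; break; }
      if (ok) {
        double tnext = t + tau;
        while (it < nt && times[it] < tnext) {
          for (int i = 0; i < n; ++i) out(it, i) = x[i];
          ++it;
        }
        x.swap(xn);
        t = tnext;
        break;
      }
      tau *= 0.5;
      if (tau < 1e-12) { t = t_end; break; }
    }
  }
  for (; it < nt; ++it)
    for (int i = 0; i < n; ++i) out(it, i) = x[i];
  return out;
}
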