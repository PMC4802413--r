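// Simulation kernels: a stack-machine evaluator for rate-law bytecode,
// the ODE right-hand side, and stochastic engines (Gillespie direct method
// with reaction-dependency updates, and an explicit tau-leap).
//
// Rate laws arrive as flat bytecode compiled in R (see compile_network):
//   op 1 PUSH_CONST(arg -> consts[arg-1])
//   op 2 PUSH_SPECIES(arg -> state[arg-1])
//   op 3 PUSH_PARAM(arg -> params[arg-1])
//   op 4..8 ADD SUB MUL DIV POW, op 9 NEG
//
// Stochastic propensities use the system-size convention: for counts n and
// size omega, a_j = omega * f_j(n / omega), which reproduces k/omega scaling
// for bimolecular and k*omega for zero-order mass-action terms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int MAX_STACK = 64;

static inline double eval_one(const int* ops, const int* args, int from, int to,
                              const double* consts, const double* x,
                              const double* p, double* stack) {
  int sp = 0;
  for (int i = from; i < to; ++i) {
    switch (ops[i]) {
    case 1: stack[sp++] = consts[args[i] - 1]; break;
    case 2: stack[sp++] = x[args[i] - 1]; break;
    case 3: stack[sp++] = p[args[i] - 1]; break;
    case 4: sp--; stack[sp - 1] += stack[sp]; break;
    case 5: sp--; stack[sp - 1] -= stack[sp]; break;
    case 6: sp--; stack[sp - 1] *= stack[sp]; break;
    case 7: sp--; stack[sp - 1] /= stack[sp]; break;
    case 8: sp--; stack[sp - 1] = std::pow(stack[sp - 1], stack[sp]); break;
    case 9: stack[sp - 1] = -stack[sp - 1]; break;
    }
  }
  return stack[0];
}

// [[Rcpp::export]]
NumericVector eval_rates_cpp(IntegerVector ops, IntegerVector args,
                             NumericVector consts, IntegerVector offsets,
                             NumericVector state, NumericVector params) {
  int M = offsets.size() - 1;
  NumericVector out(M);
  double stack[MAX_STACK];
  for (int j = 0; j < M; ++j)
    out[j] = eval_one(ops.begin(), args.begin(), offsets[j], offsets[j + 1],
                      consts.begin(), state.begin(), params.begin(), stack);
  return out;
}

// ODE right-hand side: S %*% rates via stoichiometry triplets (0-based).
// [[Rcpp::export]]
NumericVector deriv_cpp(IntegerVector ops, IntegerVector args,
                        NumericVector consts, IntegerVector offsets,
                        IntegerVector tri_rx, IntegerVector tri_sp,
                        NumericVector tri_coef, int n_species,
                        NumericVector state, NumericVector params) {
  int M = offsets.size() - 1;
  std::vector<double> rates(M);
  double stack[MAX_STACK];
  for (int j = 0; j < M; ++j)
    rates[j] = eval_one(ops.begin(), args.begin(), offsets[j], offsets[j + 1],
                        consts.begin(), state.begin(), params.begin(), stack);
  NumericVector d(n_species);
  int nt = tri_rx.size();
  for (int t = 0; t < nt; ++t)
    d[tri_sp[t]] += tri_coef[t] * rates[tri_rx[t]];
  return d;
}

// ---- counter-based RNG: splitmix64 seeding + xoshiro256++ ------------------

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0,1)
  double unif() {
    double u = (next() >> 11) * 1.1102230246251565e-16;
    return u > 0 ? u : 5e-324;
  }
  double expo() { return -std::log(unif()); }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  // Poisson: Knuth for small mean, normal approximation for large
  double pois(double lambda) {
    if (lambda <= 0) return 0.0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    double v = std::floor(lambda + std::sqrt(lambda) * norm() + 0.5);
    return v < 0 ? 0.0 : v;
  }
};

// Combine a global seed with a stream index into one 64-bit seed.
// [[Rcpp::export]]
double stream_seed_cpp(double seed, double stream) {
  uint64_t x = (uint64_t)seed * 0x9e3779b97f4a7c15ULL + (uint64_t)stream;
  uint64_t z = Xoshiro::splitmix64(x);
  // return as double exactly representable (53 bits)
  return (double)(z >> 11);
}

// ---- Gillespie direct method ----------------------------------------------

// [[Rcpp::export]]
List ssa_cpp(IntegerVector ops, IntegerVector args, NumericVector consts,
             IntegerVector offsets,
             IntegerVector tri_rx, IntegerVector tri_sp, NumericVector tri_coef,
             int n_species, List depends,
             NumericVector init_counts, NumericVector params, double omega,
             double t0, double t_end, NumericVector grid,
             double seed, double max_steps) {
  int M = offsets.size() - 1;
  std::vector<double> n(init_counts.begin(), init_counts.end());
  std::vector<double> x(n_species);
  std::vector<double> a(M);
  double stack[MAX_STACK];
  // pre-extract dependency lists (1-based from R)
  std::vector< std::vector<int> > dep(M);
  for (int j = 0; j < M; ++j) {
    IntegerVector dj = depends[j];
    dep[j].assign(dj.begin(), dj.end());
  }
  // triplets grouped by reaction for state updates
  std::vector< std::vector< std::pair<int, double> > > change(M);
  for (int t = 0; t < tri_rx.size(); ++t)
    change[tri_rx[t]].push_back(std::make_pair(tri_sp[t], tri_coef[t]));

  Xoshiro rng((uint64_t)seed);

  int G = grid.size();
  NumericMatrix out(G, n_species);
  int g = 0;

  for (int i = 0; i < n_species; ++i) x[i] = n[i] / omega;
  double a0 = 0;
  for (int j = 0; j < M; ++j) {
    a[j] = omega * eval_one(ops.begin(), args.begin(), offsets[j], offsets[j + 1],
                            consts.begin(), x.data(), params.begin(), stack);
    if (a[j] < 0) {
      if (a[j] < -1e-9 * std::max(1.0, omega))
        stop("negative propensity in reaction %d", j + 1);
      a[j] = 0;
    }
    a0 += a[j];
  }

  double t = t0;
  double steps = 0;
  while (t < t_end) {
    if (a0 <= 0) break;
    double dt = rng.expo() / a0;
    double t_next = t + dt;
    while (g < G && grid[g] <= t_next && grid[g] <= t_end) {
      for (int i = 0; i < n_species; ++i) out(g, i) = n[i];
      ++g;
    }
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;
    // select reaction
    double r = rng.unif() * a0, c = 0;
    int mu = M - 1;
    for (int j = 0; j < M; ++j) { c += a[j]; if (r <= c) { mu = j; break; } }
    // fire
    for (size_t q = 0; q < change[mu].size(); ++q) {
      int i = change[mu][q].first;
      n[i] += change[mu][q].second;
      if (n[i] < 0) n[i] = 0;  // guard; propensity forms keep this rare
      x[i] = n[i] / omega;
    }
    // update dependent propensities
    for (size_t q = 0; q < dep[mu].size(); ++q) {
      int j = dep[mu][q] - 1;
      a0 -= a[j];
      double aj = omega * eval_one(ops.begin(), args.begin(), offsets[j],
                                   offsets[j + 1], consts.begin(), x.data(),
                                   params.begin(), stack);
      if (aj < 0) {
        if (aj < -1e-9 * std::max(1.0, omega))
          stop("negative propensity in reaction %d", j + 1);
        aj = 0;
      }
      a[j] = aj; a0 += aj;
    }
    steps += 1;
    if (steps >= max_steps)
      stop("SSA exceeded max_steps (%.0f) at t = %.4f", max_steps, t);
    // refresh the propensity sum occasionally to kill accumulation error
    if (((uint64_t)steps & 0xFFFF) == 0) {
      a0 = 0;
      for (int j = 0; j < M; ++j) a0 += a[j];
    }
  }
  // fill remaining grid points with the final state
  while (g < G) {
    for (int i = 0; i < n_species; ++i) out(g, i) = n[i];
    ++g;
  }
  return List::create(_["counts"] = out,
                      _["final"] = NumericVector(n.begin(), n.end()),
                      _["steps"] = steps);
}

// ---- explicit tau-leap ------------------------------------------------------

// [[Rcpp::export]]
List tau_leap_cpp(IntegerVector ops, IntegerVector args, NumericVector consts,
                  IntegerVector offsets,
                  IntegerVector tri_rx, IntegerVector tri_sp,
                  NumericVector tri_coef, int n_species,
                  NumericVector init_counts, NumericVector params, double omega,
                  double t0, double t_end, NumericVector grid,
                  double seed, double epsilon, NumericVector max_counts,
                  double max_steps) {
  int M = offsets.size() - 1;
  std::vector<double> n(init_counts.begin(), init_counts.end());
  std::vector<double> x(n_species), a(M), mu(n_species), sig2(n_species);
  std::vector<double> k(M);
  double stack[MAX_STACK];
  std::vector< std::vector< std::pair<int, double> > > change(M);
  for (int t = 0; t < tri_rx.size(); ++t)
    change[tri_rx[t]].push_back(std::make_pair(tri_sp[t], tri_coef[t]));

  Xoshiro rng((uint64_t)seed);
  int G = grid.size();
  NumericMatrix out(G, n_species);
  int g = 0;
  double t = t0, steps = 0;

  while (t < t_end) {
    for (int i = 0; i < n_species; ++i) { x[i] = n[i] / omega; mu[i] = 0; sig2[i] = 0; }
    double a0 = 0;
    for (int j = 0; j < M; ++j) {
      double aj = omega * eval_one(ops.begin(), args.begin(), offsets[j],
                                   offsets[j + 1], consts.begin(), x.data(),
                                   params.begin(), stack);
      if (aj < 0) aj = 0;
      a[j] = aj; a0 += aj;
      for (size_t q = 0; q < change[j].size(); ++q) {
        mu[change[j][q].first] += change[j][q].second * aj;
        sig2[change[j][q].first] += change[j][q].second * change[j][q].second * aj;
      }
    }
    if (a0 <= 0) break;
    // Cao-style step control on species populations
    double tau = t_end - t;
    for (int i = 0; i < n_species; ++i) {
      double bound = std::max(epsilon * n[i], 1.0);
      if (std::fabs(mu[i]) > 0) tau = std::min(tau, bound / std::fabs(mu[i]));
      if (sig2[i] > 0) tau = std::min(tau, bound * bound / sig2[i]);
    }
    if (tau <= 0) tau = 1e-8;
    bool ok = false;
    int tries = 0;
    std::vector<double> n_new(n_species);
    while (!ok && tries < 40) {
      for (int j = 0; j < M; ++j) k[j] = rng.pois(a[j] * tau);
      for (int i = 0; i < n_species; ++i) n_new[i] = n[i];
      for (int j = 0; j < M; ++j)
        if (k[j] > 0)
          for (size_t q = 0; q < change[j].size(); ++q)
            n_new[change[j][q].first] += change[j][q].second * k[j];
      ok = true;
      for (int i = 0; i < n_species; ++i)
        if (n_new[i] < 0) { ok = false; break; }
      if (!ok) { tau /= 2; ++tries; }
    }
    if (!ok) stop("tau-leap could not find a nonnegative step at t = %.4f", t);
    for (int i = 0; i < n_species; ++i) {
      n[i] = n_new[i];
      if (R_finite(max_counts[i]) && n[i] > max_counts[i]) n[i] = max_counts[i];
    }
    double t_next = t + tau;
    while (g < G && grid[g] <= t_next && grid[g] <= t_end) {
      for (int i = 0; i < n_species; ++i) out(g, i) = n[i];
      ++g;
    }
    t = t_next;
    steps += 1;
    if (steps >= max_steps) stop("tau-leap exceeded max_steps");
  }
  while (g < G) {
    for (int i = 0; i < n_species; ++i) out(g, i) = n[i];
    ++g;
  }
  return List::create(_["counts"] = out,
                      _["final"] = NumericVector(n.begin(), n.end()),
                      _["steps"] = steps);
}
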