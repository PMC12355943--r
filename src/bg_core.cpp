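// Piecewise-analytic forward engine for the multi-route buffered GUTS
// cascade.  Exposure is piecewise constant, so on every inter-breakpoint
// interval each state is an "exponential polynomial"
//
//   D(tau) = c0 + sum_j (a_j + b_j * tau) * exp(-r_j * tau),  tau in [0, L]
//
// (the b_j terms only appear in the confluent case k_d == eta).  All
// propagation, the SD exceedance-hazard integral and the IT running
// maximum are evaluated in closed form on this representation; the only
// numeric steps are bisections for threshold-crossing and stationary
// times, refined to ~1e-14 of the interval length.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct ExpPoly {
  double c0;
  std::vector<double> r, a, b;  // coefficient (a + b*tau) on exp(-r*tau)

  double eval(double tau) const {
    double v = c0;
    for (size_t j = 0; j < r.size(); ++j)
      v += (a[j] + b[j] * tau) * std::exp(-r[j] * tau);
    return v;
  }
  double deriv(double tau) const {
    double v = 0.0;
    for (size_t j = 0; j < r.size(); ++j)
      v += (b[j] - r[j] * (a[j] + b[j] * tau)) * std::exp(-r[j] * tau);
    return v;
  }
  // antiderivative of (D(tau) - z); exact up to floating point
  double antideriv(double tau, double z) const {
    double v = (c0 - z) * tau;
    for (size_t j = 0; j < r.size(); ++j)
      v -= std::exp(-r[j] * tau) *
           ((a[j] + b[j] * tau) / r[j] + b[j] / (r[j] * r[j]));
    return v;
  }
  void add_term(double rate, double coef_a, double coef_b = 0.0) {
    for (size_t j = 0; j < r.size(); ++j) {
      if (r[j] == rate) { a[j] += coef_a; b[j] += coef_b; return; }
    }
    r.push_back(rate); a.push_back(coef_a); b.push_back(coef_b);
  }
};

// relative threshold below which k_d and eta are treated as equal and the
// confluent (tau * exp) solution is used instead of the two-exponential one
const double kEqTol = 1e-8;

// bisection for f(tau) = target between lo and hi (f monotone there)
template <typename F>
double bisect(F f, double lo, double hi, double flo) {
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (mid == lo || mid == hi) break;
    double fm = f(mid);
    if ((fm > 0) == (flo > 0)) { lo = mid; flo = fm; } else { hi = mid; }
    if (hi - lo < 1e-15 * std::max(1.0, std::abs(hi))) break;
  }
  return 0.5 * (lo + hi);
}

// Append the single-route damage solution on one interval to `out`:
//   dD/dt = k (B - D),  B(tau) = C + A exp(-eta tau),  D(0) = D0
// scaled by weight w.  Returns nothing; the caller reads state at L via
// the assembled polynomial.
void add_damage_terms(ExpPoly &out, double w, double k, double eta,
                      double C, double A, double D0) {
  out.c0 += w * C;
  if (std::abs(k - eta) > kEqTol * std::max(k, eta)) {
    double P = k * A / (k - eta);
    out.add_term(eta, w * P);
    out.add_term(k, w * (D0 - C - P));
  } else {
    // confluent limit: D = C + ((D0 - C) + k A tau) exp(-k tau)
    out.add_term(k, w * (D0 - C), w * k * A);
  }
}

struct IntervalResult {
  ExpPoly D;                       // combined damage, route-1 units
  std::vector<double> nodes;       // sorted, include 0 and L, all out times,
                                   // stationary points and z-crossings
  std::vector<double> Dnodes;      // D at nodes
  std::vector<double> Hnodes;      // cumulative exceedance integral at nodes
};

// Build the node grid and exact exceedance integral for one interval.
void scan_interval(const ExpPoly &D, double L, double z, bool want_hazard,
                   const std::vector<double> &out_local, IntervalResult &res) {
  const int ns = 33;
  std::vector<double> nodes;
  nodes.reserve(ns + out_local.size() + 8);
  for (int i = 0; i <= ns; ++i) nodes.push_back(L * i / ns);
  for (double t : out_local) nodes.push_back(t);
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());

  // stationary points of D: sign changes of D' between sample nodes
  std::vector<double> extra;
  double dprev = D.deriv(nodes[0]);
  for (size_t i = 1; i < nodes.size(); ++i) {
    double dcur = D.deriv(nodes[i]);
    if ((dprev > 0 && dcur < 0) || (dprev < 0 && dcur > 0)) {
      extra.push_back(bisect([&](double t) { return D.deriv(t); },
                             nodes[i - 1], nodes[i], dprev));
    }
    dprev = dcur;
  }
  nodes.insert(nodes.end(), extra.begin(), extra.end());
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());

  if (want_hazard) {
    // crossings of D - z (monotone between nodes now)
    extra.clear();
    double fprev = D.eval(nodes[0]) - z;
    for (size_t i = 1; i < nodes.size(); ++i) {
      double fcur = D.eval(nodes[i]) - z;
      if ((fprev > 0 && fcur < 0) || (fprev < 0 && fcur > 0)) {
        extra.push_back(bisect([&](double t) { return D.eval(t) - z; },
                               nodes[i - 1], nodes[i], fprev));
      }
      fprev = fcur;
    }
    nodes.insert(nodes.end(), extra.begin(), extra.end());
    std::sort(nodes.begin(), nodes.end());
    nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
  }

  size_t n = nodes.size();
  res.nodes = nodes;
  res.Dnodes.resize(n);
  for (size_t i = 0; i < n; ++i) res.Dnodes[i] = D.eval(nodes[i]);

  if (want_hazard) {
    res.Hnodes.assign(n, 0.0);
    double acc = 0.0;
    for (size_t i = 1; i < n; ++i) {
      double mid = 0.5 * (nodes[i - 1] + nodes[i]);
      if (D.eval(mid) > z)
        acc += D.antideriv(nodes[i], z) - D.antideriv(nodes[i - 1], z);
      res.Hnodes[i] = acc;
    }
  }
  res.D = D;
}

struct SimSpec {
  int combination;   // 0 = CA, 1 = DA
  int death;         // 0 = SD, 1 = IT
  double eta, z, kk, alpha, beta, hb;
  std::vector<double> kd, w;
};

// Simulate S (and optionally full states) at sorted `times` for exposure
// levels C (n_routes x n_intervals) on breakpoints bk (n_intervals + 1).
void simulate_core(const SimSpec &sp, const std::vector<double> &bk,
                   const NumericMatrix &C, const std::vector<double> &times,
                   bool want_states,
                   std::vector<double> &S_out, std::vector<double> &D_out,
                   std::vector<double> &H_out, NumericMatrix *B_out,
                   NumericMatrix *Droutes_out) {
  int N = C.nrow();
  int m = (int)bk.size() - 1;
  std::vector<double> B(N, 0.0);
  std::vector<double> Droute(N, 0.0);  // DA per-route damage
  double Dca = 0.0;                    // CA combined damage
  double Hexc = 0.0;                   // accumulated exceedance integral
  double runmax = 0.0;                 // running max of combined D
  size_t ti = 0;
  size_t nt = times.size();
  S_out.assign(nt, 1.0);
  D_out.assign(nt, 0.0);
  H_out.assign(nt, 0.0);

  bool sd = sp.death == 0;

  for (int seg = 0; seg < m && ti < nt; ++seg) {
    double t0 = bk[seg], t1 = bk[seg + 1], L = t1 - t0;
    ExpPoly D;
    D.c0 = 0.0;
    if (sp.combination == 0) {
      // CA: one kinetic acting on the weighted buffer sum
      double Cw = 0.0, A = 0.0;
      for (int i = 0; i < N; ++i) {
        Cw += sp.w[i] * C(i, seg);
        A += sp.w[i] * (B[i] - C(i, seg));
      }
      add_damage_terms(D, 1.0, sp.kd[0], sp.eta, Cw, A, Dca);
    } else {
      for (int i = 0; i < N; ++i)
        add_damage_terms(D, sp.w[i], sp.kd[i], sp.eta, C(i, seg),
                         B[i] - C(i, seg), Droute[i]);
    }

    // output times falling in (t0, t1]; t = 0 handled by initial state
    std::vector<double> out_local;
    size_t ti2 = ti;
    while (ti2 < nt && times[ti2] <= t1 + 1e-12 * std::max(1.0, t1)) {
      if (times[ti2] > t0) out_local.push_back(times[ti2] - t0);
      ++ti2;
    }

    IntervalResult res;
    scan_interval(D, L, sp.z, sd, out_local, res);

    // walk nodes: update running max / hazard and emit outputs
    size_t k = 0;
    double localmax = runmax;
    for (; ti < nt && times[ti] <= t1 + 1e-12 * std::max(1.0, t1); ++ti) {
      double t = times[ti];
      if (t <= t0) {  // t == 0 (grid starts at first breakpoint)
        S_out[ti] = std::exp(-sp.hb * t);
        D_out[ti] = (sp.combination == 0) ? Dca : 0.0;
        H_out[ti] = sp.kk * Hexc + sp.hb * t;
        if (want_states) {
          for (int i = 0; i < N; ++i) (*B_out)(ti, i) = B[i];
          if (Droutes_out)
            for (int i = 0; i < N; ++i) (*Droutes_out)(ti, i) = Droute[i];
        }
        continue;
      }
      double tau = t - t0;
      // advance node walker to tau, tracking the running max on the way
      while (k < res.nodes.size() && res.nodes[k] <= tau + 1e-14 * std::max(1.0, tau)) {
        localmax = std::max(localmax, res.Dnodes[k]);
        ++k;
      }
      size_t idx = (k == 0) ? 0 : k - 1;
      double Dt = res.D.eval(tau);
      localmax = std::max(localmax, Dt);
      D_out[ti] = Dt;
      if (sd) {
        double Ht = Hexc + res.Hnodes[idx];
        // partial gap [nodes[idx], tau] if D > z there
        double u = res.nodes[idx];
        if (tau > u && res.D.eval(0.5 * (u + tau)) > sp.z)
          Ht += res.D.antideriv(tau, sp.z) - res.D.antideriv(u, sp.z);
        double Htot = sp.kk * Ht + sp.hb * t;
        H_out[ti] = Htot;
        S_out[ti] = std::exp(-Htot);
      } else {
        double F = (localmax <= 0.0)
                       ? 0.0
                       : 1.0 / (1.0 + std::pow(localmax / sp.alpha, -sp.beta));
        S_out[ti] = (1.0 - F) * std::exp(-sp.hb * t);
        H_out[ti] = sp.hb * t;
      }
      if (want_states) {
        for (int i = 0; i < N; ++i)
          (*B_out)(ti, i) = C(i, seg) + (B[i] - C(i, seg)) * std::exp(-sp.eta * tau);
        if (Droutes_out) {
          for (int i = 0; i < N; ++i) {
            ExpPoly Di; Di.c0 = 0.0;
            add_damage_terms(Di, 1.0, sp.combination == 0 ? sp.kd[0] : sp.kd[i],
                             sp.eta, C(i, seg), B[i] - C(i, seg), Droute[i]);
            (*Droutes_out)(ti, i) = Di.eval(tau);
          }
        }
      }
    }

    // finish the interval: running max / hazard over remaining nodes
    for (; k < res.nodes.size(); ++k)
      localmax = std::max(localmax, res.Dnodes[k]);
    runmax = localmax;
    if (sd) Hexc += res.Hnodes.back();

    // propagate states to t1
    if (sp.combination == 0) {
      Dca = res.D.eval(L);
      for (int i = 0; i < N; ++i)
        Droute[i] = 0.0;  // unused for CA
    } else {
      for (int i = 0; i < N; ++i) {
        ExpPoly Di; Di.c0 = 0.0;
        add_damage_terms(Di, 1.0, sp.kd[i], sp.eta, C(i, seg),
                         B[i] - C(i, seg), Droute[i]);
        Droute[i] = Di.eval(L);
      }
    }
    for (int i = 0; i < N; ++i)
      B[i] = C(i, seg) + (B[i] - C(i, seg)) * std::exp(-sp.eta * L);
  }
}

SimSpec build_spec(int combination, int death, double eta, NumericVector kd,
                   NumericVector w, double z, double kk, double alpha,
                   double beta, double hb) {
  SimSpec sp;
  sp.combination = combination;
  sp.death = death;
  sp.eta = eta;
  sp.z = z; sp.kk = kk; sp.alpha = alpha; sp.beta = beta; sp.hb = hb;
  sp.kd.assign(kd.begin(), kd.end());
  sp.w.assign(w.begin(), w.end());
  return sp;
}

}  // namespace

// [[Rcpp::export]]
List bg_simulate_cpp(int combination, int death, double eta, NumericVector kd,
                     NumericVector w, double z, double kk, double alpha,
                     double beta, double hb, NumericVector breakpoints,
                     NumericMatrix levels, NumericVector times,
                     bool want_states) {
  SimSpec sp = build_spec(combination, death, eta, kd, w, z, kk, alpha, beta, hb);
  std::vector<double> bk(breakpoints.begin(), breakpoints.end());
  std::vector<double> tt(times.begin(), times.end());
  int N = levels.nrow();
  size_t nt = tt.size();
  std::vector<double> S, D, H;
  NumericMatrix B(nt, N), Droutes(nt, N);
  simulate_core(sp, bk, levels, tt, want_states, S, D, H,
                want_states ? &B : nullptr,
                (want_states && combination == 1) ? &Droutes : nullptr);
  List out = List::create(_["S"] = wrap(S), _["D"] = wrap(D), _["H"] = wrap(H));
  if (want_states) {
    out["B"] = B;
    if (combination == 1) out["D_routes"] = Droutes;
  }
  return out;
}

// Conditional-binomial (multinomial) survival log-likelihood over a packed
// dataset: each element is list(breakpoints, levels, obs_t, n_alive).
// Interval probabilities are floored at 1e-12 before taking logs.
// [[Rcpp::export]]
double bg_loglik_cpp(List packed, int combination, int death, double eta,
                     NumericVector kd, NumericVector w, double z, double kk,
                     double alpha, double beta, double hb) {
  SimSpec sp = build_spec(combination, death, eta, kd, w, z, kk, alpha, beta, hb);
  const double floor_p = 1e-12;
  double ll = 0.0;
  for (int g = 0; g < packed.size(); ++g) {
    List tr = packed[g];
    NumericVector bkv = tr["breakpoints"];
    NumericMatrix Cm = tr["levels"];
    NumericVector obst = tr["obs_t"];
    IntegerVector nal = tr["n_alive"];
    std::vector<double> bk(bkv.begin(), bkv.end());
    std::vector<double> tt(obst.begin(), obst.end());
    std::vector<double> S, D, H;
    simulate_core(sp, bk, Cm, tt, false, S, D, H, nullptr, nullptr);
    int J = (int)tt.size();
    // observations start at t = 0 with S = 1 implicitly if obs_t[0] == 0
    double Sprev = 1.0;
    int nprev = nal[0];
    int j0 = 0;
    if (tt[0] <= 0.0) { Sprev = 1.0; j0 = 1; }
    for (int j = j0; j < J; ++j) {
      double Sj = std::min(S[j], Sprev);
      int d = nprev - nal[j];
      if (d > 0) ll += d * std::log(std::max(Sprev - Sj, floor_p));
      Sprev = Sj;
      nprev = nal[j];
    }
    if (nprev > 0) ll += nprev * std::log(std::max(Sprev, floor_p));
  }
  return ll;
}
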