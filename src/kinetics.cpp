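#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gas constant, J/(mol K). Must match R_GAS in R/kinetics.R.
static const double R_GAS = 8.314462618;
// Cap on ln k (k in 1/day) to avoid overflow when optimizers probe extreme
// (lnA, Ea) corners; e^46 / day is far beyond any resolvable kinetics.
static const double LNK_CAP = 46.0;

static inline double clamp01(double a) {
  return a < 0.0 ? 0.0 : (a > 1.0 ? 1.0 : a);
}

// Conversion function f(alpha) = (1 - alpha)^n * alpha^m of the rate law.
static inline double shape_f(double a, double n, double m) {
  a = clamp01(a);
  double f = 1.0;
  if (n != 0.0) f *= std::pow(1.0 - a, n);
  if (m != 0.0) f *= std::pow(a, m);
  return f;
}

// Piecewise-linear (or step-hold) temperature program and the Arrhenius
// rate constant along it. lnk_pref = lnA + p*ln(C) so that
// k(t) = exp(lnk_pref - Ea / (R T(t))).
struct ProfileK {
  double lnk_pref, Ea;
  const double *kt, *kT;
  int nk;
  int interp; // 0 = linear, 1 = step-hold

  double temp_at(double t) const {
    if (nk == 1 || t <= kt[0]) return kT[0];
    if (t >= kt[nk - 1]) return kT[nk - 1];
    int lo = 0, hi = nk - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (kt[mid] <= t) lo = mid; else hi = mid;
    }
    if (interp == 1) return kT[lo];
    double w = (t - kt[lo]) / (kt[hi] - kt[lo]);
    return kT[lo] + w * (kT[hi] - kT[lo]);
  }

  double k_at(double t) const {
    double lnk = lnk_pref - Ea / (R_GAS * temp_at(t));
    if (lnk > LNK_CAP) lnk = LNK_CAP;
    return std::exp(lnk);
  }
};

// Closed-form isothermal solution of dalpha/dt = k (1-alpha)^n (m = 0),
// elapsed time t from alpha0.
static double alpha_iso_analytic(double t, double a0, double k, double n) {
  if (t <= 0.0 || k <= 0.0) return a0;
  double u0 = 1.0 - a0;
  if (u0 <= 0.0) return 1.0;
  if (n == 0.0) {
    double a = a0 + k * t;
    return a > 1.0 ? 1.0 : a;
  }
  if (n == 1.0) return 1.0 - u0 * std::exp(-k * t);
  // general n: (1-alpha)^(1-n) = u0^(1-n) - (1-n) k t
  double w = std::pow(u0, 1.0 - n) - (1.0 - n) * k * t;
  if (n < 1.0 && w <= 0.0) return 1.0; // completes in finite time
  double a = 1.0 - std::pow(w, 1.0 / (1.0 - n));
  return clamp01(a);
}

// Adaptive Cash-Karp RK4(5) for the scalar sub-extent ODE over [t0, t1].
static double rk45_span(double t0, double t1, double a, const ProfileK &pk,
                        double n, double m, double rtol, double atol) {
  double span = t1 - t0;
  if (span <= 0.0) return a;
  double hmin = span * 1e-12 + 1e-300;
  double t = t0, h = span * 0.05;
  long iter = 0;
  while (t < t1 && iter++ < 2000000L) {
    if (t + h > t1) h = t1 - t;
    double aa = a;
    double c1 = (aa >= 1.0 - 1e-12 && n > 0.0) ? 0.0 : pk.k_at(t) * shape_f(aa, n, m);
    double y2 = aa + h * c1 / 5.0;
    double c2 = pk.k_at(t + h / 5.0) * shape_f(y2, n, m);
    double y3 = aa + h * (3.0 * c1 + 9.0 * c2) / 40.0;
    double c3 = pk.k_at(t + 3.0 * h / 10.0) * shape_f(y3, n, m);
    double y4 = aa + h * (0.3 * c1 - 0.9 * c2 + 1.2 * c3);
    double c4 = pk.k_at(t + 3.0 * h / 5.0) * shape_f(y4, n, m);
    double y5 = aa + h * (-11.0 / 54.0 * c1 + 2.5 * c2 - 70.0 / 27.0 * c3 + 35.0 / 27.0 * c4);
    double c5 = pk.k_at(t + h) * shape_f(y5, n, m);
    double y6 = aa + h * (1631.0 / 55296.0 * c1 + 175.0 / 512.0 * c2 + 575.0 / 13824.0 * c3 +
                          44275.0 / 110592.0 * c4 + 253.0 / 4096.0 * c5);
    double c6 = pk.k_at(t + 7.0 * h / 8.0) * shape_f(y6, n, m);
    double a5 = aa + h * (37.0 / 378.0 * c1 + 250.0 / 621.0 * c3 + 125.0 / 594.0 * c4 +
                          512.0 / 1771.0 * c6);
    double a4 = aa + h * (2825.0 / 27648.0 * c1 + 18575.0 / 48384.0 * c3 +
                          13525.0 / 55296.0 * c4 + 277.0 / 14336.0 * c5 + 0.25 * c6);
    double err = std::fabs(a5 - a4);
    double tol = atol + rtol * std::fabs(a5);
    if (err <= tol || h <= hmin) {
      t += h;
      a = clamp01(a5);
      double fac = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h < hmin) h = hmin;
    } else {
      double fac = 0.9 * std::pow(tol / err, 0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) h = hmin;
    }
  }
  return a;
}

// Sub-extent trajectory of one reaction step over a temperature program.
// times: sorted ascending, absolute days; integration starts at times[0]
// with extent alpha0, and alpha is reported at every element of times.
// [[Rcpp::export]]
NumericVector substep_alpha_cpp(NumericVector times, double alpha0,
                                double lnk_pref, double Ea, double n, double m,
                                NumericVector knot_t, NumericVector knot_T,
                                int interp, double rtol, double atol) {
  int nt = times.size();
  NumericVector out(nt);
  if (nt == 0) return out;
  ProfileK pk{lnk_pref, Ea, REAL(knot_t), REAL(knot_T), (int)knot_t.size(), interp};
  double a = clamp01(alpha0);
  out[0] = a;
  double tprev = times[0];
  for (int i = 1; i < nt; ++i) {
    double ti = times[i];
    if (ti < tprev) stop("time grid must be non-decreasing");
    // split the span at interior profile knots so each piece lies in one segment
    std::vector<double> brk;
    brk.push_back(tprev);
    for (int j = 0; j < pk.nk; ++j)
      if (knot_t[j] > tprev && knot_t[j] < ti) brk.push_back(knot_t[j]);
    brk.push_back(ti);
    for (size_t s = 0; s + 1 < brk.size(); ++s) {
      double s0 = brk[s], s1 = brk[s + 1];
      if (s1 <= s0) continue;
      double mid = 0.5 * (s0 + s1);
      bool const_T = (pk.nk == 1) || (pk.interp == 1) ||
                     (std::fabs(pk.temp_at(s0) - pk.temp_at(s1)) < 1e-12);
      if (const_T && m == 0.0) {
        double lnk = lnk_pref - Ea / (R_GAS * pk.temp_at(mid));
        if (lnk > LNK_CAP) lnk = LNK_CAP;
        a = alpha_iso_analytic(s1 - s0, a, std::exp(lnk), n);
      } else {
        a = rk45_span(s0, s1, a, pk, n, m, rtol, atol);
      }
    }
    tprev = ti;
    out[i] = a;
  }
  return out;
}
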