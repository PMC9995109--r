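// Two-boundary Wiener first-passage machinery (unit diffusion coefficient).
//
// Parameterization: drift v (signed, positive toward the upper boundary),
// boundary separation a > 0, relative starting point z in (0,1) (fraction of
// a; upper boundary at a), non-decision time tau >= 0.  choice = 1 denotes
// absorption at the upper boundary, choice = 0 at the lower boundary.
//
// The defective first-passage density uses the dual small-time / large-time
// series representation with automatic truncation and switching so that the
// standardized-density truncation error is below `eps` everywhere.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double F0_EPS = 1e-12;

// Density of the first passage through the *lower* boundary of a zero-drift
// unit diffusion started at relative position z, boundaries at 0 and 1,
// evaluated at normalized time w = t / a^2.  Truncation error <= eps.
static double f0_lower(double w, double z, double eps) {
  if (w <= 0.0) return 0.0;
  // number of terms needed by each expansion (Navarro-Fuss style bounds)
  double ks, kl;
  if (2.0 * sqrt(2.0 * M_PI * w) * eps < 1.0) {
    ks = 2.0 + sqrt(-2.0 * w * log(2.0 * eps * sqrt(2.0 * M_PI * w)));
    ks = std::max(ks, sqrt(w) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * w * eps < 1.0) {
    kl = sqrt(-2.0 * log(M_PI * w * eps) / (M_PI * M_PI * w));
    kl = std::max(kl, 1.0 / (M_PI * sqrt(w)));
  } else {
    kl = 1.0 / (M_PI * sqrt(w));
  }
  double f = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)ceil(ks);
    int lower = -(int)floor((K - 1) / 2.0);
    int upper = (int)ceil((K - 1) / 2.0);
    for (int k = lower; k <= upper; ++k) {
      double zk = z + 2.0 * k;
      f += zk * exp(-zk * zk / (2.0 * w));
    }
    f /= sqrt(2.0 * M_PI * w * w * w);
  } else {  // large-time expansion
    int K = (int)ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * exp(-k * k * M_PI * M_PI * w / 2.0) * sin(k * M_PI * z);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Defective density of first passage through the boundary selected by
// `upper`, at decision time t (already net of non-decision time).
static double wfpt_density(double t, bool upper, double v, double a,
                           double z) {
  if (t <= 0.0) return 0.0;
  double vv = upper ? -v : v;
  double zz = upper ? 1.0 - z : z;
  double w = t / (a * a);
  double f0 = f0_lower(w, zz, F0_EPS);
  if (f0 <= 0.0) return 0.0;
  double lg = -vv * a * zz - vv * vv * t / 2.0 - 2.0 * log(a);
  return exp(lg) * f0;
}

static double pupper_one(double v, double a, double z) {
  double b = 2.0 * v * a;
  if (fabs(b) < 1e-9) {
    // expansion around zero drift: P = z + b z(1-z)/2 + O(b^2)
    return z + b * z * (1.0 - z) / 2.0;
  }
  if (-b > 700.0) {  // strongly negative drift; avoid overflow
    return exp(b * (1.0 - z));
  }
  return expm1(-b * z) / expm1(-b);
}

// [[Rcpp::export]]
NumericVector cpp_dwfpt(NumericVector rt, IntegerVector choice,
                        NumericVector v, NumericVector a, NumericVector z,
                        NumericVector tau, bool log_d) {
  R_xlen_t n = rt.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = wfpt_density(rt[i] - tau[i], choice[i] == 1, v[i], a[i], z[i]);
    out[i] = log_d ? (d > 0.0 ? log(d) : R_NegInf) : d;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_wfpt_loglik(NumericVector rt, IntegerVector choice,
                       NumericVector v, NumericVector a, NumericVector z,
                       NumericVector tau) {
  R_xlen_t n = rt.size();
  double ll = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = wfpt_density(rt[i] - tau[i], choice[i] == 1, v[i], a[i], z[i]);
    if (!(d > 0.0)) return R_NegInf;
    ll += log(d);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_pupper(NumericVector v, NumericVector a, NumericVector z) {
  R_xlen_t n = v.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = pupper_one(v[i], a[i], z[i]);
  return out;
}

// Draw `nrep` (choice, rt) pairs per parameter row by inverse-CDF sampling:
// the boundary is drawn from the exact absorption probability, the hitting
// time from the conditional first-passage density integrated on the fly
// (trapezoid rule, step adapted to the diffusion time scale).  Draws within a
// parameter row share one integration sweep (uniforms are sorted), so
// repeated simulation from the same trial parameters is cheap.
// [[Rcpp::export]]
List cpp_rwfpt(NumericVector v, NumericVector a, NumericVector z,
               NumericVector tau, int nrep) {
  R_xlen_t npar = v.size();
  R_xlen_t ntot = npar * (R_xlen_t)nrep;
  IntegerVector choice(ntot);
  NumericVector rt(ntot);

  for (R_xlen_t p = 0; p < npar; ++p) {
    double vp = v[p], ap = a[p], zp = z[p], taup = tau[p];
    double pu = pupper_one(vp, ap, zp);
    // partition draws by boundary
    std::vector<R_xlen_t> idx_up, idx_lo;
    for (int r = 0; r < nrep; ++r) {
      R_xlen_t i = p * nrep + r;
      if (unif_rand() < pu) {
        choice[i] = 1;
        idx_up.push_back(i);
      } else {
        choice[i] = 0;
        idx_lo.push_back(i);
      }
    }
    for (int side = 0; side < 2; ++side) {
      std::vector<R_xlen_t> &idx = side ? idx_up : idx_lo;
      if (idx.empty()) continue;
      bool upper = side == 1;
      double pb = upper ? pu : 1.0 - pu;
      double vv = upper ? -vp : vp;
      double zz = upper ? 1.0 - zp : zp;
      size_t nb = idx.size();
      // conditional-CDF targets, sorted so one sweep serves all draws
      std::vector<std::pair<double, R_xlen_t> > us(nb);
      for (size_t j = 0; j < nb; ++j)
        us[j] = std::make_pair(unif_rand() * pb, idx[j]);
      std::sort(us.begin(), us.end());
      // integration step from the characteristic decision-time scale
      double tsc = ap * ap * zp * (1.0 - zp);
      if (fabs(vp) > 1e-9) tsc = std::min(tsc, ap / fabs(vp));
      double h = tsc / 800.0;
      if (h < 1e-6) h = 1e-6;
      if (h > 0.02) h = 0.02;
      double C = 0.0, t = 0.0, fprev = 0.0;
      size_t j = 0;
      long step = 0;
      const long max_step = 100000000L;
      while (j < nb) {
        t += h;
        ++step;
        double w = t / (ap * ap);
        double f0 = f0_lower(w, zz, F0_EPS);
        double fcur =
            f0 > 0.0 ? exp(-vv * ap * zz - vv * vv * t / 2.0 - 2.0 * log(ap)) *
                           f0
                     : 0.0;
        double Cnew = C + 0.5 * h * (fprev + fcur);
        while (j < nb && us[j].first <= Cnew) {
          double dC = Cnew - C;
          double frac = dC > 0.0 ? (us[j].first - C) / dC : 1.0;
          rt[us[j].second] = taup + t - h + frac * h;
          ++j;
        }
        C = Cnew;
        fprev = fcur;
        // far tail exhausted (numerical mass < truncation error): assign rest
        if ((fcur < 1e-13 && t > 4.0 * tsc && step > 100) || step >= max_step) {
          for (; j < nb; ++j) rt[us[j].second] = taup + t;
          break;
        }
      }
    }
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
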