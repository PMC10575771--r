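#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <numeric>

using namespace Rcpp;

// Hartigan's dip statistic: the sup-norm distance from the empirical CDF to
// the nearest unimodal CDF.  Two exact routes share the work:
//
//  * tie-free samples: the iterative greatest-convex-minorant /
//    least-concave-majorant algorithm on the sorted sample.  The ecdf's lower
//    jump corners carry the GCM, the upper corners the LCM; each pass finds
//    the largest gap between the two hulls, shrinks the modal interval to its
//    location, and accumulates the deviations of the ecdf from the hulls over
//    the excluded flanks.  The dip is the accumulated maximum over 2n (the
//    best unimodal fit splits every deviation in half).
//
//  * tied samples: the nearest unimodal df may place an atom at the mode,
//    which bridges that one jump for free, so corner charging is no longer
//    valid.  Here the dip is found by bisection on d, testing whether a
//    convex-then-concave df (atom at the mode allowed) can pass through the
//    ecdf tube of half-width d.  Convex-side reachability is summarised by
//    one steepest extrapolation line per point (a valid and attained lower
//    bound), mirrored for the concave side; all mode-in-gap constraints are
//    linear in the mode position.
//
// Constant samples return the floor 1/(2n), the classical convention.

// ---------------------------------------------------------------- tie-free
static double dip_itr(const std::vector<double>& xi, int n) {
  const int m = static_cast<int>(xi.size());
  std::vector<double> lo(m), hi(m);
  for (int j = 0; j < m; ++j) { lo[j] = j; hi[j] = j + 1; }

  int L = 0, H = m - 1;
  double D = 1.0;  // one ecdf jump is always unavoidable
  std::vector<int> gcm, lcm;
  gcm.reserve(m); lcm.reserve(m);
  const double eps = 1e-9;

  for (int iter = 0; iter <= m + 1; ++iter) {
    gcm.clear();
    for (int j = L; j <= H; ++j) {
      while (gcm.size() >= 2) {
        int a = gcm[gcm.size() - 2], b = gcm[gcm.size() - 1];
        double cr = (xi[b] - xi[a]) * (lo[j] - lo[a]) -
                    (lo[b] - lo[a]) * (xi[j] - xi[a]);
        if (cr <= 0.0) gcm.pop_back(); else break;
      }
      gcm.push_back(j);
    }
    lcm.clear();
    for (int j = L; j <= H; ++j) {
      while (lcm.size() >= 2) {
        int a = lcm[lcm.size() - 2], b = lcm[lcm.size() - 1];
        double cr = (xi[b] - xi[a]) * (hi[j] - hi[a]) -
                    (hi[b] - hi[a]) * (xi[j] - xi[a]);
        if (cr >= 0.0) lcm.pop_back(); else break;
      }
      lcm.push_back(j);
    }

    double d = -1.0;
    bool at_lcm = false;
    int arg_g = L, arg_lt1 = H, arg_gs = L, arg_l = H;
    {
      size_t t = 0;
      for (size_t s = 0; s < gcm.size(); ++s) {
        int g = gcm[s];
        while (t + 1 < lcm.size() && xi[lcm[t + 1]] < xi[g]) ++t;
        int p = lcm[t];
        int q = (t + 1 < lcm.size()) ? lcm[t + 1] : lcm[t];
        double lv = (q == p) ? hi[p]
          : hi[p] + (hi[q] - hi[p]) * (xi[g] - xi[p]) / (xi[q] - xi[p]);
        double gap = lv - lo[g];
        if (gap > d) { d = gap; at_lcm = false; arg_g = g; arg_lt1 = q; }
      }
    }
    {
      size_t s = 0;
      for (size_t t = 0; t < lcm.size(); ++t) {
        int l = lcm[t];
        while (s + 1 < gcm.size() && xi[gcm[s + 1]] < xi[l]) ++s;
        int p = gcm[s];
        int q = (s + 1 < gcm.size()) ? gcm[s + 1] : gcm[s];
        double gv = (q == p) ? lo[p]
          : lo[p] + (lo[q] - lo[p]) * (xi[l] - xi[p]) / (xi[q] - xi[p]);
        double gap = hi[l] - gv;
        if (gap > d) { d = gap; at_lcm = true; arg_gs = p; arg_l = l; }
      }
    }

    if (d <= D + eps) break;

    int newL = at_lcm ? arg_gs : arg_g;
    int newH = at_lcm ? arg_l : arg_lt1;
    if (newL < L) newL = L;
    if (newH > H) newH = H;

    double dl = hi[newL] - lo[newL];
    for (size_t s = 0; s + 1 < gcm.size() && gcm[s] < newL; ++s) {
      int p = gcm[s], q = gcm[s + 1];
      int jend = std::min(q, newL);
      for (int j = p; j <= jend; ++j) {
        double gv = lo[p] + (lo[q] - lo[p]) * (xi[j] - xi[p]) / (xi[q] - xi[p]);
        double dev = hi[j] - gv;
        if (dev > dl) dl = dev;
      }
    }
    double du = hi[newH] - lo[newH];
    for (size_t t = 0; t + 1 < lcm.size(); ++t) {
      int p = lcm[t], q = lcm[t + 1];
      if (q < newH) continue;
      int jstart = std::max(p, newH);
      for (int j = jstart; j <= q; ++j) {
        double lv = hi[p] + (hi[q] - hi[p]) * (xi[j] - xi[p]) / (xi[q] - xi[p]);
        double dev = lv - lo[j];
        if (dev > du) du = dev;
      }
    }

    if (dl > D) D = dl;
    if (du > D) D = du;

    if (newL <= L && newH >= H) {
      if (d > D) D = d;
      break;
    }
    L = newL; H = newH;
  }
  return D / (2.0 * n);
}

// ---------------------------------------------------------------- tied data
struct FeasCtx {
  int m;
  std::vector<double> xi, cc, cp;  // distinct values, cum fraction, prev cum
  double X0, X1;                   // distant anchors carrying G = 0 and 1
};

static bool dip_feasible(const FeasCtx& C, double d) {
  const int m = C.m;
  const double EPS = 1e-12;
  std::vector<double> l(m), u(m);
  for (int i = 0; i < m; ++i) {
    l[i] = std::max(0.0, C.cc[i] - d);
    u[i] = std::min(1.0, C.cp[i] + d);
  }

  // prefix convex feasibility: greatest convex minorant of the upper bounds
  // (anchored at (X0, 0)) must dominate the lower bounds
  std::vector<char> pf0(m + 1, 0), sf0(m + 2, 0);
  {
    std::vector<double> hx(1, C.X0), hy(1, 0.0);
    pf0[0] = 1;
    bool ok = true;
    for (int j = 0; j < m && ok; ++j) {
      while (hx.size() >= 2) {
        size_t b = hx.size() - 1, a = b - 1;
        double cr = (hx[b] - hx[a]) * (u[j] - hy[a]) - (hy[b] - hy[a]) * (C.xi[j] - hx[a]);
        if (cr <= 0.0) { hx.pop_back(); hy.pop_back(); } else break;
      }
      hx.push_back(C.xi[j]); hy.push_back(u[j]);
      // recheck dominated lower bounds under the (possibly lowered) hull
      size_t s = 0;
      for (int i = 0; i <= j && ok; ++i) {
        while (s + 1 < hx.size() && hx[s + 1] < C.xi[i]) ++s;
        double hv = (s + 1 < hx.size() && hx[s + 1] > hx[s])
          ? hy[s] + (hy[s + 1] - hy[s]) * (C.xi[i] - hx[s]) / (hx[s + 1] - hx[s])
          : hy[s + (s + 1 < hx.size() ? 1 : 0)];
        if (hv < l[i] - EPS) ok = false;
      }
      pf0[j + 1] = ok ? 1 : 0;
    }
  }
  {
    std::vector<double> hx(1, C.X1), hy(1, 1.0);
    sf0[m] = 1; sf0[m + 1] = 1;
    bool ok = true;
    for (int j = m - 1; j >= 0 && ok; --j) {
      // least concave majorant of lower bounds, right-to-left, must stay
      // below the upper bounds (mirror of the prefix test)
      while (hx.size() >= 2) {
        size_t b = hx.size() - 1, a = b - 1;
        double cr = (hx[b] - hx[a]) * (l[j] - hy[a]) - (hy[b] - hy[a]) * (C.xi[j] - hx[a]);
        if (cr <= 0.0) { hx.pop_back(); hy.pop_back(); } else break;
      }
      hx.push_back(C.xi[j]); hy.push_back(l[j]);
      size_t s = 0;
      for (int i = m - 1; i >= j && ok; --i) {
        while (s + 1 < hx.size() && hx[s + 1] > C.xi[i]) ++s;
        double hv = (s + 1 < hx.size() && hx[s] > hx[s + 1])
          ? hy[s] + (hy[s + 1] - hy[s]) * (C.xi[i] - hx[s]) / (hx[s + 1] - hx[s])
          : hy[s + (s + 1 < hx.size() ? 1 : 0)];
        if (hv > u[i] + EPS) ok = false;
      }
      sf0[j] = ok ? 1 : 0;
    }
  }

  // steepest valid extrapolation line per point:
  //  convex side, point q: line through (x_q, l_q) with slope
  //    s_q = max(0, max_{p<q} (l_q - u_p)/(x_q - x_p))  (p includes anchor)
  //  concave side, point q: line through (x_q, u_q) with slope
  //    t_q = max(0, max_{p>q} (l_p - u_q)/(x_p - x_q))  (p includes anchor)
  std::vector<double> sl(m), tl(m);
  for (int q = 0; q < m; ++q) {
    double best = (l[q] - 0.0) / (C.xi[q] - C.X0);
    for (int p = 0; p < q; ++p)
      best = std::max(best, (l[q] - u[p]) / (C.xi[q] - C.xi[p]));
    sl[q] = std::max(0.0, best);
    double best2 = (1.0 - u[q]) / (C.X1 - C.xi[q]);
    for (int p = q + 1; p < m; ++p)
      best2 = std::max(best2, (l[p] - u[q]) / (C.xi[p] - C.xi[q]));
    tl[q] = std::max(0.0, best2);
  }

  // mode at data point j, atom allowed: the left limit t1 sits within d of
  // F(x_j-), the value t2 within d of F(x_j), and t1 <= t2
  for (int j = 0; j < m; ++j) {
    if (!pf0[j] || !sf0[j + 1]) continue;
    double Amin = 0.0;
    for (int q = 0; q < j; ++q)
      Amin = std::max(Amin, l[q] + sl[q] * (C.xi[j] - C.xi[q]));
    double t1A = std::max(std::max(0.0, C.cp[j] - d), Amin);
    if (t1A > std::min(1.0, C.cp[j] + d) + 1e-11) continue;
    double Bmax = 1.0;
    for (int q = j + 1; q < m; ++q)
      Bmax = std::min(Bmax, u[q] - tl[q] * (C.xi[q] - C.xi[j]));
    double t2B = std::min(std::min(1.0, C.cc[j] + d), Bmax);
    if (t2B < std::max(0.0, C.cc[j] - d) - 1e-11) continue;
    if (t1A <= t2B + 1e-11) return true;
  }

  // mode strictly inside gap (j, j+1): junction value within d of F's level
  // in the gap; all constraints are linear in the mode position mu
  for (int j = 0; j + 1 < m; ++j) {
    if (!pf0[j + 1] || !sf0[j + 1]) continue;
    double lt = std::max(0.0, C.cc[j] - d), ut = std::min(1.0, C.cc[j] + d);
    double mlo = C.xi[j], mhi = C.xi[j + 1];
    bool ok = true;
    for (int q = 0; q <= j && ok; ++q) {   // lambda_q(mu) <= ut
      double v0 = l[q] + sl[q] * (mlo - C.xi[q]);
      if (sl[q] > 0.0) mhi = std::min(mhi, C.xi[q] + (ut - l[q]) / sl[q]);
      else if (v0 > ut + 1e-11) ok = false;
    }
    for (int q = j + 1; q < m && ok; ++q) { // mu_q(mu) >= lt
      if (tl[q] > 0.0) mlo = std::max(mlo, C.xi[q] - (u[q] - lt) / tl[q]);
      else if (u[q] < lt - 1e-11) ok = false;
    }
    if (!ok || mlo > mhi + 1e-11 * (1.0 + std::fabs(mhi))) continue;
    for (int q = 0; q <= j && ok; ++q) {
      double aL = l[q] - sl[q] * C.xi[q];     // lambda_q(mu) = aL + sl[q]*mu
      for (int r = j + 1; r < m && ok; ++r) {
        double aU = u[r] - tl[r] * (C.xi[r]); // mu_r(mu) = aU + tl[r]*mu
        double db = sl[q] - tl[r], da = aL - aU;
        if (std::fabs(db) < 1e-300) { if (da > 1e-11) ok = false; }
        else if (db > 0.0) mhi = std::min(mhi, -da / db);
        else mlo = std::max(mlo, -da / db);
        if (mlo > mhi + 1e-11 * (1.0 + std::fabs(mhi))) ok = false;
      }
    }
    if (ok) return true;
  }
  return false;
}

static double dip_feas(const std::vector<double>& xi,
                       const std::vector<int>& cnt, int n) {
  FeasCtx C;
  C.m = static_cast<int>(xi.size());
  C.xi = xi;
  C.cc.resize(C.m); C.cp.resize(C.m);
  int run = 0;
  for (int i = 0; i < C.m; ++i) {
    C.cp[i] = static_cast<double>(run) / n;
    run += cnt[i];
    C.cc[i] = static_cast<double>(run) / n;
  }
  double rng = xi[C.m - 1] - xi[0];
  C.X0 = xi[0] - 10.0 * rng - 1.0;
  C.X1 = xi[C.m - 1] + 10.0 * rng + 1.0;

  double dlo = 0.0, dhi = 0.2600001;
  for (int it = 0; it < 60 && dhi - dlo > 1e-12; ++it) {
    double mid = 0.5 * (dlo + dhi);
    if (dip_feasible(C, mid)) dhi = mid; else dlo = mid;
  }
  return std::max(dhi, 0.5 / n);
}

// ------------------------------------------------------------- dispatcher
static double dip_sorted(const std::vector<double>& x) {
  const int n = static_cast<int>(x.size());
  if (n < 2) return (n == 1) ? 0.5 : NA_REAL;

  std::vector<double> xi;
  std::vector<int> cnt;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    xi.push_back(x[i]);
    cnt.push_back(j + 1 - i);
    i = j + 1;
  }
  const int m = static_cast<int>(xi.size());
  if (m == 1) return 0.5 / n;

  int g = cnt[0];
  for (int k = 1; k < m && g > 1; ++k) g = std::gcd(g, cnt[k]);
  int neff = n;
  if (g > 1) {
    neff = n / g;
    for (int k = 0; k < m; ++k) cnt[k] /= g;
  }
  bool tied = false;
  for (int k = 0; k < m; ++k) if (cnt[k] > 1) { tied = true; break; }
  if (!tied) return dip_itr(xi, neff);
  return dip_feas(xi, cnt, neff);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  return dip_sorted(v);
}

// feasibility-search route regardless of ties (internal cross-check)
// [[Rcpp::export]]
double dip_stat_feas_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  const int n = static_cast<int>(v.size());
  std::vector<double> xi;
  std::vector<int> cnt;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[j + 1] == v[i]) ++j;
    xi.push_back(v[i]);
    cnt.push_back(j + 1 - i);
    i = j + 1;
  }
  if (xi.size() < 2) return 0.5 / n;
  return dip_feas(xi, cnt, n);
}

// Dip statistics of `n_sim` samples of size n from Uniform(0,1), using R's
// RNG stream (so set.seed() in R governs reproducibility).
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int n_sim) {
  NumericVector out(n_sim);
  std::vector<double> v(n);
  for (int s = 0; s < n_sim; ++s) {
    for (int i = 0; i < n; ++i) v[i] = R::unif_rand();
    std::sort(v.begin(), v.end());
    out[s] = dip_sorted(v);
  }
  return out;
}
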