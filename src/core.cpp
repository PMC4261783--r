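// Numerical core: stiff Rosenbrock 2(3) and Dormand-Prince RK45 integrators,
// moment-form cubic splines, and a compiled fitness path for the bundled
// models so the genetic algorithm can evaluate thousands of candidate
// parameter vectors per second.

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Right-hand sides of the bundled models
// ---------------------------------------------------------------------------

// ERK activation by MEKpp: distributive two-collision dual phosphorylation.
// States: M, E, M.E, Ep, M.Ep, Epp
// Params: kon1, koff1, kcat1, kon2, koff2, kcat2
static void rhs_erk(const double* y, const double* p, double* dy) {
  const double M = y[0], E = y[1], ME = y[2], Ep = y[3], MEp = y[4];
  const double v_bind1 = p[0] * M * E;
  const double v_rel1  = p[1] * ME;
  const double v_cat1  = p[2] * ME;
  const double v_bind2 = p[3] * M * Ep;
  const double v_rel2  = p[4] * MEp;
  const double v_cat2  = p[5] * MEp;
  dy[0] = -v_bind1 + v_rel1 + v_cat1 - v_bind2 + v_rel2 + v_cat2;
  dy[1] = -v_bind1 + v_rel1;
  dy[2] =  v_bind1 - v_rel1 - v_cat1;
  dy[3] =  v_cat1 - v_bind2 + v_rel2;
  dy[4] =  v_bind2 - v_rel2 - v_cat2;
  dy[5] =  v_cat2;
}

// pRB/E2F1 G1/S transition module (autocatalytic, bistable).
// States: pRB, E2F1
// Params: k1, Kn1, J11, phi_pRB, kp, k2, a, Kn2, J12, phi_E2F1
static void rhs_g1s(const double* y, const double* p, double* dy) {
  const double pRB = y[0], E2F1 = y[1];
  dy[0] = p[0] * E2F1 / (p[1] + E2F1) * p[2] / (p[2] + pRB) - p[3] * pRB;
  dy[1] = p[4] + p[5] * (p[6] * p[6] + E2F1 * E2F1) /
            (p[7] * p[7] + E2F1 * E2F1) * p[8] / (p[8] + pRB) -
          p[9] * E2F1;
}

// Dispatcher.  model_id: 1 = ERK, 2 = G1/S, 0 = R callback.
struct OdeSystem {
  int model_id;
  int n;
  const double* pars;
  int npars;
  SEXP rfun;
  NumericVector rpars;

  OdeSystem(int id, int n_, const double* pars_, int npars_, SEXP rf,
            NumericVector rp)
    : model_id(id), n(n_), pars(pars_), npars(npars_), rfun(rf), rpars(rp) {}

  // returns false when the derivative is non-finite
  bool eval(double t, const double* y, double* dy) {
    if (model_id == 1) {
      rhs_erk(y, pars, dy);
    } else if (model_id == 2) {
      rhs_g1s(y, pars, dy);
    } else {
      Function f(rfun);
      NumericVector yy(y, y + n);
      NumericVector out = f(yy, rpars, t);
      if (out.size() != n) stop("rhs returned wrong length");
      for (int i = 0; i < n; ++i) dy[i] = out[i];
    }
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(dy[i])) return false;
    return true;
  }
};

// ---------------------------------------------------------------------------
// Dense LU with partial pivoting (systems here are tiny)
// ---------------------------------------------------------------------------

static bool lu_factor(std::vector<double>& A, std::vector<int>& piv, int n) {
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int k = 0; k < n; ++k) {
    int imax = k;
    double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > amax) { amax = v; imax = i; }
    }
    if (amax < 1e-300 || !std::isfinite(amax)) return false;
    if (imax != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[imax * n + j]);
      std::swap(piv[k], piv[imax]);
    }
    const double pivval = A[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      const double m = A[i * n + k] / pivval;
      A[i * n + k] = m;
      for (int j = k + 1; j < n; ++j) A[i * n + j] -= m * A[k * n + j];
    }
  }
  return true;
}

static void lu_solve(const std::vector<double>& A, const std::vector<int>& piv,
                     int n, const double* b, double* x) {
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = b[piv[i]];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) y[i] -= A[i * n + j] * y[j];
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) y[i] -= A[i * n + j] * y[j];
    y[i] /= A[i * n + i];
  }
  for (int i = 0; i < n; ++i) x[i] = y[i];
}

// ---------------------------------------------------------------------------
// Integrators
// ---------------------------------------------------------------------------

struct IntResult {
  bool success;
  std::string message;
};

// Shampine's Rosenbrock 2(3) pair (the ode23s family): L-stable, numerical
// Jacobian, suitable for the stiff mass-action benchmarks.
static IntResult integrate_rosenbrock(OdeSystem& sys, const double* y0,
                                      const std::vector<double>& times,
                                      double rtol, double atol, int max_steps,
                                      double* out /* n x ntimes, col-major */) {
  const int n = sys.n;
  const int nt = (int)times.size();
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  std::vector<double> y(y0, y0 + n), ynew(n), F0(n), F1(n), F2(n);
  std::vector<double> k1(n), k2(n), k3(n), tmp(n), err(n);
  std::vector<double> J(n * n), W(n * n), ypert(n), fpert(n);
  std::vector<int> piv(n);

  double t = times[0];
  for (int i = 0; i < n; ++i) out[i] = y[i];

  const double span = times[nt - 1] - times[0];
  double h = span / 100.0;
  int steps = 0;

  for (int k = 1; k < nt; ++k) {
    const double target = times[k];
    while (target - t > 1e-14 * std::max(1.0, std::fabs(target))) {
      if (++steps > max_steps)
        return {false, "maximum number of steps exceeded"};
      if (h > target - t) h = target - t;
      const double hmin = 16.0 * DBL_EPSILON * std::max(std::fabs(t), 1.0);
      if (h < hmin) return {false, "step size underflow"};

      if (!sys.eval(t, y.data(), F0.data()))
        return {false, "non-finite derivative"};

      // forward-difference Jacobian at (t, y)
      const double sqeps = std::sqrt(DBL_EPSILON);
      for (int j = 0; j < n; ++j) {
        double del = sqeps * std::max(std::fabs(y[j]), 1e-5);
        for (int i = 0; i < n; ++i) ypert[i] = y[i];
        ypert[j] += del;
        if (!sys.eval(t, ypert.data(), fpert.data()))
          return {false, "non-finite derivative in Jacobian"};
        for (int i = 0; i < n; ++i) J[i * n + j] = (fpert[i] - F0[i]) / del;
      }

      bool accepted = false;
      // W = I - h d J
      for (int i = 0; i < n * n; ++i) W[i] = -h * d * J[i];
      for (int i = 0; i < n; ++i) W[i * n + i] += 1.0;
      std::vector<double> WLU = W;
      if (!lu_factor(WLU, piv, n)) { h *= 0.5; continue; }

      lu_solve(WLU, piv, n, F0.data(), k1.data());
      for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
      if (!sys.eval(t + 0.5 * h, tmp.data(), F1.data()))
        return {false, "non-finite derivative"};
      for (int i = 0; i < n; ++i) tmp[i] = F1[i] - k1[i];
      lu_solve(WLU, piv, n, tmp.data(), k2.data());
      for (int i = 0; i < n; ++i) k2[i] += k1[i];
      for (int i = 0; i < n; ++i) ynew[i] = y[i] + h * k2[i];
      bool ok = sys.eval(t + h, ynew.data(), F2.data());
      double errnorm = HUGE_VAL;
      if (ok) {
        for (int i = 0; i < n; ++i)
          tmp[i] = F2[i] - e32 * (k2[i] - F1[i]) - 2.0 * (k1[i] - F0[i]);
        lu_solve(WLU, piv, n, tmp.data(), k3.data());
        errnorm = 0.0;
        for (int i = 0; i < n; ++i) {
          err[i] = (h / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
          const double sc =
            atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
          const double e = std::fabs(err[i]) / sc;
          if (e > errnorm) errnorm = e;
        }
        if (!std::isfinite(errnorm)) errnorm = HUGE_VAL;
      }
      if (errnorm <= 1.0) {
        t += h;
        y = ynew;
        accepted = true;
      }
      double fac = 0.8 * std::pow(std::max(errnorm, 1e-16), -1.0 / 3.0);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (!accepted && !std::isfinite(h)) return {false, "step failure"};
      (void)accepted;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(y[i])) return {false, "non-finite state"};
      out[k * n + i] = y[i];
    }
  }
  return {true, "ok"};
}

// Dormand-Prince 5(4) explicit pair: the independent high-accuracy route.
static IntResult integrate_dopri(OdeSystem& sys, const double* y0,
                                 const std::vector<double>& times,
                                 double rtol, double atol, int max_steps,
                                 double* out) {
  const int n = sys.n;
  const int nt = (int)times.size();

  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = b1 - 5179.0 / 57600, e3 = b3 - 7571.0 / 16695,
                      e4 = b4 - 393.0 / 640, e5 = b5 + 92097.0 / 339200,
                      e6 = b6 - 187.0 / 2100, e7 = -1.0 / 40;

  std::vector<double> y(y0, y0 + n), ynew(n), tmp(n);
  std::vector<std::vector<double> > K(7, std::vector<double>(n));

  double t = times[0];
  for (int i = 0; i < n; ++i) out[i] = y[i];
  const double span = times[nt - 1] - times[0];
  double h = span / 100.0;
  int steps = 0;

  if (!sys.eval(t, y.data(), K[0].data()))
    return {false, "non-finite derivative"};
  bool have_k1 = true;

  for (int k = 1; k < nt; ++k) {
    const double target = times[k];
    while (target - t > 1e-14 * std::max(1.0, std::fabs(target))) {
      if (++steps > max_steps)
        return {false, "maximum number of steps exceeded"};
      if (h > target - t) h = target - t;
      const double hmin = 16.0 * DBL_EPSILON * std::max(std::fabs(t), 1.0);
      if (h < hmin) return {false, "step size underflow"};

      if (!have_k1 && !sys.eval(t, y.data(), K[0].data()))
        return {false, "non-finite derivative"};

      bool ok = true;
      for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * a21 * K[0][i];
      ok = ok && sys.eval(t + c2 * h, tmp.data(), K[1].data());
      if (ok) {
        for (int i = 0; i < n; ++i)
          tmp[i] = y[i] + h * (a31 * K[0][i] + a32 * K[1][i]);
        ok = sys.eval(t + c3 * h, tmp.data(), K[2].data());
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          tmp[i] = y[i] + h * (a41 * K[0][i] + a42 * K[1][i] + a43 * K[2][i]);
        ok = sys.eval(t + c4 * h, tmp.data(), K[3].data());
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          tmp[i] = y[i] + h * (a51 * K[0][i] + a52 * K[1][i] + a53 * K[2][i] +
                               a54 * K[3][i]);
        ok = sys.eval(t + c5 * h, tmp.data(), K[4].data());
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          tmp[i] = y[i] + h * (a61 * K[0][i] + a62 * K[1][i] + a63 * K[2][i] +
                               a64 * K[3][i] + a65 * K[4][i]);
        ok = sys.eval(t + h, tmp.data(), K[5].data());
      }
      double errnorm = HUGE_VAL;
      if (ok) {
        for (int i = 0; i < n; ++i)
          ynew[i] = y[i] + h * (b1 * K[0][i] + b3 * K[2][i] + b4 * K[3][i] +
                                b5 * K[4][i] + b6 * K[5][i]);
        ok = sys.eval(t + h, ynew.data(), K[6].data());
        if (ok) {
          errnorm = 0.0;
          for (int i = 0; i < n; ++i) {
            const double err =
              h * (e1 * K[0][i] + e3 * K[2][i] + e4 * K[3][i] + e5 * K[4][i] +
                   e6 * K[5][i] + e7 * K[6][i]);
            const double sc =
              atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
            const double e = std::fabs(err) / sc;
            if (e > errnorm) errnorm = e;
          }
          if (!std::isfinite(errnorm)) errnorm = HUGE_VAL;
        }
      }
      if (errnorm <= 1.0) {
        t += h;
        y = ynew;
        K[0] = K[6];  // FSAL; on rejection K[0] stays valid at (t, y)
        have_k1 = true;
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-16), -1.0 / 5.0);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(y[i])) return {false, "non-finite state"};
      out[k * n + i] = y[i];
    }
  }
  return {true, "ok"};
}

// [[Rcpp::export]]
List integrate_ode_cpp(int model_id, SEXP rhs_fun, NumericVector params,
                       NumericVector y0, NumericVector times, double rtol,
                       double atol, int method, int max_steps) {
  const int n = y0.size();
  const int nt = times.size();
  std::vector<double> tt(times.begin(), times.end());
  NumericMatrix out(n, nt);  // col j = state at times[j]
  OdeSystem sys(model_id, n, REAL(params), params.size(), rhs_fun, params);
  std::vector<double> buf(n * nt, NA_REAL);
  std::vector<double> y0v(y0.begin(), y0.end());
  IntResult res = (method == 2)
    ? integrate_dopri(sys, y0v.data(), tt, rtol, atol, max_steps, buf.data())
    : integrate_rosenbrock(sys, y0v.data(), tt, rtol, atol, max_steps,
                           buf.data());
  if (res.success)
    for (int j = 0; j < nt; ++j)
      for (int i = 0; i < n; ++i) out(i, j) = buf[j * n + i];
  return List::create(_["success"] = res.success, _["values"] = out,
                      _["message"] = res.message);
}

// ---------------------------------------------------------------------------
// Cubic splines in moment form
// ---------------------------------------------------------------------------

// boundary: 0 natural, 1 parabolic, 2 cubic runout
static void spline_moments(const double* x, const double* y, int m, int ncomp,
                           int boundary, double* M /* m x ncomp col-major */) {
  const int ni = m - 2;  // interior unknowns M_2..M_{m-1}
  std::vector<double> h(m - 1);
  for (int i = 0; i < m - 1; ++i) h[i] = x[i + 1] - x[i];

  std::vector<double> sub(ni), diag(ni), sup(ni);
  for (int r = 0; r < ni; ++r) {
    // interior equation at knot i = r + 1 (0-based)
    const int i = r + 1;
    sub[r] = h[i - 1];
    diag[r] = 2.0 * (h[i - 1] + h[i]);
    sup[r] = h[i];
  }
  // fold the boundary relations into the first/last interior rows
  if (boundary == 1) {           // M1 = M2 ; Mm = M_{m-1}
    diag[0] += h[0];
    diag[ni - 1] += h[m - 2];
  } else if (boundary == 2) {    // M1 = 2 M2 - M3 ; Mm = 2 M_{m-1} - M_{m-2}
    diag[0] += 2.0 * h[0];
    sup[0] -= h[0];
    diag[ni - 1] += 2.0 * h[m - 2];
    sub[ni - 1] -= h[m - 2];
  }

  std::vector<double> cp(ni), rhs(ni);
  for (int c = 0; c < ncomp; ++c) {
    const double* yc = y + (size_t)c * m;
    double* Mc = M + (size_t)c * m;
    for (int r = 0; r < ni; ++r) {
      const int i = r + 1;
      rhs[r] = 6.0 * ((yc[i + 1] - yc[i]) / h[i] - (yc[i] - yc[i - 1]) / h[i - 1]);
    }
    // Thomas algorithm
    std::vector<double> dd(diag);
    for (int r = 1; r < ni; ++r) {
      const double w = sub[r] / dd[r - 1];
      dd[r] -= w * sup[r - 1];
      rhs[r] -= w * rhs[r - 1];
    }
    Mc[m - 2] = rhs[ni - 1] / dd[ni - 1];
    for (int r = ni - 2; r >= 0; --r)
      Mc[r + 1] = (rhs[r] - sup[r] * Mc[r + 2]) / dd[r];
    if (boundary == 0) {
      Mc[0] = 0.0; Mc[m - 1] = 0.0;
    } else if (boundary == 1) {
      Mc[0] = Mc[1]; Mc[m - 1] = Mc[m - 2];
    } else {
      Mc[0] = 2.0 * Mc[1] - Mc[2];
      Mc[m - 1] = 2.0 * Mc[m - 2] - Mc[m - 3];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix spline_moments_cpp(NumericVector x, NumericMatrix y,
                                 int boundary) {
  const int m = x.size(), ncomp = y.ncol();
  if (y.nrow() != m) stop("y must have one row per knot");
  NumericMatrix M(m, ncomp);
  spline_moments(REAL(x), REAL(y), m, ncomp, boundary, REAL(M));
  return M;
}

static int find_interval(const double* x, int m, double t) {
  // greatest i with x[i] <= t, clamped to [0, m-2]
  if (t <= x[0]) return 0;
  if (t >= x[m - 1]) return m - 2;
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= t) lo = mid; else hi = mid;
  }
  return lo;
}

static double spline_eval1(const double* x, const double* yc, const double* Mc,
                           int m, double t, int order) {
  const int i = find_interval(x, m, t);
  const double h = x[i + 1] - x[i];
  const double a = yc[i];
  const double b = (yc[i + 1] - yc[i]) / h - h * (2.0 * Mc[i] + Mc[i + 1]) / 6.0;
  const double cc = Mc[i] / 2.0;
  const double dd = (Mc[i + 1] - Mc[i]) / (6.0 * h);
  const double u = t - x[i];
  if (order == 0) return a + u * (b + u * (cc + u * dd));
  if (order == 1) return b + u * (2.0 * cc + 3.0 * dd * u);
  return 2.0 * cc + 6.0 * dd * u;
}

// [[Rcpp::export]]
NumericMatrix spline_eval_cpp(NumericVector x, NumericMatrix y, NumericMatrix M,
                              NumericVector tt, int order) {
  const int m = x.size(), ncomp = y.ncol(), nt = tt.size();
  NumericMatrix out(nt, ncomp);
  for (int c = 0; c < ncomp; ++c) {
    const double* yc = REAL(y) + (size_t)c * m;
    const double* Mc = REAL(M) + (size_t)c * m;
    for (int j = 0; j < nt; ++j)
      out(j, c) = spline_eval1(REAL(x), yc, Mc, m, tt[j], order);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Compiled fitness path for native models
// ---------------------------------------------------------------------------

// Squared-difference sums.  All matrices are (npoints x ncomp), column-major.
// Relative terms skip entries whose denominator magnitude is <= guard.
static double sq_err(const double* sim, const double* obs, int npt, int nc,
                     bool relative, double guard, const double* w) {
  double s = 0.0;
  for (int c = 0; c < nc; ++c) {
    for (int j = 0; j < npt; ++j) {
      const size_t k = (size_t)c * npt + j;
      double d = sim[k] - obs[k];
      if (relative) {
        if (std::fabs(obs[k]) <= guard) continue;
        d /= obs[k];
      }
      s += (w ? w[j] : 1.0) * d * d;
    }
  }
  return s;
}

// per-component maximum |curvature| (optionally scaled by |value|)
static void max_curv(const double* d2, const double* val, int npt, int nc,
                     bool relative, double guard, double* out) {
  for (int c = 0; c < nc; ++c) {
    double mx = 0.0;
    for (int j = 0; j < npt; ++j) {
      const size_t k = (size_t)c * npt + j;
      double v = std::fabs(d2[k]);
      if (relative) {
        if (std::fabs(val[k]) <= guard) continue;
        v /= std::fabs(val[k]);
      }
      if (v > mx) mx = v;
    }
    out[c] = mx;
  }
}

// [[Rcpp::export]]
List fitness_native_cpp(int model_id, NumericVector params, NumericVector y0,
                        NumericVector obs_times, NumericMatrix obs_vals,
                        NumericMatrix obs_d1, NumericMatrix obs_d2,
                        NumericVector grid, NumericMatrix og0,
                        NumericMatrix og1, NumericMatrix og2,
                        IntegerVector terms, NumericVector weights,
                        NumericVector sim_grid, double rtol, double atol,
                        int max_steps, double guard) {
  const int n = y0.size();
  bool continuous = false, need_d1 = false, need_d2 = false, need_rough = false;
  for (int q = 0; q < terms.size(); ++q) {
    const int e = terms[q];
    if (e >= 10) continuous = true;
    if (e == 4 || e == 5 || e == 12 || e == 13) need_d1 = true;
    if (e == 6 || e == 7 || e == 14 || e == 15) need_d2 = true;
    if (e == 8 || e == 9 || e == 16 || e == 17) { need_d2 = true; need_rough = true; }
  }

  const NumericVector& tsim = continuous ? sim_grid : obs_times;
  const int nt = tsim.size();
  std::vector<double> tt(tsim.begin(), tsim.end());
  std::vector<double> buf((size_t)n * nt);
  std::vector<double> y0v(y0.begin(), y0.end());
  OdeSystem sys(model_id, n, REAL(params), params.size(), R_NilValue,
                NumericVector(0));
  IntResult res = integrate_rosenbrock(sys, y0v.data(), tt, rtol, atol,
                                       max_steps, buf.data());
  NumericVector per(terms.size(), NA_REAL);
  if (!res.success)
    return List::create(_["total"] = R_PosInf, _["per_term"] = per,
                        _["failed"] = true, _["message"] = res.message);

  // sim values, times in rows / components in columns
  std::vector<double> sv((size_t)nt * n);
  for (int j = 0; j < nt; ++j)
    for (int c = 0; c < n; ++c) sv[(size_t)c * nt + j] = buf[(size_t)j * n + c];

  // spline of the simulation on its own grid (natural boundary)
  std::vector<double> sM((size_t)nt * n);
  std::vector<double> s0, s1, s2;
  const int m_obs = obs_times.size();
  int npt;         // number of comparison points
  const double* S0; const double* S1 = nullptr; const double* S2 = nullptr;
  const double* O0; const double* O1 = nullptr; const double* O2 = nullptr;

  if (!continuous) {
    npt = m_obs;
    S0 = sv.data(); O0 = REAL(obs_vals); O1 = REAL(obs_d1); O2 = REAL(obs_d2);
    if (need_d1 || need_d2) {
      spline_moments(tt.data(), sv.data(), nt, n, 0, sM.data());
      s1.resize((size_t)npt * n); s2.resize((size_t)npt * n);
      for (int c = 0; c < n; ++c)
        for (int j = 0; j < npt; ++j) {
          const double* yc = sv.data() + (size_t)c * nt;
          const double* Mc = sM.data() + (size_t)c * nt;
          if (need_d1)
            s1[(size_t)c * npt + j] =
              spline_eval1(tt.data(), yc, Mc, nt, obs_times[j], 1);
          s2[(size_t)c * npt + j] =
            spline_eval1(tt.data(), yc, Mc, nt, obs_times[j], 2);
        }
      S1 = s1.data(); S2 = s2.data();
    }
  } else {
    npt = grid.size();
    spline_moments(tt.data(), sv.data(), nt, n, 0, sM.data());
    s0.resize((size_t)npt * n); s1.resize((size_t)npt * n);
    s2.resize((size_t)npt * n);
    for (int c = 0; c < n; ++c) {
      const double* yc = sv.data() + (size_t)c * nt;
      const double* Mc = sM.data() + (size_t)c * nt;
      for (int j = 0; j < npt; ++j) {
        s0[(size_t)c * npt + j] = spline_eval1(tt.data(), yc, Mc, nt, grid[j], 0);
        if (need_d1)
          s1[(size_t)c * npt + j] = spline_eval1(tt.data(), yc, Mc, nt, grid[j], 1);
        if (need_d2)
          s2[(size_t)c * npt + j] = spline_eval1(tt.data(), yc, Mc, nt, grid[j], 2);
      }
    }
    S0 = s0.data(); S1 = s1.data(); S2 = s2.data();
    O0 = REAL(og0); O1 = REAL(og1); O2 = REAL(og2);
  }

  // Simpson weights on the sampling grid (uniform, even panel count)
  std::vector<double> simp;
  if (continuous) {
    simp.resize(npt);
    const double hh = (grid[npt - 1] - grid[0]) / (npt - 1);
    for (int j = 0; j < npt; ++j)
      simp[j] = (j == 0 || j == npt - 1) ? hh / 3.0
                : ((j % 2 == 1) ? 4.0 * hh / 3.0 : 2.0 * hh / 3.0);
  }
  const double* w = continuous ? simp.data() : nullptr;

  std::vector<double> rs(n), ro(n);
  double total = 0.0;
  for (int q = 0; q < terms.size(); ++q) {
    const int e = terms[q];
    double v = 0.0;
    switch (e) {
      case 2:  v = sq_err(S0, O0, npt, n, false, guard, nullptr); break;
      case 3:  v = sq_err(S0, O0, npt, n, true, guard, nullptr); break;
      case 4:  v = sq_err(S1, O1, npt, n, false, guard, nullptr); break;
      case 5:  v = sq_err(S1, O1, npt, n, true, guard, nullptr); break;
      case 6:  v = sq_err(S2, O2, npt, n, false, guard, nullptr); break;
      case 7:  v = sq_err(S2, O2, npt, n, true, guard, nullptr); break;
      case 10: v = sq_err(S0, O0, npt, n, false, guard, w); break;
      case 11: v = sq_err(S0, O0, npt, n, true, guard, w); break;
      case 12: v = sq_err(S1, O1, npt, n, false, guard, w); break;
      case 13: v = sq_err(S1, O1, npt, n, true, guard, w); break;
      case 14: v = sq_err(S2, O2, npt, n, false, guard, w); break;
      case 15: v = sq_err(S2, O2, npt, n, true, guard, w); break;
      case 8: case 9: case 16: case 17: {
        // squared difference of per-component maximal |curvature|; the
        // relative form divides the difference by the observed maximum
        const bool rel = (e == 9 || e == 17);
        max_curv(S2, S0, npt, n, false, guard, rs.data());
        max_curv(O2, O0, npt, n, false, guard, ro.data());
        v = 0.0;
        for (int c = 0; c < n; ++c) {
          double d = rs[c] - ro[c];
          if (rel) {
            if (ro[c] <= guard) continue;
            d /= ro[c];
          }
          v += d * d;
        }
        break;
      }
      default: stop("unknown term id");
    }
    per[q] = v;
    total += weights[q] * v;
  }
  return List::create(_["total"] = total, _["per_term"] = per,
                      _["failed"] = false, _["message"] = "ok");
}
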