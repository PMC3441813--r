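#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state (retained/lost) hidden Markov chain along an ordered set of
// markers.  Initial distribution (r, 1-r) is the stationary distribution of
// every transition step, so the likelihood is invariant under order reversal.
// Calls are coded 0 = absent, 1 = present, 2 = ambiguous (no emission factor).

static inline double clamp_log(double p) {
  return std::log(p > 1e-300 ? p : 1e-300);
}

// forward log-likelihood for one clone vector laid out in `calls` column j
static double forward_clone(const int* calls, int m, int stride,
                            const double* thetas, double r, double err) {
  double e1r = 1.0 - err, e1l = err;   // P(obs = 1 | state)
  double e0r = err, e0l = 1.0 - err;   // P(obs = 0 | state)
  int c = calls[0];
  double a_ret = r, a_lost = 1.0 - r;
  if (c == 1)      { a_ret *= e1r; a_lost *= e1l; }
  else if (c == 0) { a_ret *= e0r; a_lost *= e0l; }
  double ll = 0.0, s = a_ret + a_lost;
  if (s <= 0) return -1e300;
  ll += std::log(s); a_ret /= s; a_lost /= s;
  for (int k = 1; k < m; ++k) {
    double th = thetas[k - 1];
    double rr = (1.0 - th) + th * r;          // ret -> ret
    double rl = th * (1.0 - r);               // ret -> lost
    double lr = th * r;                       // lost -> ret
    double llo = (1.0 - th) + th * (1.0 - r); // lost -> lost
    double n_ret = a_ret * rr + a_lost * lr;
    double n_lost = a_ret * rl + a_lost * llo;
    c = calls[(size_t)k * stride];
    if (c == 1)      { n_ret *= e1r; n_lost *= e1l; }
    else if (c == 0) { n_ret *= e0r; n_lost *= e0l; }
    s = n_ret + n_lost;
    if (s <= 0) return -1e300;
    ll += std::log(s);
    a_ret = n_ret / s; a_lost = n_lost / s;
  }
  return ll;
}

// [[Rcpp::export(name = ".mp_loglik_cpp")]]
double mp_loglik_cpp(IntegerMatrix calls, NumericVector thetas,
                     double r, double err) {
  int n = calls.nrow(), m = calls.ncol();
  if (thetas.size() != m - 1) stop("thetas must have length ncol(calls) - 1");
  double total = 0.0;
  const int* base = INTEGER(calls);
  for (int i = 0; i < n; ++i)
    total += forward_clone(base + i, m, n, REAL(thetas), r, err);
  return total;
}

static double loglik_all(const int* base, int n, int m,
                         const std::vector<double>& thetas, double r,
                         double err) {
  double total = 0.0;
  for (int i = 0; i < n; ++i)
    total += forward_clone(base + i, m, n, thetas.data(), r, err);
  return total;
}

// golden-section maximization of the full likelihood in one theta
static double golden_theta(const int* base, int n, int m,
                           std::vector<double>& thetas, int idx, double r,
                           double err, double lo, double hi, double xtol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  thetas[idx] = x1; double f1 = loglik_all(base, n, m, thetas, r, err);
  thetas[idx] = x2; double f2 = loglik_all(base, n, m, thetas, r, err);
  while (b - a > xtol) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a);
      thetas[idx] = x2; f2 = loglik_all(base, n, m, thetas, r, err); }
    else { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a);
      thetas[idx] = x1; f1 = loglik_all(base, n, m, thetas, r, err); }
  }
  double xm = 0.5 * (a + b);
  thetas[idx] = xm;
  double fm = loglik_all(base, n, m, thetas, r, err);
  // keep exact boundary solutions (theta = 0 for duplicated markers)
  thetas[idx] = lo;
  double fl = loglik_all(base, n, m, thetas, r, err);
  if (fl >= fm) return fl;
  thetas[idx] = xm;
  return fm;
}

// [[Rcpp::export(name = ".mp_fit_thetas_cpp")]]
List mp_fit_thetas_cpp(IntegerMatrix calls, double r, double err,
                       NumericVector init, double tol, double xtol,
                       int min_sweeps, int max_sweeps) {
  int n = calls.nrow(), m = calls.ncol();
  if (m < 2) stop("need at least two markers");
  std::vector<double> thetas(m - 1);
  for (int k = 0; k < m - 1; ++k) thetas[k] = init[k];
  const int* base = INTEGER(calls);
  const double hi = 1.0 - 1e-6;
  double ll = loglik_all(base, n, m, thetas, r, err);
  bool converged = false;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    double ll_new = ll;
    for (int k = 0; k < m - 1; ++k)
      ll_new = golden_theta(base, n, m, thetas, k, r, err, 0.0, hi, xtol);
    if (sweep >= min_sweeps && ll_new - ll < tol) { converged = true; ll = ll_new; break; }
    ll = ll_new;
  }
  return List::create(_["thetas"] = NumericVector(thetas.begin(), thetas.end()),
                      _["loglik"] = ll, _["sweeps"] = sweep,
                      _["converged"] = converged);
}

// Exhaustive (theta, r) lattice search for the two-point linked likelihood.
// Brute-force reference: shares nothing with the optim-based estimator.
// The linked likelihood depends on the table only through n11, n10 + n01, n00.
// [[Rcpp::export(name = ".tp_grid_search_cpp")]]
NumericMatrix tp_grid_search_cpp(NumericMatrix tables, double step) {
  int nth = (int)std::lround(1.0 / step) + 1;   // theta in {0, step, ..., 1}
  int nr = (int)std::lround(1.0 / step) - 1;    // r in {step, ..., 1 - step}
  size_t G = (size_t)nth * nr;
  std::vector<double> L11(G), L10(G), L00(G);
  size_t g = 0;
  for (int it = 0; it < nth; ++it) {
    double th = it * step;
    for (int ir = 1; ir <= nr; ++ir, ++g) {
      double r = ir * step;
      double p11 = r * (1.0 - th) + r * r * th;
      double p10 = r * th * (1.0 - r);
      double p00 = (1.0 - th) * (1.0 - r) + th * (1.0 - r) * (1.0 - r);
      L11[g] = clamp_log(p11); L10[g] = clamp_log(p10); L00[g] = clamp_log(p00);
    }
  }
  int nt = tables.nrow();
  NumericMatrix out(nt, 3);
  for (int t = 0; t < nt; ++t) {
    double n11 = tables(t, 0), ns = tables(t, 1), n00 = tables(t, 2);
    double best = -1e308; size_t bg = 0;
    for (size_t i = 0; i < G; ++i) {
      double ll = n11 * L11[i] + ns * L10[i] + n00 * L00[i];
      if (ll > best) { best = ll; bg = i; }
    }
    int it = (int)(bg / nr), ir = (int)(bg % nr) + 1;
    out(t, 0) = it * step;
    out(t, 1) = ir * step;
    out(t, 2) = best;
  }
  return out;
}
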