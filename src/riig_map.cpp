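// Fast RiIG sliding-window fitting for parametric imaging.
//
// Same likelihood as the R-level fitter: the RiIG log-density uses the
// closed form of K_{3/2} and a polynomial I_0 (Abramowitz & Stegun
// 9.8.1/9.8.2), maximized over (alpha, beta, delta) in the
// reparametrization (log(alpha-|beta|), beta, log delta) by Nelder-Mead
// from the symmetric moment initialization. All computation per window is
// independent of scan order, so maps computed at different strides agree
// exactly on shared grid points.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

double log_i0(double x) {
  x = std::fabs(x);
  if (x < 3.75) {
    double t = (x / 3.75) * (x / 3.75);
    double p = 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
               t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
    return std::log(p);
  }
  double u = 3.75 / x;
  double p = 0.39894228 + u * (0.01328592 + u * (0.00225319 + u * (-0.00157565 +
             u * (0.00916281 + u * (-0.02057706 + u * (0.02635537 +
             u * (-0.01647633 + u * 0.00392377)))))));
  return x - 0.5 * std::log(x) + std::log(p);
}

// Negative log-likelihood at par = (u, beta, s); r2 holds r^2, lr log r.
double riig_nll(const double* par, const std::vector<double>& r,
                const std::vector<double>& r2, const std::vector<double>& lr) {
  double beta = par[1];
  double alpha = std::fabs(beta) + std::exp(par[0]);
  double delta = std::exp(par[2]);
  if (!std::isfinite(alpha) || alpha > 500.0 || delta > 1e3 || delta < 1e-6)
    return 1e10;
  double gam = std::sqrt(alpha * alpha - beta * beta);
  double d2 = delta * delta;
  double cst = 0.5 * std::log(2.0 / M_PI) + 1.5 * std::log(alpha) +
               std::log(delta) + delta * gam + 0.5 * std::log(M_PI / 2.0);
  double ll = 0.0;
  const size_t n = r.size();
  for (size_t i = 0; i < n; ++i) {
    double y = d2 + r2[i];
    double sq = std::sqrt(y);
    double s = alpha * sq;
    // log K_{3/2}(s) = 0.5*log(pi/(2s)) - s + log1p(1/s); the 0.5*log(pi/2)
    // piece is folded into cst.
    double lk = -0.5 * std::log(s) - s + std::log1p(1.0 / s);
    double li = (beta != 0.0) ? log_i0(beta * r[i]) : 0.0;
    ll += lr[i] - 0.75 * std::log(y) + lk + li;
  }
  ll += n * cst;
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}

struct FitOut { double alpha, beta, delta, nll; bool converged; };

// Compact Nelder-Mead on the 3-parameter RiIG likelihood.
FitOut nelder_mead(const std::vector<double>& r, double max_evals) {
  const size_t n = r.size();
  std::vector<double> r2(n), lr(n);
  double m2 = 0, m4 = 0;
  for (size_t i = 0; i < n; ++i) {
    r2[i] = r[i] * r[i];
    lr[i] = std::log(std::max(r[i], 1e-300));
    m2 += r2[i]; m4 += r2[i] * r2[i];
  }
  m2 /= n; m4 /= n;
  double ratio = m4 / (2.0 * m2 * m2);
  double dg = 1.0 / std::max(ratio - 1.0, 0.02);
  double delta0 = std::sqrt(std::max(m2 * dg / 2.0, 1e-10));
  delta0 = std::min(std::max(delta0, 1e-5), 990.0);
  double gamma0 = std::min(std::max(dg / delta0, 1e-3), 450.0);

  const int d = 3;
  double simplex[4][3];
  double f[4];
  double p0[3] = {std::log(gamma0), 0.0, std::log(delta0)};
  double step[3] = {0.5, 0.3, 0.5};
  for (int v = 0; v < 4; ++v) {
    for (int j = 0; j < d; ++j) simplex[v][j] = p0[j];
    if (v > 0) simplex[v][v - 1] += step[v - 1];
    f[v] = riig_nll(simplex[v], r, r2, lr);
  }
  int evals = 4;
  while (evals < max_evals) {
    // order
    int lo = 0, hi = 0;
    for (int v = 1; v < 4; ++v) {
      if (f[v] < f[lo]) lo = v;
      if (f[v] > f[hi]) hi = v;
    }
    int nh = (hi == 0) ? 1 : 0;
    for (int v = 0; v < 4; ++v)
      if (v != hi && f[v] > f[nh]) nh = v;
    if (f[hi] - f[lo] < 1e-5 * (std::fabs(f[lo]) + 1e-8)) break;
    double cen[3] = {0, 0, 0};
    for (int v = 0; v < 4; ++v)
      if (v != hi) for (int j = 0; j < d; ++j) cen[j] += simplex[v][j] / 3.0;
    double refl[3];
    for (int j = 0; j < d; ++j) refl[j] = cen[j] + (cen[j] - simplex[hi][j]);
    double fr = riig_nll(refl, r, r2, lr); ++evals;
    if (fr < f[lo]) {
      double exp_[3];
      for (int j = 0; j < d; ++j) exp_[j] = cen[j] + 2.0 * (cen[j] - simplex[hi][j]);
      double fe = riig_nll(exp_, r, r2, lr); ++evals;
      if (fe < fr) { std::copy(exp_, exp_ + 3, simplex[hi]); f[hi] = fe; }
      else { std::copy(refl, refl + 3, simplex[hi]); f[hi] = fr; }
    } else if (fr < f[nh]) {
      std::copy(refl, refl + 3, simplex[hi]); f[hi] = fr;
    } else {
      double con[3];
      for (int j = 0; j < d; ++j) con[j] = cen[j] + 0.5 * (simplex[hi][j] - cen[j]);
      double fc = riig_nll(con, r, r2, lr); ++evals;
      if (fc < f[hi]) { std::copy(con, con + 3, simplex[hi]); f[hi] = fc; }
      else {
        for (int v = 0; v < 4; ++v) {
          if (v == lo) continue;
          for (int j = 0; j < d; ++j)
            simplex[v][j] = simplex[lo][j] + 0.5 * (simplex[v][j] - simplex[lo][j]);
          f[v] = riig_nll(simplex[v], r, r2, lr); ++evals;
        }
      }
    }
  }
  int lo = 0;
  for (int v = 1; v < 4; ++v) if (f[v] < f[lo]) lo = v;
  FitOut out;
  out.beta = simplex[lo][1];
  out.alpha = std::fabs(out.beta) + std::exp(simplex[lo][0]);
  out.delta = std::exp(simplex[lo][2]);
  out.nll = f[lo];
  out.converged = std::isfinite(f[lo]) && f[lo] < 1e9;
  if (!out.converged) {
    out.alpha = gamma0; out.beta = 0.0; out.delta = delta0;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".riig_fit_cpp")]]
List riig_fit_cpp(NumericVector x, int max_evals = 200) {
  std::vector<double> r(x.begin(), x.end());
  FitOut fit = nelder_mead(r, max_evals);
  return List::create(_["alpha"] = fit.alpha, _["beta"] = fit.beta,
                      _["delta"] = fit.delta, _["loglik"] = -fit.nll,
                      _["converged"] = fit.converged);
}

// [[Rcpp::export(name = ".riig_map_cpp")]]
List riig_map_cpp(NumericMatrix xp, int window, IntegerVector g1,
                  IntegerVector g2, int max_evals = 120) {
  const int n1 = g1.size(), n2 = g2.size();
  NumericMatrix vals(n1, n2);
  LogicalMatrix conv(n1, n2);
  std::vector<double> w((size_t)window * window);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      // window top-left in padded coords = (g-1) (centers are 1-based in
      // the unpadded image; padding width equals the half-window)
      int r0 = g1[i] - 1, c0 = g2[j] - 1;
      size_t t = 0;
      double s1 = 0, s2 = 0;
      for (int cc = 0; cc < window; ++cc)
        for (int rr = 0; rr < window; ++rr) {
          double v = xp(r0 + rr, c0 + cc);
          w[t++] = v; s1 += v; s2 += v * v;
        }
      double nw = (double)window * window;
      double mean = s1 / nw;
      double sd = std::sqrt(std::max(s2 / nw - mean * mean, 0.0));
      if (sd < 1e-12 * (std::fabs(mean) + 1e-300)) {
        vals(i, j) = std::max(std::sqrt(s2 / nw / 2.0), 1e-6);
        conv(i, j) = false;
        continue;
      }
      FitOut fit = nelder_mead(w, max_evals);
      if (fit.converged) {
        vals(i, j) = fit.delta;
        conv(i, j) = true;
      } else {
        vals(i, j) = std::max(std::sqrt(s2 / nw / 2.0), 1e-6);
        conv(i, j) = false;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["values"] = vals, _["converged"] = conv);
}
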