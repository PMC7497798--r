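// Per-pixel TCSPC decay fitting.
//
// The expected decay is the discrete convolution of a (possibly
// fractionally shifted) instrument response function with a one- or
// two-component exponential, plus a constant offset:
//
//   m_k = a1 * y_k(tau1) + a2 * y_k(tau2) + offset
//   y_k(tau) = sum_{j<=k} irf_j * exp(-(k-j) * dt / tau)
//
// y_k obeys the O(n) recursion y_k = exp(-dt/tau) * y_{k-1} + irf_k,
// which also yields d y_k / d tau recursively, so one Levenberg-Marquardt
// iteration costs O(n_bins) rather than O(n_bins^2). Residuals are
// Poisson-weighted with model-based variance (Pearson chi-square):
// r_k = (m_k - d_k) / sqrt(max(m_k, 1)), weights recomputed at every
// evaluation. Data-based weights 1/max(d_k, 1) bias the long-lifetime
// component low wherever tail bins hold only a few photons; model-based
// weights remove that bias. The weight's own parameter dependence is
// ignored in the Jacobian (standard IRLS approximation); step acceptance
// uses the exact objective, so the iteration stays monotone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sample v at positions (k - s) with linear interpolation, zero outside.
// Positive s moves the curve toward later bins.
static arma::vec shift_linear(const arma::vec &v, double s) {
  const int n = v.n_elem;
  if (s == 0.0) return v;
  arma::vec out(n, arma::fill::zeros);
  for (int k = 0; k < n; ++k) {
    double x = k - s;
    int i0 = (int)std::floor(x);
    double f = x - i0;
    double lo = (i0 >= 0 && i0 < n) ? v[i0] : 0.0;
    double hi = (i0 + 1 >= 0 && i0 + 1 < n) ? v[i0 + 1] : 0.0;
    out[k] = (1.0 - f) * lo + f * hi;
  }
  return out;
}

// Convolution of irf with exp(-t/tau) at bin resolution; optional d/dtau.
static void conv_exp(const arma::vec &irf, double tau, double dt,
                     arma::vec &y, arma::vec *dy = nullptr) {
  const int n = irf.n_elem;
  const double e = std::exp(-dt / tau);
  const double de = e * dt / (tau * tau);
  y.set_size(n);
  y[0] = irf[0];
  if (dy) { dy->set_size(n); (*dy)[0] = 0.0; }
  for (int k = 1; k < n; ++k) {
    y[k] = e * y[k - 1] + irf[k];
    if (dy) (*dy)[k] = e * (*dy)[k - 1] + de * y[k - 1];
  }
}

struct FitOpts {
  double dt;
  int k0, k1;            // fit window (0-based, inclusive)
  bool fit_shift;
  double shift_bound;
  int max_iter;
  double tol;
  double tau_min, tau_max;
};

struct FitResult {
  double tau1, tau2, a1, a2, offset, shift, chi2;
  bool converged;
  int iterations;
  int n_components;
};

// parameter vector layout: two components -> (tau1, tau2, a1, a2, offset[, shift])
//                          one component  -> (tau1, a1, offset[, shift])
static void clamp_params(arma::vec &p, int ncomp, const FitOpts &o) {
  if (ncomp == 2) {
    p[0] = std::min(std::max(p[0], o.tau_min), o.tau_max);
    p[1] = std::min(std::max(p[1], o.tau_min), o.tau_max);
    p[2] = std::max(p[2], 0.0);
    p[3] = std::max(p[3], 0.0);
    p[4] = std::max(p[4], 0.0);
    if (o.fit_shift) p[5] = std::min(std::max(p[5], -o.shift_bound), o.shift_bound);
  } else {
    p[0] = std::min(std::max(p[0], o.tau_min), o.tau_max);
    p[1] = std::max(p[1], 0.0);
    p[2] = std::max(p[2], 0.0);
    if (o.fit_shift) p[3] = std::min(std::max(p[3], -o.shift_bound), o.shift_bound);
  }
}

// model and weighted Jacobian over the fit window; sw is filled with the
// model-based weights 1/sqrt(max(m_k, 1)) used for this evaluation
static void eval_model(const arma::vec &p, int ncomp, const arma::vec &irf,
                       const FitOpts &o, arma::vec &sw,
                       arma::vec &r, const arma::vec &data,
                       arma::mat *J = nullptr) {
  const int nw = o.k1 - o.k0 + 1;
  double shift = 0.0;
  int ip_off = (ncomp == 2) ? 4 : 2;
  if (o.fit_shift) shift = p[ip_off + 1];
  arma::vec irf_s = shift_linear(irf, shift);

  arma::vec y1, y2, dy1, dy2;
  if (J) {
    conv_exp(irf_s, p[0], o.dt, y1, &dy1);
    if (ncomp == 2) conv_exp(irf_s, p[1], o.dt, y2, &dy2);
  } else {
    conv_exp(irf_s, p[0], o.dt, y1);
    if (ncomp == 2) conv_exp(irf_s, p[1], o.dt, y2);
  }

  const double a1 = (ncomp == 2) ? p[2] : p[1];
  const double a2 = (ncomp == 2) ? p[3] : 0.0;
  const double off = p[ip_off];

  r.set_size(nw);
  sw.set_size(nw);
  for (int k = 0; k < nw; ++k) {
    double m = a1 * y1[o.k0 + k] + off;
    if (ncomp == 2) m += a2 * y2[o.k0 + k];
    sw[k] = 1.0 / std::sqrt(std::max(m, 1.0));
    r[k] = (m - data[o.k0 + k]) * sw[k];
  }

  if (J) {
    int npar = ip_off + 1 + (o.fit_shift ? 1 : 0);
    J->set_size(nw, npar);
    for (int k = 0; k < nw; ++k) {
      int kk = o.k0 + k;
      if (ncomp == 2) {
        (*J)(k, 0) = a1 * dy1[kk] * sw[k];
        (*J)(k, 1) = a2 * dy2[kk] * sw[k];
        (*J)(k, 2) = y1[kk] * sw[k];
        (*J)(k, 3) = y2[kk] * sw[k];
        (*J)(k, 4) = sw[k];
      } else {
        (*J)(k, 0) = a1 * dy1[kk] * sw[k];
        (*J)(k, 1) = y1[kk] * sw[k];
        (*J)(k, 2) = sw[k];
      }
    }
    if (o.fit_shift) {
      // central finite difference on the shift
      const double h = 1e-3;
      arma::vec pl = p, ph = p;
      pl[ip_off + 1] -= h; ph[ip_off + 1] += h;
      arma::vec il = shift_linear(irf, pl[ip_off + 1]);
      arma::vec ih = shift_linear(irf, ph[ip_off + 1]);
      arma::vec y1l, y1h, y2l, y2h;
      conv_exp(il, p[0], o.dt, y1l);
      conv_exp(ih, p[0], o.dt, y1h);
      if (ncomp == 2) { conv_exp(il, p[1], o.dt, y2l); conv_exp(ih, p[1], o.dt, y2h); }
      for (int k = 0; k < nw; ++k) {
        int kk = o.k0 + k;
        double ml = a1 * y1l[kk], mh = a1 * y1h[kk];
        if (ncomp == 2) { ml += a2 * y2l[kk]; mh += a2 * y2h[kk]; }
        (*J)(k, ip_off + 1) = (mh - ml) / (2.0 * h) * sw[k];
      }
    }
  }
}

static FitResult lm_fit(const arma::vec &data, const arma::vec &irf,
                        arma::vec p, int ncomp, const FitOpts &o) {
  const int nw = o.k1 - o.k0 + 1;
  arma::vec sw(nw);

  clamp_params(p, ncomp, o);
  arma::vec r;
  arma::mat J;
  eval_model(p, ncomp, irf, o, sw, r, data, &J);
  double sse = arma::dot(r, r);

  double mu = 1e-3;
  bool converged = false;
  int it = 0;
  const int npar = p.n_elem;

  for (it = 0; it < o.max_iter; ++it) {
    arma::mat A = J.t() * J;
    arma::vec g = J.t() * r;
    bool accepted = false;
    for (int inner = 0; inner < 12; ++inner) {
      arma::mat Areg = A;
      for (int i = 0; i < npar; ++i)
        Areg(i, i) += mu * std::max(A(i, i), 1e-12);
      arma::vec step;
      bool ok = arma::solve(step, Areg, g, arma::solve_opts::no_approx);
      if (!ok) { mu *= 10.0; continue; }
      arma::vec pn = p - step;
      clamp_params(pn, ncomp, o);
      arma::vec rn;
      eval_model(pn, ncomp, irf, o, sw, rn, data);
      double ssen = arma::dot(rn, rn);
      if (ssen <= sse) {
        double rel = (sse - ssen) / std::max(sse, 1e-300);
        p = pn;
        double prev = sse;
        sse = ssen;
        mu = std::max(mu / 3.0, 1e-12);
        eval_model(p, ncomp, irf, o, sw, r, data, &J);
        accepted = true;
        if (rel < o.tol || prev == 0.0) converged = true;
        break;
      }
      mu *= 5.0;
      if (mu > 1e12) break;
    }
    if (!accepted) { converged = true; break; }  // stuck: local minimum
    if (converged) break;
  }

  FitResult res;
  if (ncomp == 2) {
    res.tau1 = p[0]; res.tau2 = p[1]; res.a1 = p[2]; res.a2 = p[3];
    res.offset = p[4];
    res.shift = o.fit_shift ? p[5] : 0.0;
  } else {
    res.tau1 = p[0]; res.tau2 = p[0]; res.a1 = p[1]; res.a2 = 0.0;
    res.offset = p[2];
    res.shift = o.fit_shift ? p[3] : 0.0;
  }
  int nfree = npar;
  res.chi2 = sse / std::max(nw - nfree, 1);
  res.converged = converged;
  res.iterations = it + 1;
  res.n_components = ncomp;
  return res;
}

// Starting values: fixed lifetimes, offset from pre-rise bins, amplitudes by
// matching the total count with a fixed split between the components.
static arma::vec init_params(const arma::vec &data, int irf_mode,
                             const FitOpts &o, int ncomp,
                             double tau1 = 0.5, double tau2 = 2.5,
                             double f = 0.7) {
  const int n = data.n_elem;
  double offset = 0.0;
  int pre_hi = irf_mode - 3, pre_lo = irf_mode - 7;
  if (pre_hi >= 0) {
    pre_lo = std::max(pre_lo, 0);
    double s = 0.0;
    for (int k = pre_lo; k <= pre_hi; ++k) s += data[k];
    offset = s / (pre_hi - pre_lo + 1);
  }
  double total = 0.0;
  for (int k = 0; k < n; ++k) total += data[k];
  double sig = std::max(total - offset * n, 1.0);

  auto geom = [&](double tau) {
    double e = std::exp(-o.dt / tau);
    return (1.0 - std::pow(e, n)) / (1.0 - e);
  };
  arma::vec p;
  if (ncomp == 2) {
    double denom = f * geom(tau1) + (1.0 - f) * geom(tau2);
    p.set_size(o.fit_shift ? 6 : 5);
    p[0] = tau1; p[1] = tau2;
    p[2] = f * sig / denom;
    p[3] = (1.0 - f) * sig / denom;
    p[4] = offset;
    if (o.fit_shift) p[5] = 0.0;
  } else {
    p.set_size(o.fit_shift ? 4 : 3);
    p[0] = 1.0;
    p[1] = sig / geom(1.0);
    p[2] = offset;
    if (o.fit_shift) p[3] = 0.0;
  }
  return p;
}

static FitResult fit_one(const arma::vec &data, const arma::vec &irf,
                         int irf_mode, FitOpts o) {
  const int n = data.n_elem;
  // fit window: 2 bins before the IRF mode to the last informative bin
  o.k0 = std::max(irf_mode - 2, 0);
  int k1 = n - 1;
  while (k1 > o.k0 && data[k1] < 1.0) --k1;
  o.k1 = std::max(k1, std::min(o.k0 + 8, n - 1));

  arma::vec p0 = init_params(data, irf_mode, o, 2);
  FitResult res = lm_fit(data, irf, p0, 2, o);

  // LM can pin an amplitude at its bound from an unlucky start; retry
  // poorly fitting pixels from alternative starting points and keep the
  // best reduced chi-square
  if (res.chi2 > 2.0) {
    const double alt[2][3] = {{0.5, 2.5, 0.3}, {0.3, 1.5, 0.5}};
    for (int a = 0; a < 2; ++a) {
      arma::vec pa = init_params(data, irf_mode, o, 2,
                                 alt[a][0], alt[a][1], alt[a][2]);
      FitResult ra = lm_fit(data, irf, pa, 2, o);
      if (ra.chi2 < res.chi2) res = ra;
      if (res.chi2 <= 2.0) break;
    }
  }

  // order components and collapse near-degenerate two-component fits
  if (res.tau1 > res.tau2) {
    std::swap(res.tau1, res.tau2);
    std::swap(res.a1, res.a2);
  }
  if (res.tau2 / std::max(res.tau1, 1e-12) < 1.5) {
    arma::vec p1 = init_params(data, irf_mode, o, 1);
    FitResult r1 = lm_fit(data, irf, p1, 1, o);
    res = r1;
  }
  return res;
}

static NumericVector result_to_vector(const FitResult &r) {
  double asum = r.a1 + r.a2;
  double a1pct = (asum > 0) ? 100.0 * r.a1 / asum : NA_REAL;
  double taum = (asum > 0) ? (r.a1 * r.tau1 + r.a2 * r.tau2) / asum : NA_REAL;
  return NumericVector::create(
      _["tau1"] = r.tau1, _["tau2"] = r.tau2, _["a1"] = r.a1, _["a2"] = r.a2,
      _["a1_pct"] = a1pct, _["tau_m"] = taum, _["chi2"] = r.chi2,
      _["offset"] = r.offset, _["shift"] = r.shift,
      _["converged"] = r.converged ? 1.0 : 0.0,
      _["iterations"] = (double)r.iterations,
      _["n_components"] = (double)r.n_components);
}

static FitOpts make_opts(double dt, bool fit_shift, double shift_bound,
                         int max_iter, double tol) {
  FitOpts o;
  o.dt = dt;
  o.fit_shift = fit_shift;
  o.shift_bound = shift_bound;
  o.max_iter = max_iter;
  o.tol = tol;
  o.tau_min = 0.01;
  o.tau_max = 12.5;
  o.k0 = 0; o.k1 = 0;
  return o;
}

// [[Rcpp::export]]
NumericVector fit_decay_cpp(NumericVector decay, NumericVector irf, double dt,
                            bool fit_shift, double shift_bound,
                            int max_iter, double tol) {
  arma::vec d = as<arma::vec>(decay);
  arma::vec f = as<arma::vec>(irf);
  int mode = f.index_max();
  FitOpts o = make_opts(dt, fit_shift, shift_bound, max_iter, tol);
  return result_to_vector(fit_one(d, f, mode, o));
}

// decays: n_pixels x n_bins; returns n_pixels x 12 parameter matrix
// [[Rcpp::export]]
NumericMatrix fit_decays_cpp(NumericMatrix decays, NumericVector irf, double dt,
                             bool fit_shift, double shift_bound,
                             int max_iter, double tol) {
  const int np = decays.nrow(), nb = decays.ncol();
  arma::vec f = as<arma::vec>(irf);
  int mode = f.index_max();
  FitOpts o = make_opts(dt, fit_shift, shift_bound, max_iter, tol);

  NumericMatrix out(np, 12);
  CharacterVector cn = CharacterVector::create(
      "tau1", "tau2", "a1", "a2", "a1_pct", "tau_m", "chi2", "offset",
      "shift", "converged", "iterations", "n_components");
  colnames(out) = cn;
  arma::vec d(nb);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < nb; ++k) d[k] = decays(i, k);
    if (arma::accu(d) <= 0) {
      for (int j = 0; j < 12; ++j) out(i, j) = NA_REAL;
      continue;
    }
    NumericVector v = result_to_vector(fit_one(d, f, mode, o));
    for (int j = 0; j < 12; ++j) out(i, j) = v[j];
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
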