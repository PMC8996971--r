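#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

// Family codes shared with R/families.R:
//   0 binomial, 1 betabinomial, 2 poisson, 3 genpois, 4 nb1, 5 nb2.
// Logit families (0, 1) take eta on the log-odds scale and ignore the offset;
// log-link count families (2-5) have mean exp(eta + offset).

static inline double inv_logit(double eta) {
  if (eta > 0) return 1.0 / (1.0 + std::exp(-eta));
  double e = std::exp(eta);
  return e / (1.0 + e);
}

// log-pmf of one observation together with first and second derivatives with
// respect to the linear predictor eta. d1/d2 may be NULL when only the value
// is needed.
// `cst` excludes the theta-independent combinatorial constant (lchoose for
// the logit families, -lgamma(k+1) for the count families): the Laplace hot
// path drops it and the caller adds the precomputed sum back once.
// `val` skips the log-likelihood value itself (returning 0) when only the
// eta-derivatives are needed, saving the lgamma calls in the Newton loop.
static double ll_eta(int fam, double k, double m, double eta, double off,
                     double disp, double *d1, double *d2, bool cst = true,
                     bool val = true) {
  switch (fam) {
  case 0: { // binomial, logit link
    double p = inv_logit(eta);
    double ll = 0.0;
    if (val) {
      ll = k * eta - m * Rf_log1pexp(eta);
      if (cst) ll += R::lchoose(m, k);
    }
    if (d1) { *d1 = k - m * p; *d2 = -m * p * (1.0 - p); }
    return ll;
  }
  case 1: { // beta-binomial, logit link, shapes a = p*phi, b = (1-p)*phi
    double p = inv_logit(eta);
    double phi = disp;
    double a = p * phi, b = (1.0 - p) * phi;
    // guard against underflow of a shape parameter at extreme eta
    if (a < 1e-12) a = 1e-12;
    if (b < 1e-12) b = 1e-12;
    double ll = 0.0;
    if (val) {
      ll = std::lgamma(k + a) + std::lgamma(m - k + b)
        - std::lgamma(m + phi) - std::lgamma(a) - std::lgamma(b)
        + std::lgamma(phi);
      if (cst) ll += R::lchoose(m, k);
    }
    if (d1) {
      double w = phi * p * (1.0 - p);
      double D = R::digamma(k + a) - R::digamma(a)
        - (R::digamma(m - k + b) - R::digamma(b));
      double T = R::trigamma(k + a) - R::trigamma(a)
        + R::trigamma(m - k + b) - R::trigamma(b);
      *d1 = w * D;
      *d2 = w * (1.0 - 2.0 * p) * D + w * w * T;
    }
    return ll;
  }
  case 2: { // poisson, log link
    double lp = eta + off, mu = std::exp(lp);
    double ll = 0.0;
    if (val) {
      ll = k * lp - mu;
      if (cst) ll -= std::lgamma(k + 1.0);
    }
    if (d1) { *d1 = k - mu; *d2 = -mu; }
    return ll;
  }
  case 3: { // generalized poisson, variance = mu * phi, phi >= 1
    double mu = std::exp(eta + off);
    double s = std::sqrt(disp);
    double th = mu / s, lam = 1.0 - 1.0 / s;
    double denom = th + lam * k;
    double ll = 0.0;
    if (val) {
      ll = std::log(th) + (k - 1.0) * std::log(denom) - th - lam * k;
      if (cst) ll -= std::lgamma(k + 1.0);
    }
    if (d1) {
      double r = th * (k - 1.0) / denom;
      *d1 = 1.0 + r - th;
      *d2 = r - th * r / denom - th;
    }
    return ll;
  }
  case 4: { // NB1: variance = mu * (1 + alpha); size r = mu/alpha
    double mu = std::exp(eta + off);
    double alpha = disp;
    double r = mu / alpha;
    double l1a = std::log1p(alpha);
    double ll = 0.0;
    if (val) {
      ll = std::lgamma(k + r) - std::lgamma(r)
        - r * l1a + k * (std::log(alpha) - l1a);
      if (cst) ll -= std::lgamma(k + 1.0);
    }
    if (d1) {
      double D = R::digamma(k + r) - R::digamma(r) - l1a;
      *d1 = r * D;
      *d2 = r * D + r * r * (R::trigamma(k + r) - R::trigamma(r));
    }
    return ll;
  }
  case 5: { // NB2: variance = mu + mu^2/theta; size theta
    double mu = std::exp(eta + off);
    double th = disp;
    double ll = 0.0;
    if (val) {
      ll = std::lgamma(k + th) - std::lgamma(th)
        + th * std::log(th / (th + mu));
      if (cst) ll -= std::lgamma(k + 1.0);
      if (k > 0) ll += k * std::log(mu / (th + mu));
    }
    if (d1) {
      *d1 = k - mu * (k + th) / (th + mu);
      *d2 = -(k + th) * mu * th / ((th + mu) * (th + mu));
    }
    return ll;
  }
  }
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector logpmf_eta_cpp(int fam, NumericVector k, NumericVector m,
                             NumericVector eta, NumericVector off, double disp) {
  R_xlen_t n = k.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double e = eta.size() == 1 ? eta[0] : eta[i];
    double o = off.size() == 1 ? off[0] : off[i];
    double mm = m.size() == 1 ? m[0] : m[i];
    out[i] = ll_eta(fam, k[i], mm, e, o, disp, nullptr, nullptr);
  }
  return out;
}

// Laplace-approximated marginal log-likelihood for the nested-random-intercept
// model. Rows must be sorted by individual then by sample within individual.
//
//   ind_start   0-based row offsets per individual, length n_ind + 1
//   samp_of_row 0-based sample index within the row's individual
//   n_samp      number of samples per individual
//   modes       warm-start cache, length sum_i (1 + n_samp[i]); updated in
//               place (pass a vector created in R and kept across calls)
//
// Per individual the joint mode of (u, v_1..v_J) is found by damped Newton
// iterations on the negative joint log-density; the Hessian has arrow
// structure (u borders a diagonal v-block) and is solved in O(J).
// [[Rcpp::export]]
List laplace_loglik_cpp(NumericVector beta, double sd_u, double sd_v,
                        double disp, int fam, NumericMatrix X,
                        NumericVector off, NumericVector k, NumericVector m,
                        NumericVector w,
                        IntegerVector ind_start, IntegerVector samp_of_row,
                        IntegerVector n_samp, bool has_u, bool has_v,
                        NumericVector modes) {
  const int n_ind = n_samp.size();
  const int p = X.ncol();
  const R_xlen_t n = k.size();

  // fixed-effect part of the linear predictor
  std::vector<double> xb(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    double acc = 0.0;
    for (int j = 0; j < p; ++j) acc += X(r, j) * beta[j];
    xb[r] = acc;
  }

  const double su2 = sd_u * sd_u, sv2 = sd_v * sd_v;
  double total = 0.0;
  int n_fail = 0;
  int mode_off = 0;

  for (int i = 0; i < n_ind; ++i) {
    const int J = n_samp[i];
    const int r0 = ind_start[i], r1 = ind_start[i + 1];
    const int dim = (has_u ? 1 : 0) + (has_v ? J : 0);

    if (dim == 0) { // pure fixed-effects likelihood
      for (int r = r0; r < r1; ++r)
        total += w[r] * ll_eta(fam, k[r], m[r], xb[r], off[r], disp, nullptr, nullptr, false);
      mode_off += 1 + J;
      continue;
    }

    double u = has_u ? modes[mode_off] : 0.0;
    std::vector<double> v(J, 0.0);
    if (has_v) for (int j = 0; j < J; ++j) v[j] = modes[mode_off + 1 + j];

    std::vector<double> gs(J), W(J), gv(J), dv(J);
    double ll = 0.0, quad = 0.0, logdet = 0.0;
    bool ok = false;

    auto objective = [&](double uu, const std::vector<double> &vv) {
      double s = 0.0;
      for (int r = r0; r < r1; ++r) {
        double e = xb[r] + (has_u ? uu : 0.0) + (has_v ? vv[samp_of_row[r]] : 0.0);
        s -= w[r] * ll_eta(fam, k[r], m[r], e, off[r], disp, nullptr, nullptr, false);
      }
      if (has_u) s += uu * uu / (2.0 * su2);
      if (has_v) for (int j = 0; j < J; ++j) s += vv[j] * vv[j] / (2.0 * sv2);
      return s;
    };

    double f = objective(u, v);
    double last_dec = R_PosInf;
    int q_iter = 0; // consecutive full-Newton (quadratic-basin) steps
    for (int it = 0; it < 60; ++it) {
      // gradient and per-sample curvature at current point
      std::fill(gs.begin(), gs.end(), 0.0);
      std::fill(W.begin(), W.end(), 0.0);
      for (int r = r0; r < r1; ++r) {
        int s = samp_of_row[r];
        double e = xb[r] + (has_u ? u : 0.0) + (has_v ? v[s] : 0.0);
        double d1, d2;
        ll_eta(fam, k[r], m[r], e, off[r], disp, &d1, &d2, false, false);
        gs[s] += w[r] * d1;
        W[s] -= w[r] * d2;
      }
      double gu = 0.0, sumW = 0.0;
      for (int j = 0; j < J; ++j) sumW += W[j];
      if (has_u) gu = -std::accumulate(gs.begin(), gs.end(), 0.0) + u / su2;
      double gmax = has_u ? std::fabs(gu) : 0.0;
      if (has_v)
        for (int j = 0; j < J; ++j) {
          gv[j] = -gs[j] + v[j] / sv2;
          gmax = std::max(gmax, std::fabs(gv[j]));
        }

      if (gmax < 1e-8 || !std::isfinite(f)) {
        ok = std::isfinite(f);
        break;
      }

      // damped Newton step with ridge escalation on indefiniteness
      double du = 0.0;
      bool solved = false;
      for (double ridge = 0.0; ridge < 1e8; ridge = (ridge == 0.0 ? 1e-6 : ridge * 100.0)) {
        bool pd = true;
        double c = sumW + (has_u ? 1.0 / su2 : 0.0) + ridge;
        double schur = c;
        for (int j = 0; j < J && has_v; ++j) {
          double Dj = W[j] + 1.0 / sv2 + ridge;
          if (Dj <= 1e-12) { pd = false; break; }
          if (has_u) schur -= W[j] * W[j] / Dj;
        }
        if (!pd) continue;
        if (has_u && schur <= 1e-12) continue;
        if (has_u && has_v) {
          double acc = 0.0;
          for (int j = 0; j < J; ++j) acc += W[j] * gv[j] / (W[j] + 1.0 / sv2 + ridge);
          du = (-gu + acc) / schur;
          for (int j = 0; j < J; ++j)
            dv[j] = (-gv[j] - W[j] * du) / (W[j] + 1.0 / sv2 + ridge);
        } else if (has_u) {
          du = -gu / schur;
        } else {
          for (int j = 0; j < J; ++j) dv[j] = -gv[j] / (W[j] + 1.0 / sv2 + ridge);
        }
        solved = true;
        break;
      }
      if (!solved) break;

      // Newton decrement: scale-invariant convergence measure that stays
      // meaningful when a tiny random-effect SD makes the gradient scale
      // explode (prior precision 1/sd^2). The mode must be resolved to
      // near machine precision or finite-difference Hessians of the outer
      // objective pick up cache-dependent noise.
      double dec = 0.0;
      if (has_u) dec -= gu * du;
      if (has_v) for (int j = 0; j < J; ++j) dec -= gv[j] * dv[j];
      // The log-determinant term of the Laplace value depends on the mode
      // to FIRST order, so the mode must be pushed to near machine
      // precision or finite differences of the outer objective inherit
      // noise; the decrement floor set by gradient rounding is far below
      // this tolerance.
      bool stalled = dec > 0.5 * last_dec;
      last_dec = dec;
      if (dec < 1e-15 || (stalled && dec < 1e-8)) { ok = true; break; }

      if (dec < 1e-4) {
        // quadratic basin: full Newton step, no objective-based test (its
        // resolution is too coarse this close to the mode)
        if (++q_iter > 40) {
          ok = dec < 1e-8;
          break;
        }
        u += du;
        if (has_v) for (int j = 0; j < J; ++j) v[j] += dv[j];
        continue;
      }
      q_iter = 0;
      f = objective(u, v); // refresh: line search below compares against it

      // backtracking line search
      double step = 1.0;
      bool improved = false;
      for (int h = 0; h < 40; ++h) {
        double ut = u + step * du;
        std::vector<double> vt(v);
        if (has_v) for (int j = 0; j < J; ++j) vt[j] = v[j] + step * dv[j];
        double ft = objective(ut, vt);
        if (std::isfinite(ft) && ft < f - 1e-14) {
          u = ut; v = vt; f = ft; improved = true;
          break;
        }
        step *= 0.5;
      }
      if (!improved) {
        ok = last_dec < 1e-8 && std::isfinite(f);
        break;
      }
    }

    if (!ok) ok = last_dec < 1e-8 && std::isfinite(f);

    if (!ok) {
      ++n_fail;
      mode_off += 1 + J;
      continue;
    }

    // curvature and log-determinant at the mode
    std::fill(W.begin(), W.end(), 0.0);
    ll = 0.0;
    for (int r = r0; r < r1; ++r) {
      int s = samp_of_row[r];
      double e = xb[r] + (has_u ? u : 0.0) + (has_v ? v[s] : 0.0);
      double d1, d2;
      ll += w[r] * ll_eta(fam, k[r], m[r], e, off[r], disp, &d1, &d2, false);
      W[s] -= w[r] * d2;
    }
    double sumW = 0.0;
    for (int j = 0; j < J; ++j) sumW += W[j];
    logdet = 0.0;
    if (has_u && has_v) {
      double c = sumW + 1.0 / su2, schur = c;
      for (int j = 0; j < J; ++j) {
        double Dj = W[j] + 1.0 / sv2;
        if (Dj <= 0.0) { ok = false; break; }
        logdet += std::log(Dj);
        schur -= W[j] * W[j] / Dj;
      }
      if (ok && schur > 0.0) logdet += std::log(schur); else ok = false;
    } else if (has_u) {
      double c = sumW + 1.0 / su2;
      if (c > 0.0) logdet = std::log(c); else ok = false;
    } else {
      for (int j = 0; j < J; ++j) {
        double Dj = W[j] + 1.0 / sv2;
        if (Dj <= 0.0) { ok = false; break; }
        logdet += std::log(Dj);
      }
    }
    if (!ok) {
      ++n_fail;
      mode_off += 1 + J;
      continue;
    }

    quad = 0.0;
    if (has_u) quad += u * u / (2.0 * su2);
    if (has_v) for (int j = 0; j < J; ++j) quad += v[j] * v[j] / (2.0 * sv2);

    double prior_norm = 0.0;
    if (has_u) prior_norm += std::log(su2);
    if (has_v) prior_norm += J * std::log(sv2);

    total += ll - quad - 0.5 * prior_norm - 0.5 * logdet;

    if (has_u) modes[mode_off] = u;
    if (has_v) for (int j = 0; j < J; ++j) modes[mode_off + 1 + j] = v[j];
    mode_off += 1 + J;
  }

  if (n_fail > 0) total = R_NegInf;
  return List::create(Named("loglik") = total, Named("n_fail") = n_fail);
}
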