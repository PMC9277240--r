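// EM machinery for negative-binomial mixtures and NB-emission hidden
// Markov models. These run inside every likelihood evaluation of the
// synthetic-model surrogate (refit at each MCMC proposal), hence C++.
//
// Parameterization: NB(r, p) with pmf Gamma(x+r)/(Gamma(r) x!) p^r (1-p)^x,
// mean mu = r(1-p)/p, variance mu + mu^2/r (Fano factor 1 + mu/r > 1).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

const double R_MIN = 1e-3, R_MAX = 1e4;

inline double nb_logpmf(double x, double r, double p) {
  return R::lgammafn(x + r) - R::lgammafn(r) - R::lgammafn(x + 1.0) +
         r * std::log(p) + x * std::log1p(-p);
}

// Weighted NB maximum likelihood: p profiled out via p = r / (r + mu),
// r by safeguarded Newton on the profile score in log(r). Counts are
// small integers, so weights are first aggregated per distinct value,
// which makes each digamma/trigamma pass O(#distinct) not O(n).
void weighted_nb_fit(const double *x0, const double *w0, int n0, double rInit,
                     double &rOut, double &pOut) {
  double xmax = 0.0;
  for (int i = 0; i < n0; ++i) if (x0[i] > xmax) xmax = x0[i];
  std::vector<double> xs, ws;
  const double *x = x0, *w = w0;
  int n = n0;
  if (xmax <= 65536.0) {
    std::vector<double> agg(static_cast<int>(xmax) + 1, 0.0);
    for (int i = 0; i < n0; ++i) agg[static_cast<int>(x0[i])] += w0[i];
    for (int v = 0; v <= static_cast<int>(xmax); ++v)
      if (agg[v] > 0.0) { xs.push_back(v); ws.push_back(agg[v]); }
    x = xs.data(); w = ws.data(); n = static_cast<int>(xs.size());
  }
  double W = 0.0, sx = 0.0;
  for (int i = 0; i < n; ++i) { W += w[i]; sx += w[i] * x[i]; }
  if (W <= 0.0) { rOut = 1.0; pOut = 0.5; return; }
  double mu = sx / W;
  if (mu < 1e-10) mu = 1e-10;
  double sv = 0.0;
  for (int i = 0; i < n; ++i) sv += w[i] * (x[i] - mu) * (x[i] - mu);
  double var = sv / W;
  if (var <= mu * (1.0 + 1e-12)) { // at/below Poisson dispersion: clamp
    rOut = R_MAX;
    pOut = R_MAX / (R_MAX + mu);
    return;
  }
  double r = rInit > 0 ? rInit : mu * mu / (var - mu);
  if (r < R_MIN) r = R_MIN;
  if (r > R_MAX) r = R_MAX;
  double lo = std::log(R_MIN), hi = std::log(R_MAX), t = std::log(r);
  for (int it = 0; it < 60; ++it) {
    r = std::exp(t);
    double s = W * std::log(r / (r + mu));
    double ds = W * mu / (r * (r + mu));
    for (int i = 0; i < n; ++i) {
      if (w[i] == 0.0) continue;
      s += w[i] * (R::digamma(x[i] + r) - R::digamma(r));
      ds += w[i] * (R::trigamma(x[i] + r) - R::trigamma(r));
    }
    if (s > 0.0) lo = t; else hi = t; // score decreasing in r
    double g = r * ds; // d score / d log r
    double step = (g < 0.0) ? -s / g : NA_REAL;
    double tNew = t + (R_finite(step) ? step : 0.0);
    if (!R_finite(tNew) || tNew <= lo || tNew >= hi) tNew = 0.5 * (lo + hi);
    if (std::fabs(tNew - t) < 1e-11 || std::fabs(s) < 1e-10 * (W + 1.0)) {
      t = tNew;
      break;
    }
    t = tNew;
  }
  rOut = std::exp(t);
  pOut = rOut / (rOut + mu);
  // generalized-EM guard: the profile score can have several roots for
  // awkward weight configurations; never accept a candidate that is worse
  // than the warm start (keeps Baum-Welch monotone)
  if (rInit > 0.0) {
    auto profll = [&](double rr) {
      double ll = W * rr * std::log(rr / (rr + mu)) -
                  sx * std::log(rr + mu);
      for (int i = 0; i < n; ++i)
        if (w[i] > 0.0)
          ll += w[i] * (R::lgammafn(x[i] + rr) - R::lgammafn(rr));
      return ll;
    };
    double rPrev = std::min(std::max(rInit, R_MIN), R_MAX);
    if (profll(rPrev) > profll(rOut)) {
      rOut = rPrev;
      pOut = rOut / (rOut + mu);
    }
  }
}

inline double logsumexp_row(const double *v, int K) {
  double m = v[0];
  for (int k = 1; k < K; ++k) if (v[k] > m) m = v[k];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

} // namespace

// [[Rcpp::export(name = ".cpp_nb_fit")]]
NumericVector cpp_nb_fit(NumericVector x, NumericVector w, double rInit) {
  double r, p;
  weighted_nb_fit(x.begin(), w.begin(), x.size(), rInit, r, p);
  return NumericVector::create(r, p);
}

// EM for a K-component mixture of product-NB distributions over S species.
// X: n x S counts; returns weights, r (K x S), p (K x S), loglik trace.
// [[Rcpp::export(name = ".cpp_mnb_em")]]
List cpp_mnb_em(NumericMatrix X, NumericVector w0, NumericMatrix r0,
                NumericMatrix p0, int maxIter, double tol,
                double weightFloor) {
  const int n = X.nrow(), S = X.ncol(), K = w0.size();
  NumericVector w = clone(w0);
  NumericMatrix r = clone(r0), p = clone(p0);
  std::vector<double> logc(n * K), resp(n * K), buf(K), wk(n);
  std::vector<double> trace;
  double llOld = R_NegInf;
  for (int iter = 0; iter < maxIter; ++iter) {
    // E-step
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) {
        double lp = std::log(w[k]);
        for (int s = 0; s < S; ++s)
          lp += nb_logpmf(X(i, s), r(k, s), p(k, s));
        buf[k] = lp;
      }
      double lse = logsumexp_row(buf.data(), K);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[i + n * k] = std::exp(buf[k] - lse);
    }
    trace.push_back(ll);
    if (R_finite(llOld) &&
        std::fabs(ll - llOld) < tol * (std::fabs(llOld) + 1.0)) break;
    llOld = ll;
    // M-step
    double wTot = 0.0;
    for (int k = 0; k < K; ++k) {
      double sk = 0.0;
      for (int i = 0; i < n; ++i) sk += resp[i + n * k];
      w[k] = std::max(sk / n, weightFloor);
      wTot += w[k];
    }
    for (int k = 0; k < K; ++k) w[k] /= wTot;
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) wk[i] = resp[i + n * k];
      for (int s = 0; s < S; ++s) {
        double rr, pp;
        std::vector<double> xs(n);
        for (int i = 0; i < n; ++i) xs[i] = X(i, s);
        weighted_nb_fit(xs.data(), wk.data(), n, r(k, s), rr, pp);
        r(k, s) = rr;
        p(k, s) = pp;
      }
    }
  }
  return List::create(_["weights"] = w, _["r"] = r, _["p"] = p,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Forward algorithm (scaled) for NB-emission HMMs on a shared time grid.
// X: n x T x S counts; pi: K; trans: (T-1) x K x K (row-stochastic slices,
// trans[t, i, j] = P(z_{t+1}=j | z_t=i)); r, p: T x K x S.
// Returns per-cell log-likelihoods.
// [[Rcpp::export(name = ".cpp_forward_loglik")]]
NumericVector cpp_forward_loglik(NumericVector X, NumericVector pi,
                                 NumericVector trans, NumericVector r,
                                 NumericVector p) {
  IntegerVector dim = X.attr("dim");
  const int n = dim[0], T = dim[1], S = dim[2];
  const int K = pi.size();
  const int TM = T - 1;
  NumericVector out(n);
  std::vector<double> logb(K), alpha(K), tmp(K);
  for (int i = 0; i < n; ++i) {
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lb = 0.0;
        for (int s = 0; s < S; ++s)
          lb += nb_logpmf(X[i + n * (t + T * s)], r[t + T * (k + K * s)],
                          p[t + T * (k + K * s)]);
        logb[k] = lb;
        if (lb > m) m = lb;
      }
      if (t == 0) {
        for (int k = 0; k < K; ++k) alpha[k] = pi[k] * std::exp(logb[k] - m);
      } else {
        for (int k = 0; k < K; ++k) {
          double s2 = 0.0;
          for (int j = 0; j < K; ++j)
            s2 += tmp[j] * trans[(t - 1) + TM * (j + K * k)];
          alpha[k] = s2 * std::exp(logb[k] - m);
        }
      }
      double c = 0.0;
      for (int k = 0; k < K; ++k) c += alpha[k];
      if (c <= 0.0 || !R_finite(c)) { ll = R_NegInf; break; }
      for (int k = 0; k < K; ++k) tmp[k] = alpha[k] / c;
      ll += std::log(c) + m;
    }
    out[i] = ll;
  }
  return out;
}

// Baum-Welch for time-inhomogeneous NB-emission HMMs (optionally tied
// transitions/emissions across time). X: n x T x S.
// [[Rcpp::export(name = ".cpp_baum_welch")]]
List cpp_baum_welch(NumericVector X, NumericVector pi0, NumericVector trans0,
                    NumericVector r0, NumericVector p0, int maxIter,
                    double tol, double weightFloor, bool tiedTrans,
                    bool tiedEmis) {
  IntegerVector dim = X.attr("dim");
  const int n = dim[0], T = dim[1], S = dim[2];
  const int K = pi0.size();
  const int TM = std::max(T - 1, 1);
  NumericVector pi = clone(pi0), trans = clone(trans0), r = clone(r0),
                p = clone(p0);
  // workspaces
  std::vector<double> logb(n * T * K), scal(n * T), mrow(K);
  std::vector<double> alpha(n * T * K), beta(n * T * K);
  std::vector<double> gamma(n * T * K), xi(TM * K * K);
  std::vector<double> trace;
  double llOld = R_NegInf;
  NumericVector cellLL(n);

  // counts are small integers: precompute per-(t,s) the distinct values so
  // emission log-pmfs are evaluated once per distinct value, not per cell
  double xmaxAll = 0.0;
  for (int i = 0; i < n * T * S; ++i) if (X[i] > xmaxAll) xmaxAll = X[i];
  const bool bucket = xmaxAll + 1 <= std::min(65536.0, 2.0 * n + 64.0);
  const int nv = bucket ? static_cast<int>(xmaxAll) + 1 : 0;
  std::vector<double> lut(bucket ? nv : 0);

  for (int iter = 0; iter < maxIter; ++iter) {
    // emission log-probs
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        if (bucket) {
          for (int s = 0; s < S; ++s) {
            double rr = r[t + T * (k + K * s)], pp = p[t + T * (k + K * s)];
            double base = rr * std::log(pp) - R::lgammafn(rr);
            double l1p = std::log1p(-pp);
            for (int v = 0; v < nv; ++v)
              lut[v] = R::lgammafn(v + rr) - R::lgammafn(v + 1.0) + base +
                       v * l1p;
            if (s == 0)
              for (int i = 0; i < n; ++i)
                logb[i + n * (t + T * k)] =
                    lut[static_cast<int>(X[i + n * t])];
            else
              for (int i = 0; i < n; ++i)
                logb[i + n * (t + T * k)] +=
                    lut[static_cast<int>(X[i + n * (t + T * s)])];
          }
        } else {
          for (int i = 0; i < n; ++i) {
            double lb = 0.0;
            for (int s = 0; s < S; ++s)
              lb += nb_logpmf(X[i + n * (t + T * s)], r[t + T * (k + K * s)],
                              p[t + T * (k + K * s)]);
            logb[i + n * (t + T * k)] = lb;
          }
        }
      }
    // scaled forward
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double lli = 0.0;
      for (int t = 0; t < T; ++t) {
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          double lb = logb[i + n * (t + T * k)];
          if (lb > m) m = lb;
        }
        double c = 0.0;
        for (int k = 0; k < K; ++k) {
          double b = std::exp(logb[i + n * (t + T * k)] - m);
          double a;
          if (t == 0) a = pi[k] * b;
          else {
            double s2 = 0.0;
            for (int j = 0; j < K; ++j)
              s2 += alpha[i + n * ((t - 1) + T * j)] *
                    trans[(t - 1) + TM * (j + K * k)];
            a = s2 * b;
          }
          alpha[i + n * (t + T * k)] = a;
          c += a;
        }
        if (c <= 0.0 || !R_finite(c)) { lli = R_NegInf; c = 1.0; }
        scal[i + n * t] = c;
        for (int k = 0; k < K; ++k) alpha[i + n * (t + T * k)] /= c;
        if (R_finite(lli)) lli += std::log(c) + m;
      }
      cellLL[i] = lli;
      ll += lli;
    }
    trace.push_back(ll);
    if (R_finite(llOld) &&
        std::fabs(ll - llOld) < tol * (std::fabs(llOld) + 1.0)) break;
    llOld = ll;
    // scaled backward + xi accumulation
    std::fill(xi.begin(), xi.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) beta[i + n * ((T - 1) + T * k)] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          double lb = logb[i + n * ((t + 1) + T * k)];
          if (lb > m) m = lb;
        }
        double c = scal[i + n * (t + 1)];
        for (int k = 0; k < K; ++k) {
          double s2 = 0.0;
          for (int j = 0; j < K; ++j)
            s2 += trans[t + TM * (k + K * j)] *
                  std::exp(logb[i + n * ((t + 1) + T * j)] - m) *
                  beta[i + n * ((t + 1) + T * j)];
          beta[i + n * (t + T * k)] = s2 / c;
        }
        // scal[t+1] was computed on the same exp(logb - m) convention in
        // the forward pass, so gamma = alpha * beta without rescaling.
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < K; ++j)
            xi[t + TM * (k + K * j)] +=
                alpha[i + n * (t + T * k)] * trans[t + TM * (k + K * j)] *
                std::exp(logb[i + n * ((t + 1) + T * j)] - m) *
                beta[i + n * ((t + 1) + T * j)] / c;
      }
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < K; ++k)
          gamma[i + n * (t + T * k)] =
              alpha[i + n * (t + T * k)] * beta[i + n * (t + T * k)];
    }
    // M-step: initial distribution
    for (int k = 0; k < K; ++k) {
      double s2 = 0.0;
      for (int i = 0; i < n; ++i) s2 += gamma[i + n * (0 + T * k)];
      pi[k] = std::max(s2 / n, weightFloor);
    }
    double piTot = 0.0;
    for (int k = 0; k < K; ++k) piTot += pi[k];
    for (int k = 0; k < K; ++k) pi[k] /= piTot;
    // transitions
    if (T > 1) {
      if (tiedTrans) {
        for (int k = 0; k < K; ++k) {
          std::vector<double> row(K, 0.0);
          double tot = 0.0;
          for (int j = 0; j < K; ++j)
            for (int t = 0; t < T - 1; ++t) {
              row[j] += xi[t + TM * (k + K * j)];
            }
          for (int j = 0; j < K; ++j) tot += row[j];
          for (int t = 0; t < T - 1; ++t)
            for (int j = 0; j < K; ++j)
              trans[t + TM * (k + K * j)] =
                  tot > 0 ? std::max(row[j] / tot, weightFloor) : 1.0 / K;
        }
      } else {
        for (int t = 0; t < T - 1; ++t)
          for (int k = 0; k < K; ++k) {
            double tot = 0.0;
            for (int j = 0; j < K; ++j) tot += xi[t + TM * (k + K * j)];
            for (int j = 0; j < K; ++j)
              trans[t + TM * (k + K * j)] =
                  tot > 0 ? std::max(xi[t + TM * (k + K * j)] / tot,
                                     weightFloor)
                          : 1.0 / K;
          }
      }
      // renormalize rows after flooring
      for (int t = 0; t < T - 1; ++t)
        for (int k = 0; k < K; ++k) {
          double tot = 0.0;
          for (int j = 0; j < K; ++j) tot += trans[t + TM * (k + K * j)];
          for (int j = 0; j < K; ++j) trans[t + TM * (k + K * j)] /= tot;
        }
    }
    // emissions: weighted NB fits per (time, state, species)
    std::vector<double> wts(tiedEmis ? n * T : n), xs(tiedEmis ? n * T : n);
    for (int k = 0; k < K; ++k) {
      if (tiedEmis) {
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < n; ++i)
            wts[i + n * t] = gamma[i + n * (t + T * k)];
        for (int s = 0; s < S; ++s) {
          for (int t = 0; t < T; ++t)
            for (int i = 0; i < n; ++i)
              xs[i + n * t] = X[i + n * (t + T * s)];
          double rr, pp;
          weighted_nb_fit(xs.data(), wts.data(), n * T, r[0 + T * (k + K * s)],
                          rr, pp);
          for (int t = 0; t < T; ++t) {
            r[t + T * (k + K * s)] = rr;
            p[t + T * (k + K * s)] = pp;
          }
        }
      } else {
        for (int t = 0; t < T; ++t) {
          double mass = 0.0;
          for (int i = 0; i < n; ++i) {
            wts[i] = gamma[i + n * (t + T * k)];
            mass += wts[i];
          }
          if (mass < 1e-8 * n) continue; // starved state: keep previous fit
          for (int s = 0; s < S; ++s) {
            for (int i = 0; i < n; ++i) xs[i] = X[i + n * (t + T * s)];
            double rr, pp;
            weighted_nb_fit(xs.data(), wts.data(), n, r[t + T * (k + K * s)],
                            rr, pp);
            r[t + T * (k + K * s)] = rr;
            p[t + T * (k + K * s)] = pp;
          }
        }
      }
    }
  }
  return List::create(_["pi"] = pi, _["trans"] = trans, _["r"] = r,
                      _["p"] = p,
                      _["trace"] =
                          NumericVector(trace.begin(), trace.end()),
                      _["cell_loglik"] = cellLL);
}
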