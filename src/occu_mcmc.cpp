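// Marginal likelihoods (latent occupancy states summed out analytically) and
// adaptive random-walk Metropolis-within-Gibbs samplers for the hierarchical
// single-scale and multi-scale occupancy models.
//
// Array layout (row-major flattening of [unit i, year j, plot k, visit l]):
//   cell  c = (i*J + j)*K + k          -- plot-year cell, ncell = I*J*K
//   visit v = c*L + l                  -- ncell*L visit slots
//   unit-year c2 = i*J + j             -- multi-scale occupancy cell
#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1p_exp(double x) {
  if (x <= -37.0) return std::exp(x);
  if (x <= 18.0)  return std::log1p(std::exp(x));
  if (x <= 33.3)  return x + std::exp(-x);
  return x;
}
static inline double log_plogis(double x)   { return -log1p_exp(-x); } // log p
static inline double log1m_plogis(double x) { return -log1p_exp(x);  } // log(1-p)

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// conditional detection log-likelihood of one plot-year cell given occupancy,
// plus the "no observed detection" flag; missing visits contribute factor 1
static void cell_det_loglik(const int *y, const int *miss, int L,
                            const double *det_lin, double &ld, bool &nodet) {
  ld = 0.0; nodet = true;
  for (int l = 0; l < L; ++l) {
    if (miss[l]) continue;
    if (y[l] == 1) {
      ld += log_plogis(det_lin[l]);
      nodet = false;
    } else {
      ld += log1m_plogis(det_lin[l]);
    }
  }
}

// marginal contribution of one plot-year cell: log[psi e^{ld} + (1-psi) I(nodet)]
static inline double cell_marginal(double eta_psi, double ld, bool nodet) {
  double a = log_plogis(eta_psi) + ld;
  if (!nodet) return a;
  return logsumexp2(a, log1m_plogis(eta_psi));
}

// ---------------------------------------------------------------------------
// single-scale model (also covers the empirical variant: arbitrary occupancy
// and detection design matrices)
// ---------------------------------------------------------------------------

struct SingleWork {
  int I, J, K, L, ncell, P, Q;
  const int *y, *miss;
  const double *Xpsi, *Xdet;              // column-major, ncell x P / nvisit x Q
  std::vector<double> psi_lin, det_lin;   // caches excluding b0
  std::vector<double> ld;                 // per-cell conditional detection loglik
  std::vector<char> nodet;

  void init(IntegerVector y_, LogicalVector miss_, int I_, int J_, int K_, int L_,
            NumericMatrix Xpsi_, NumericMatrix Xdet_) {
    I = I_; J = J_; K = K_; L = L_; ncell = I * J * K;
    P = Xpsi_.ncol(); Q = Xdet_.ncol();
    y = INTEGER(y_); miss = LOGICAL(miss_);
    Xpsi = REAL(Xpsi_); Xdet = REAL(Xdet_);
    psi_lin.assign(ncell, 0.0);
    det_lin.assign(ncell * L, 0.0);
    ld.assign(ncell, 0.0);
    nodet.assign(ncell, 1);
  }
  void set_psi_lin(const double *beta) {
    for (int c = 0; c < ncell; ++c) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) s += Xpsi[p * ncell + c] * beta[p];
      psi_lin[c] = s;
    }
  }
  void set_det_lin(const double *gamma) {
    int nv = ncell * L;
    for (int v = 0; v < nv; ++v) {
      double s = 0.0;
      for (int q = 0; q < Q; ++q) s += Xdet[q * nv + v] * gamma[q];
      det_lin[v] = s;
    }
    refresh_ld();
  }
  void refresh_ld() {
    for (int c = 0; c < ncell; ++c) {
      double d; bool nd;
      cell_det_loglik(y + c * L, miss + c * L, L, det_lin.data() + c * L, d, nd);
      ld[c] = d; nodet[c] = nd ? 1 : 0;
    }
  }
  // loglik of one unit given its random intercept
  double unit_loglik(int i, double b0i) const {
    double s = 0.0;
    int c0 = i * J * K, c1 = (i + 1) * J * K;
    for (int c = c0; c < c1; ++c)
      s += cell_marginal(psi_lin[c] + b0i, ld[c], nodet[c]);
    return s;
  }
  double total_loglik(const double *b0, std::vector<double> &ull) const {
    double s = 0.0;
    for (int i = 0; i < I; ++i) { ull[i] = unit_loglik(i, b0[i]); s += ull[i]; }
    return s;
  }
};

// [[Rcpp::export]]
double cpp_loglik_single(IntegerVector y, LogicalVector miss,
                         int I, int J, int K, int L,
                         NumericMatrix Xpsi, NumericMatrix Xdet,
                         NumericVector beta, NumericVector gamma,
                         NumericVector b0) {
  SingleWork w;
  w.init(y, miss, I, J, K, L, Xpsi, Xdet);
  w.set_psi_lin(REAL(beta));
  w.set_det_lin(REAL(gamma));
  std::vector<double> ull(I);
  return w.total_loglik(REAL(b0), ull);
}

// ---------------------------------------------------------------------------
// multi-scale model: unit-year occupancy z ~ Bern(theta), conditional plot
// occupancy psi and detection p constant on the logit scale
// ---------------------------------------------------------------------------

struct MultiWork {
  int I, J, K, L, nc2, P;
  const double *Xtheta;                 // nc2 x P column-major
  std::vector<double> theta_lin;
  std::vector<int> n1, n0;              // observed detections / non-detections per plot
  std::vector<double> m;                // per-plot mixture term given z = 1
  std::vector<char> nodet_plot, nodet_unit;

  void init(IntegerVector y_, LogicalVector miss_, int I_, int J_, int K_, int L_,
            NumericMatrix Xtheta_) {
    I = I_; J = J_; K = K_; L = L_; nc2 = I * J; P = Xtheta_.ncol();
    Xtheta = REAL(Xtheta_);
    theta_lin.assign(nc2, 0.0);
    int nplot = nc2 * K;
    n1.assign(nplot, 0); n0.assign(nplot, 0);
    m.assign(nplot, 0.0);
    nodet_plot.assign(nplot, 1); nodet_unit.assign(nc2, 1);
    const int *y = INTEGER(y_); const int *miss = LOGICAL(miss_);
    for (int pc = 0; pc < nplot; ++pc) {
      for (int l = 0; l < L; ++l) {
        int v = pc * L + l;
        if (miss[v]) continue;
        if (y[v] == 1) ++n1[pc]; else ++n0[pc];
      }
      nodet_plot[pc] = (n1[pc] == 0) ? 1 : 0;
    }
    for (int c2 = 0; c2 < nc2; ++c2) {
      bool nd = true;
      for (int k = 0; k < K; ++k) if (!nodet_plot[c2 * K + k]) nd = false;
      nodet_unit[c2] = nd ? 1 : 0;
    }
  }
  void set_theta_lin(const double *alpha) {
    for (int c = 0; c < nc2; ++c) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) s += Xtheta[p * nc2 + c] * alpha[p];
      theta_lin[c] = s;
    }
  }
  // plot mixture terms log[psi p^{n1}(1-p)^{n0} + (1-psi) I(n1==0)]
  void set_plot_terms(double lpsi, double lp) {
    double logp = log_plogis(lp), log1mp = log1m_plogis(lp);
    double logpsi = log_plogis(lpsi), log1mpsi = log1m_plogis(lpsi);
    int nplot = nc2 * K;
    for (int pc = 0; pc < nplot; ++pc) {
      double a = logpsi + n1[pc] * logp + n0[pc] * log1mp;
      m[pc] = nodet_plot[pc] ? logsumexp2(a, log1mpsi) : a;
    }
  }
  double unit_loglik(int i, double a0i) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) {
      int c2 = i * J + j;
      double sm = 0.0;
      for (int k = 0; k < K; ++k) sm += m[c2 * K + k];
      double eta = theta_lin[c2] + a0i;
      double a = log_plogis(eta) + sm;
      s += nodet_unit[c2] ? logsumexp2(a, log1m_plogis(eta)) : a;
    }
    return s;
  }
  double total_loglik(const double *a0, std::vector<double> &ull) const {
    double s = 0.0;
    for (int i = 0; i < I; ++i) { ull[i] = unit_loglik(i, a0[i]); s += ull[i]; }
    return s;
  }
};

// [[Rcpp::export]]
double cpp_loglik_multi(IntegerVector y, LogicalVector miss,
                        int I, int J, int K, int L,
                        NumericMatrix Xtheta, NumericVector alpha,
                        NumericVector a0, double lpsi, double lp) {
  MultiWork w;
  w.init(y, miss, I, J, K, L, Xtheta);
  w.set_theta_lin(REAL(alpha));
  w.set_plot_terms(lpsi, lp);
  std::vector<double> ull(I);
  return w.total_loglik(REAL(a0), ull);
}

// ---------------------------------------------------------------------------
// samplers
// ---------------------------------------------------------------------------

static inline double dnorm_log(double x, double mean, double var) {
  double z = x - mean;
  return -0.5 * std::log(2.0 * M_PI * var) - 0.5 * z * z / var;
}
// Gamma(shape, rate) log-density
static inline double dgamma_log(double x, double shape, double rate) {
  if (x <= 0) return R_NegInf;
  return shape * std::log(rate) - std::lgamma(shape) +
         (shape - 1.0) * std::log(x) - rate * x;
}

// Robbins-Monro style batch adaptation toward 0.44 acceptance (burn-in only)
struct Adapt {
  std::vector<double> lstep;
  std::vector<int> acc, tries;
  int batch;
  void init(int n, double step0) {
    lstep.assign(n, std::log(step0));
    acc.assign(n, 0); tries.assign(n, 0); batch = 0;
  }
  void maybe_adapt() {
    ++batch;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
    for (size_t j = 0; j < lstep.size(); ++j) {
      if (tries[j] == 0) continue;
      double rate = (double)acc[j] / tries[j];
      lstep[j] += (rate > 0.44 ? delta : -delta);
      acc[j] = 0; tries[j] = 0;
    }
  }
};

// [[Rcpp::export]]
List cpp_mcmc_single(IntegerVector y, LogicalVector miss,
                     int I, int J, int K, int L,
                     NumericMatrix Xpsi, NumericMatrix Xdet,
                     NumericVector beta_init, NumericVector gamma_init,
                     NumericVector b0_init, double sigma_init,
                     NumericVector beta_pm, NumericVector beta_pv,
                     NumericVector gamma_pm, NumericVector gamma_pv,
                     double sigma_shape, double sigma_rate,
                     int n_iter, int burnin, int thin,
                     LogicalVector update_beta, LogicalVector update_gamma,
                     bool update_b0, bool update_sigma) {
  SingleWork w;
  w.init(y, miss, I, J, K, L, Xpsi, Xdet);
  int P = w.P, Q = w.Q;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> gamma(gamma_init.begin(), gamma_init.end());
  std::vector<double> b0(b0_init.begin(), b0_init.end());
  double sigma = sigma_init;
  w.set_psi_lin(beta.data());
  w.set_det_lin(gamma.data());
  std::vector<double> ull(I), ull_prop(I);
  double ll = w.total_loglik(b0.data(), ull);
  if (!R_finite(ll)) stop("non-finite log-likelihood at initial values");

  int npar = P + Q + I + 1;
  int n_keep = (n_iter - burnin) / thin;
  NumericMatrix draws(n_keep, npar);
  Adapt ad; ad.init(npar, 0.5);
  std::vector<double> acc_post(npar, 0.0); int n_post = 0;
  std::vector<double> psi_lin_cur, det_lin_cur, ld_cur;
  std::vector<char> nodet_cur;
  int row = 0;

  for (int t = 1; t <= n_iter; ++t) {
    bool adapting = t <= burnin;
    // fixed effects: occupancy
    for (int p = 0; p < P; ++p) {
      if (!update_beta[p]) continue;
      double step = std::exp(ad.lstep[p]);
      double old = beta[p], prop = old + step * R::norm_rand();
      psi_lin_cur = w.psi_lin;
      double d = prop - old;
      for (int c = 0; c < w.ncell; ++c) w.psi_lin[c] += d * w.Xpsi[p * w.ncell + c];
      double llp = w.total_loglik(b0.data(), ull_prop);
      double lr = llp - ll + dnorm_log(prop, beta_pm[p], beta_pv[p]) -
                  dnorm_log(old, beta_pm[p], beta_pv[p]);
      ++ad.tries[p];
      if (std::log(R::unif_rand()) < lr) {
        beta[p] = prop; ll = llp; ull = ull_prop; ++ad.acc[p];
        if (!adapting) acc_post[p] += 1.0;
      } else {
        w.psi_lin = psi_lin_cur;
      }
    }
    // fixed effects: detection
    for (int q = 0; q < Q; ++q) {
      if (!update_gamma[q]) continue;
      int jj = P + q;
      double step = std::exp(ad.lstep[jj]);
      double old = gamma[q], prop = old + step * R::norm_rand();
      det_lin_cur = w.det_lin; ld_cur = w.ld; nodet_cur = w.nodet;
      double d = prop - old;
      int nv = w.ncell * L;
      for (int v = 0; v < nv; ++v) w.det_lin[v] += d * w.Xdet[q * nv + v];
      w.refresh_ld();
      double llp = w.total_loglik(b0.data(), ull_prop);
      double lr = llp - ll + dnorm_log(prop, gamma_pm[q], gamma_pv[q]) -
                  dnorm_log(old, gamma_pm[q], gamma_pv[q]);
      ++ad.tries[jj];
      if (std::log(R::unif_rand()) < lr) {
        gamma[q] = prop; ll = llp; ull = ull_prop; ++ad.acc[jj];
        if (!adapting) acc_post[jj] += 1.0;
      } else {
        w.det_lin = det_lin_cur; w.ld = ld_cur; w.nodet = nodet_cur;
      }
    }
    // unit random intercepts
    if (update_b0) {
      for (int i = 0; i < I; ++i) {
        int jj = P + Q + i;
        double step = std::exp(ad.lstep[jj]);
        double old = b0[i], prop = old + step * R::norm_rand();
        double uip = w.unit_loglik(i, prop);
        double lr = uip - ull[i] +
                    dnorm_log(prop, 0.0, sigma * sigma) -
                    dnorm_log(old, 0.0, sigma * sigma);
        ++ad.tries[jj];
        if (std::log(R::unif_rand()) < lr) {
          ll += uip - ull[i]; ull[i] = uip; b0[i] = prop; ++ad.acc[jj];
          if (!adapting) acc_post[jj] += 1.0;
        }
      }
    }
    // random-intercept SD, log-scale walk with Jacobian
    if (update_sigma) {
      int jj = npar - 1;
      double step = std::exp(ad.lstep[jj]);
      double prop = sigma * std::exp(step * R::norm_rand());
      double lr = dgamma_log(prop, sigma_shape, sigma_rate) -
                  dgamma_log(sigma, sigma_shape, sigma_rate) +
                  std::log(prop) - std::log(sigma);
      for (int i = 0; i < I; ++i)
        lr += dnorm_log(b0[i], 0.0, prop * prop) - dnorm_log(b0[i], 0.0, sigma * sigma);
      ++ad.tries[jj];
      if (std::log(R::unif_rand()) < lr) {
        sigma = prop; ++ad.acc[jj];
        if (!adapting) acc_post[jj] += 1.0;
      }
    }
    if (adapting) {
      if (t % 50 == 0) ad.maybe_adapt();
    } else {
      ++n_post;
      if ((t - burnin) % thin == 0 && row < n_keep) {
        for (int p = 0; p < P; ++p) draws(row, p) = beta[p];
        for (int q = 0; q < Q; ++q) draws(row, P + q) = gamma[q];
        for (int i = 0; i < I; ++i) draws(row, P + Q + i) = b0[i];
        draws(row, npar - 1) = sigma;
        ++row;
      }
    }
  }
  NumericVector acc_rate(npar);
  for (int j = 0; j < npar; ++j) acc_rate[j] = n_post > 0 ? acc_post[j] / n_post : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = acc_rate,
                      _["loglik"] = ll);
}

// [[Rcpp::export]]
List cpp_mcmc_multi(IntegerVector y, LogicalVector miss,
                    int I, int J, int K, int L,
                    NumericMatrix Xtheta,
                    NumericVector alpha_init, double lpsi_init, double lp_init,
                    NumericVector a0_init, double sigma_init,
                    NumericVector alpha_pm, NumericVector alpha_pv,
                    double lpsi_pm, double lpsi_pv, double lp_pm, double lp_pv,
                    double sigma_shape, double sigma_rate,
                    int n_iter, int burnin, int thin,
                    LogicalVector update_alpha, bool update_lpsi, bool update_lp,
                    bool update_a0, bool update_sigma) {
  MultiWork w;
  w.init(y, miss, I, J, K, L, Xtheta);
  int P = w.P;
  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<double> a0(a0_init.begin(), a0_init.end());
  double lpsi = lpsi_init, lp = lp_init, sigma = sigma_init;
  w.set_theta_lin(alpha.data());
  w.set_plot_terms(lpsi, lp);
  std::vector<double> ull(I), ull_prop(I);
  double ll = w.total_loglik(a0.data(), ull);
  if (!R_finite(ll)) stop("non-finite log-likelihood at initial values");

  int npar = P + 2 + I + 1; // alpha, lpsi, lp, a0, sigma
  int n_keep = (n_iter - burnin) / thin;
  NumericMatrix draws(n_keep, npar);
  Adapt ad; ad.init(npar, 0.5);
  std::vector<double> acc_post(npar, 0.0); int n_post = 0;
  std::vector<double> theta_cur, m_cur;
  int row = 0;

  for (int t = 1; t <= n_iter; ++t) {
    bool adapting = t <= burnin;
    for (int p = 0; p < P; ++p) {
      if (!update_alpha[p]) continue;
      double step = std::exp(ad.lstep[p]);
      double old = alpha[p], prop = old + step * R::norm_rand();
      theta_cur = w.theta_lin;
      double d = prop - old;
      for (int c = 0; c < w.nc2; ++c) w.theta_lin[c] += d * w.Xtheta[p * w.nc2 + c];
      double llp = w.total_loglik(a0.data(), ull_prop);
      double lr = llp - ll + dnorm_log(prop, alpha_pm[p], alpha_pv[p]) -
                  dnorm_log(old, alpha_pm[p], alpha_pv[p]);
      ++ad.tries[p];
      if (std::log(R::unif_rand()) < lr) {
        alpha[p] = prop; ll = llp; ull = ull_prop; ++ad.acc[p];
        if (!adapting) acc_post[p] += 1.0;
      } else {
        w.theta_lin = theta_cur;
      }
    }
    // constant conditional plot occupancy / detection (logit scale)
    for (int which = 0; which < 2; ++which) {
      if (which == 0 && !update_lpsi) continue;
      if (which == 1 && !update_lp) continue;
      int jj = P + which;
      double step = std::exp(ad.lstep[jj]);
      double old = which == 0 ? lpsi : lp;
      double prop = old + step * R::norm_rand();
      m_cur = w.m;
      if (which == 0) w.set_plot_terms(prop, lp); else w.set_plot_terms(lpsi, prop);
      double llp = w.total_loglik(a0.data(), ull_prop);
      double pm = which == 0 ? lpsi_pm : lp_pm;
      double pv = which == 0 ? lpsi_pv : lp_pv;
      double lr = llp - ll + dnorm_log(prop, pm, pv) - dnorm_log(old, pm, pv);
      ++ad.tries[jj];
      if (std::log(R::unif_rand()) < lr) {
        if (which == 0) lpsi = prop; else lp = prop;
        ll = llp; ull = ull_prop; ++ad.acc[jj];
        if (!adapting) acc_post[jj] += 1.0;
      } else {
        w.m = m_cur;
      }
    }
    if (update_a0) {
      for (int i = 0; i < I; ++i) {
        int jj = P + 2 + i;
        double step = std::exp(ad.lstep[jj]);
        double old = a0[i], prop = old + step * R::norm_rand();
        double uip = w.unit_loglik(i, prop);
        double lr = uip - ull[i] +
                    dnorm_log(prop, 0.0, sigma * sigma) -
                    dnorm_log(old, 0.0, sigma * sigma);
        ++ad.tries[jj];
        if (std::log(R::unif_rand()) < lr) {
          ll += uip - ull[i]; ull[i] = uip; a0[i] = prop; ++ad.acc[jj];
          if (!adapting) acc_post[jj] += 1.0;
        }
      }
    }
    if (update_sigma) {
      int jj = npar - 1;
      double step = std::exp(ad.lstep[jj]);
      double prop = sigma * std::exp(step * R::norm_rand());
      double lr = dgamma_log(prop, sigma_shape, sigma_rate) -
                  dgamma_log(sigma, sigma_shape, sigma_rate) +
                  std::log(prop) - std::log(sigma);
      for (int i = 0; i < I; ++i)
        lr += dnorm_log(a0[i], 0.0, prop * prop) - dnorm_log(a0[i], 0.0, sigma * sigma);
      ++ad.tries[jj];
      if (std::log(R::unif_rand()) < lr) {
        sigma = prop; ++ad.acc[jj];
        if (!adapting) acc_post[jj] += 1.0;
      }
    }
    if (adapting) {
      if (t % 50 == 0) ad.maybe_adapt();
    } else {
      ++n_post;
      if ((t - burnin) % thin == 0 && row < n_keep) {
        for (int p = 0; p < P; ++p) draws(row, p) = alpha[p];
        draws(row, P) = lpsi; draws(row, P + 1) = lp;
        for (int i = 0; i < I; ++i) draws(row, P + 2 + i) = a0[i];
        draws(row, npar - 1) = sigma;
        ++row;
      }
    }
  }
  NumericVector acc_rate(npar);
  for (int j = 0; j < npar; ++j) acc_rate[j] = n_post > 0 ? acc_post[j] / n_post : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = acc_rate,
                      _["loglik"] = ll);
}
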