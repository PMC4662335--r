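// Adaptive random-walk Metropolis samplers for the two occupancy models.
//
// Latent occupancy states are marginalized analytically (zero-inflated
// Bernoulli for the static model, two-state forward algorithm for the
// dynamic model), so the chains move only through the continuous
// parameters.  Updates are one parameter at a time within blocks, and each
// update recomputes only the slice of cached likelihood terms it can
// affect.  Proposal scales adapt by Robbins-Monro during burn-in and are
// frozen afterwards.  All randomness comes from R's RNG, so set.seed() in R
// makes runs bit-reproducible.
//
// Data enter collapsed: site-years (static) or whole wetland histories
// (dynamic) that are identical within an area are represented once with a
// multiplicity weight, which leaves the likelihood unchanged.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -20.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double expit_(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double log_expit_(double x) { return -log1pexp_(-x); }
// log density of logistic(0,1): the prior on a logit-scale intercept whose
// inverse-logit is Uniform(0,1)
static inline double dlogis_log_(double x) { return x - 2.0 * log1pexp_(x); }
static inline double dnorm_log_(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.918938533204672742 - std::log(s) - 0.5 * z * z;
}
// Gamma(0.1, 0.1) prior for an SD, parameter sampled as log(sigma)
// (Jacobian included).  prec_conv switches the prior to the precision.
static inline double lsigma_prior_(double ls, int prec_conv) {
  double s = std::exp(ls);
  if (!prec_conv) return 0.1 * ls - 0.1 * s;
  // tau = s^-2 ~ Gamma(0.1, 0.1); transform to log(sigma)
  double tau = 1.0 / (s * s);
  return (0.1 - 1.0) * std::log(tau) - 0.1 * tau - 3.0 * std::log(s) + ls +
         std::log(2.0);
}

struct Adapt {
  std::vector<double> ls;
  std::vector<long> n;
  double target;
  bool on;
  Adapt(int k, const NumericVector& init, double t)
      : ls(k), n(k, 0), target(t), on(true) {
    for (int i = 0; i < k; ++i) ls[i] = std::log(init[i]);
  }
  double scale(int k) const { return std::exp(ls[k]); }
  void update(int k, bool acc) {
    if (!on) return;
    ++n[k];
    double step = 1.0 / std::sqrt((double)n[k]);
    if (step > 0.25) step = 0.25;
    ls[k] += step * ((acc ? 1.0 : 0.0) - target);
    if (ls[k] < -8.0) ls[k] = -8.0;
    if (ls[k] > 4.0) ls[k] = 4.0;
  }
};

// ------------------------------------------------------------------------
// Static trend model
// ------------------------------------------------------------------------

struct StaticState {
  int nA, nAY, nP, nR;
  IntegerVector ay_area, prof_ay, prof_allzero, prof_start, rec_y;
  IntegerVector ay_prof_start, area_prof_start;
  NumericVector ay_Y, L, prof_w, rec_date;
  int nested, use_det_re;
  int ia, id0, ib, imu, ils, ida, idb, ilsp, idd, npar;
  std::vector<double> th, cond, sitell;
  double ll;  // total weighted log-likelihood

  StaticState(List dat, int nested_, int use_det_re_)
      : ay_area(as<IntegerVector>(dat["ay_area"])),
        prof_ay(as<IntegerVector>(dat["prof_ay"])),
        prof_allzero(as<IntegerVector>(dat["prof_allzero"])),
        prof_start(as<IntegerVector>(dat["prof_start"])),
        rec_y(as<IntegerVector>(dat["rec_y"])),
        ay_prof_start(as<IntegerVector>(dat["ay_prof_start"])),
        area_prof_start(as<IntegerVector>(dat["area_prof_start"])),
        ay_Y(as<NumericVector>(dat["ay_Y"])),
        L(as<NumericVector>(dat["L"])),
        prof_w(as<NumericVector>(dat["prof_w"])),
        rec_date(as<NumericVector>(dat["rec_date"])),
        nested(nested_), use_det_re(use_det_re_) {
    nA = L.size(); nAY = ay_area.size(); nP = prof_ay.size(); nR = rec_y.size();
    ia = 0; id0 = nA; ib = 2 * nA; imu = ib + 1; ils = ib + 2;
    ida = ib + 3; idb = ib + 4; ilsp = ib + 5; idd = ib + 6;
    npar = 2 * nA + 6 + nAY;
    th.assign(npar, 0.0);
    cond.assign(nP, 0.0);
    sitell.assign(nP, 0.0);
    ll = 0.0;
  }

  double trend(int a) const {
    return th[ib] * L[a] + (nested ? th[id0 + a] : th[imu]);
  }
  double psi_lin(int q) const {
    int ay = prof_ay[q], a = ay_area[ay];
    return th[ia + a] + trend(a) * ay_Y[ay];
  }
  double comp_cond(int q, double da, double db, double ddv) const {
    double c = 0.0;
    for (int r = prof_start[q]; r < prof_start[q + 1]; ++r) {
      double lin = da + db * rec_date[r] + ddv;
      c += rec_y[r] ? log_expit_(lin) : -log1pexp_(lin);
    }
    return c;
  }
  double site_ll(int q, double plin, double c) const {
    double la = log_expit_(plin) + c;
    if (!prof_allzero[q]) return la;
    double lb = -log1pexp_(plin);
    double m = la > lb ? la : lb;
    return m + std::log(std::exp(la - m) + std::exp(lb - m));
  }
  void rebuild() {
    ll = 0.0;
    for (int q = 0; q < nP; ++q) {
      double ddv = use_det_re ? th[idd + prof_ay[q]] : 0.0;
      cond[q] = comp_cond(q, th[ida], th[idb], ddv);
      sitell[q] = site_ll(q, psi_lin(q), cond[q]);
      ll += prof_w[q] * sitell[q];
    }
  }
};

// total marginal log-likelihood at a given parameter vector (test hook)
// [[Rcpp::export(name = ".static_loglik_cpp")]]
double static_loglik_cpp(List dat, NumericVector theta, int nested,
                         int use_det_re) {
  StaticState st(dat, nested, use_det_re);
  if ((int)theta.size() != st.npar) stop("theta has wrong length");
  for (int i = 0; i < st.npar; ++i) st.th[i] = theta[i];
  st.rebuild();
  return st.ll;
}

// [[Rcpp::export(name = ".static_mcmc_cpp")]]
List static_mcmc_cpp(List dat, List cfg) {
  int nested = as<int>(cfg["nested"]);
  int use_det_re = as<int>(cfg["use_det_re"]);
  int prec_conv = as<int>(cfg["prior_precision"]);
  int n_burn = as<int>(cfg["n_burn"]);
  int n_keep = as<int>(cfg["n_keep"]);
  double target = as<double>(cfg["target_acc"]);
  NumericVector init = as<NumericVector>(cfg["init"]);
  IntegerVector fixed = as<IntegerVector>(cfg["fixed"]);
  NumericVector sc0 = as<NumericVector>(cfg["scales"]);

  StaticState st(dat, nested, use_det_re);
  int npar = st.npar, nA = st.nA, nAY = st.nAY;
  if ((int)init.size() != npar || (int)fixed.size() != npar ||
      (int)sc0.size() != npar)
    stop("init/fixed/scales must have length %d", npar);
  for (int i = 0; i < npar; ++i) st.th[i] = init[i];
  st.rebuild();
  if (!R_finite(st.ll)) stop("non-finite log-likelihood at initialization");

  Adapt ad(npar, sc0, target);
  std::vector<double> nsll(st.nP), ncond(st.nP);
  std::vector<long> prop(npar, 0), acc(npar, 0);

  // generic slice update over profiles [q0, q1) when only psi changes
  auto upd_psi_slice = [&](int k, int q0, int q1, double dlp_extra,
                           double thp) {
    double save = st.th[k];
    st.th[k] = thp;
    double dll = 0.0;
    for (int q = q0; q < q1; ++q) {
      nsll[q] = st.site_ll(q, st.psi_lin(q), st.cond[q]);
      dll += st.prof_w[q] * (nsll[q] - st.sitell[q]);
    }
    if (std::log(unif_rand()) < dlp_extra + dll) {
      for (int q = q0; q < q1; ++q) st.sitell[q] = nsll[q];
      st.ll += dll;
      return true;
    }
    st.th[k] = save;
    return false;
  };

  auto metro_psi = [&](int k, int q0, int q1,
                       std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    bool ok = upd_psi_slice(k, q0, q1, dprior(xp, x), xp);
    if (ok) ++acc[k];
    ad.update(k, ok);
  };

  // prior-only Metropolis (no likelihood dependence)
  auto metro_prior = [&](int k, std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    bool ok = std::log(unif_rand()) < dprior(xp, x);
    if (ok) { st.th[k] = xp; ++acc[k]; }
    ad.update(k, ok);
  };

  // detection-parameter update over profiles [q0, q1): cond changes too
  auto metro_det = [&](int k, int q0, int q1,
                       std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    st.th[k] = xp;
    double dll = 0.0;
    for (int q = q0; q < q1; ++q) {
      double ddv = use_det_re ? st.th[st.idd + st.prof_ay[q]] : 0.0;
      ncond[q] = st.comp_cond(q, st.th[st.ida], st.th[st.idb], ddv);
      nsll[q] = st.site_ll(q, st.psi_lin(q), ncond[q]);
      dll += st.prof_w[q] * (nsll[q] - st.sitell[q]);
    }
    bool ok = std::log(unif_rand()) < dprior(xp, x) + dll;
    if (ok) {
      for (int q = q0; q < q1; ++q) {
        st.cond[q] = ncond[q];
        st.sitell[q] = nsll[q];
      }
      st.ll += dll;
      ++acc[k];
    } else {
      st.th[k] = x;
    }
    ad.update(k, ok);
  };

  auto dlogis_d = [](double xp, double x) {
    return dlogis_log_(xp) - dlogis_log_(x);
  };
  auto dnorm100_d = [](double xp, double x) {
    return dnorm_log_(xp, 0, 100) - dnorm_log_(x, 0, 100);
  };

  // translation moves: shift a weakly identified global parameter and
  // counter-shift the random effects it is confounded with, leaving the
  // likelihood invariant (prior-only Metropolis along the ridge)
  NumericVector tr_sc0 = NumericVector::create(0.1, 0.1);
  Adapt tad(2, tr_sc0, target);
  bool fix_any_delta = false, fix_any_dd = false;
  for (int a = 0; a < nA; ++a) fix_any_delta |= fixed[st.id0 + a] != 0;
  for (int j = 0; j < nAY; ++j) fix_any_dd |= fixed[st.idd + j] != 0;

  auto translate_beta = [&]() {  // beta_lat vs delta_i (slope ridge)
    if (!nested || fixed[st.ib] || fix_any_delta) return;
    double eps = tad.scale(0) * norm_rand();
    double sg = std::exp(st.th[st.ils]);
    double d = dnorm_log_(st.th[st.ib] + eps, 0, 100) -
               dnorm_log_(st.th[st.ib], 0, 100);
    for (int a = 0; a < nA; ++a)
      d += dnorm_log_(st.th[st.id0 + a] - eps * st.L[a], st.th[st.imu], sg) -
           dnorm_log_(st.th[st.id0 + a], st.th[st.imu], sg);
    bool ok = std::log(unif_rand()) < d;
    if (ok) {
      st.th[st.ib] += eps;
      for (int a = 0; a < nA; ++a) st.th[st.id0 + a] -= eps * st.L[a];
    }
    tad.update(0, ok);
  };
  auto translate_det = [&]() {  // det_alpha vs delta_det (intercept ridge)
    if (!use_det_re || fixed[st.ida] || fix_any_dd) return;
    double eps = tad.scale(1) * norm_rand();
    double sp = std::exp(st.th[st.ilsp]);
    double d = dlogis_log_(st.th[st.ida] + eps) - dlogis_log_(st.th[st.ida]);
    for (int j = 0; j < nAY; ++j)
      d += dnorm_log_(st.th[st.idd + j] - eps, 0, sp) -
           dnorm_log_(st.th[st.idd + j], 0, sp);
    bool ok = std::log(unif_rand()) < d;
    if (ok) {
      st.th[st.ida] += eps;
      for (int j = 0; j < nAY; ++j) st.th[st.idd + j] -= eps;
    }
    tad.update(1, ok);
  };

  NumericMatrix samp(n_keep, npar);
  int n_total = n_burn + n_keep;
  for (int it = 0; it < n_total; ++it) {
    ad.on = it < n_burn;
    tad.on = it < n_burn;
    for (int a = 0; a < nA; ++a)
      metro_psi(st.ia + a, st.area_prof_start[a], st.area_prof_start[a + 1],
                dlogis_d);
    if (nested) {
      for (int a = 0; a < nA; ++a)
        metro_psi(st.id0 + a, st.area_prof_start[a], st.area_prof_start[a + 1],
                  [&](double xp, double x) {
                    double sg = std::exp(st.th[st.ils]);
                    return dnorm_log_(xp, st.th[st.imu], sg) -
                           dnorm_log_(x, st.th[st.imu], sg);
                  });
      // hyper-mean and hyper-SD only touch the prior of the delta block
      metro_prior(st.imu, [&](double xp, double x) {
        double sg = std::exp(st.th[st.ils]);
        double d = dnorm100_d(xp, x);
        for (int a = 0; a < nA; ++a)
          d += dnorm_log_(st.th[st.id0 + a], xp, sg) -
               dnorm_log_(st.th[st.id0 + a], x, sg);
        return d;
      });
      metro_prior(st.ils, [&](double xp, double x) {
        double sp = std::exp(xp), sc = std::exp(x);
        double d = lsigma_prior_(xp, prec_conv) - lsigma_prior_(x, prec_conv);
        for (int a = 0; a < nA; ++a)
          d += dnorm_log_(st.th[st.id0 + a], st.th[st.imu], sp) -
               dnorm_log_(st.th[st.id0 + a], st.th[st.imu], sc);
        return d;
      });
    } else {
      metro_psi(st.imu, 0, st.nP, dnorm100_d);  // shared trend slope
    }
    metro_psi(st.ib, 0, st.nP, dnorm100_d);
    metro_det(st.ida, 0, st.nP, dlogis_d);
    metro_det(st.idb, 0, st.nP, dnorm100_d);
    if (use_det_re) {
      metro_prior(st.ilsp, [&](double xp, double x) {
        double sp = std::exp(xp), sc = std::exp(x);
        double d = lsigma_prior_(xp, prec_conv) - lsigma_prior_(x, prec_conv);
        for (int j = 0; j < nAY; ++j)
          d += dnorm_log_(st.th[st.idd + j], 0, sp) -
               dnorm_log_(st.th[st.idd + j], 0, sc);
        return d;
      });
      for (int j = 0; j < nAY; ++j)
        metro_det(st.idd + j, st.ay_prof_start[j], st.ay_prof_start[j + 1],
                  [&](double xp, double x) {
                    double sp = std::exp(st.th[st.ilsp]);
                    return dnorm_log_(xp, 0, sp) - dnorm_log_(x, 0, sp);
                  });
    }
    translate_beta();
    translate_det();
    if (it >= n_burn) {
      int row = it - n_burn;
      for (int kk = 0; kk < npar; ++kk) samp(row, kk) = st.th[kk];
      // report SDs on the natural scale
      samp(row, st.ils) = std::exp(st.th[st.ils]);
      samp(row, st.ilsp) = std::exp(st.th[st.ilsp]);
    }
  }
  NumericVector arate(npar);
  for (int kk = 0; kk < npar; ++kk)
    arate[kk] = prop[kk] ? (double)acc[kk] / prop[kk] : NA_REAL;
  return List::create(_["samples"] = samp, _["accept"] = arate,
                      _["loglik"] = st.ll);
}

// ------------------------------------------------------------------------
// Dynamic colonization/persistence model
// ------------------------------------------------------------------------

struct DynState {
  int nA, T, nAY, nS, nR;
  IntegerVector site_area, sy_off, sy_len, sy_ay, rec_y, area_site_start;
  IntegerVector ay_area, ay_t;
  NumericVector site_w, rec_date;
  int re_area, re_year, re_det;
  // parameter indices
  int ipsi, ica, icd, ict, ilcsa, ilcst, ipa, ipd, ipt, ilpsa, ilpst;
  int ida, idb, ilsp, idd, npar;
  std::vector<double> th;
  std::vector<double> e0, e1;     // per (site, year) emissions
  std::vector<double> phi, gam;   // per (area, interval)
  std::vector<double> sll;        // per site log-likelihood
  double ll;

  DynState(List dat, int re_area_, int re_year_, int re_det_)
      : site_area(as<IntegerVector>(dat["site_area"])),
        sy_off(as<IntegerVector>(dat["sy_off"])),
        sy_len(as<IntegerVector>(dat["sy_len"])),
        sy_ay(as<IntegerVector>(dat["sy_ay"])),
        rec_y(as<IntegerVector>(dat["rec_y"])),
        area_site_start(as<IntegerVector>(dat["area_site_start"])),
        ay_area(as<IntegerVector>(dat["ay_area"])),
        ay_t(as<IntegerVector>(dat["ay_t"])),
        site_w(as<NumericVector>(dat["site_w"])),
        rec_date(as<NumericVector>(dat["rec_date"])),
        re_area(re_area_), re_year(re_year_), re_det(re_det_) {
    nA = area_site_start.size() - 1;
    T = as<int>(dat["T"]);
    nAY = ay_area.size();
    nS = site_area.size();
    nR = rec_y.size();
    ipsi = 0;
    ica = nA; icd = ica + 1; ict = icd + nA;
    ilcsa = ict + (T - 1); ilcst = ilcsa + 1;
    ipa = ilcst + 1; ipd = ipa + 1; ipt = ipd + nA;
    ilpsa = ipt + (T - 1); ilpst = ilpsa + 1;
    ida = ilpst + 1; idb = ida + 1; ilsp = idb + 1; idd = ilsp + 1;
    npar = idd + nAY;
    th.assign(npar, 0.0);
    e0.assign(nS * T, 1.0);
    e1.assign(nS * T, 1.0);
    phi.assign(nA * (T - 1), 0.5);
    gam.assign(nA * (T - 1), 0.5);
    sll.assign(nS, 0.0);
    ll = 0.0;
  }

  double phi_lin(int a, int t) const {
    return th[ipa] + (re_area ? th[ipd + a] : 0.0) +
           (re_year ? th[ipt + t] : 0.0);
  }
  double gam_lin(int a, int t) const {
    return th[ica] + (re_area ? th[icd + a] : 0.0) +
           (re_year ? th[ict + t] : 0.0);
  }
  void comp_emit(int s, int t, double da, double db, double* e0o,
                 double* e1o) const {
    int idx = s * T + t, len = sy_len[idx];
    if (!len) { *e0o = 1.0; *e1o = 1.0; return; }
    double ddv = re_det ? th[idd + sy_ay[idx]] : 0.0;
    double c = 0.0;
    bool allz = true;
    for (int r = sy_off[idx]; r < sy_off[idx] + len; ++r) {
      double lin = da + db * rec_date[r] + ddv;
      if (rec_y[r]) { c += log_expit_(lin); allz = false; }
      else c += -log1pexp_(lin);
    }
    *e1o = std::exp(c);
    *e0o = allz ? 1.0 : 0.0;
  }
  // forward pass for site s with candidate arrays
  double fwd(int s, const double* phiv, const double* gamv, double psi1,
             const double* e0v, const double* e1v) const {
    int a = site_area[s];
    double f1 = psi1, f0 = 1.0 - psi1, acc = 0.0;
    const double* ph = phiv + a * (T - 1);
    const double* ga = gamv + a * (T - 1);
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        double g1 = f0 * ga[t - 1] + f1 * ph[t - 1];
        f0 = f0 + f1 - g1;
        f1 = g1;
      }
      int idx = s * T + t;
      f0 *= e0v[idx]; f1 *= e1v[idx];
      double sm = f0 + f1;
      if (sm <= 0.0) return R_NegInf;
      if (sm < 1e-12) { acc += std::log(sm); f0 /= sm; f1 /= sm; }
    }
    return acc + std::log(f0 + f1);
  }
  void rebuild() {
    for (int a = 0; a < nA; ++a)
      for (int t = 0; t < T - 1; ++t) {
        phi[a * (T - 1) + t] = expit_(phi_lin(a, t));
        gam[a * (T - 1) + t] = expit_(gam_lin(a, t));
      }
    for (int s = 0; s < nS; ++s)
      for (int t = 0; t < T; ++t)
        comp_emit(s, t, th[ida], th[idb], &e0[s * T + t], &e1[s * T + t]);
    ll = 0.0;
    for (int s = 0; s < nS; ++s) {
      sll[s] = fwd(s, phi.data(), gam.data(), expit_(th[ipsi + site_area[s]]),
                   e0.data(), e1.data());
      ll += site_w[s] * sll[s];
    }
  }
};

// [[Rcpp::export(name = ".dynamic_loglik_cpp")]]
double dynamic_loglik_cpp(List dat, NumericVector theta, int re_area,
                          int re_year, int re_det) {
  DynState st(dat, re_area, re_year, re_det);
  if ((int)theta.size() != st.npar) stop("theta has wrong length");
  for (int i = 0; i < st.npar; ++i) st.th[i] = theta[i];
  st.rebuild();
  return st.ll;
}

// [[Rcpp::export(name = ".dynamic_mcmc_cpp")]]
List dynamic_mcmc_cpp(List dat, List cfg) {
  int re_area = as<int>(cfg["re_area"]);
  int re_year = as<int>(cfg["re_year"]);
  int re_det = as<int>(cfg["re_det"]);
  int prec_conv = as<int>(cfg["prior_precision"]);
  int n_burn = as<int>(cfg["n_burn"]);
  int n_keep = as<int>(cfg["n_keep"]);
  double target = as<double>(cfg["target_acc"]);
  NumericVector init = as<NumericVector>(cfg["init"]);
  IntegerVector fixed = as<IntegerVector>(cfg["fixed"]);
  NumericVector sc0 = as<NumericVector>(cfg["scales"]);

  DynState st(dat, re_area, re_year, re_det);
  int npar = st.npar, nA = st.nA, T = st.T, nAY = st.nAY, nS = st.nS;
  if ((int)init.size() != npar || (int)fixed.size() != npar ||
      (int)sc0.size() != npar)
    stop("init/fixed/scales must have length %d", npar);
  for (int i = 0; i < npar; ++i) st.th[i] = init[i];
  st.rebuild();
  if (!R_finite(st.ll)) stop("non-finite log-likelihood at initialization");

  Adapt ad(npar, sc0, target);
  std::vector<double> nsll(nS), nphi(nA * (T - 1)), ngam(nA * (T - 1));
  std::vector<double> ne0(nS * T), ne1(nS * T);
  std::vector<long> prop(npar, 0), acc(npar, 0);

  // accept/reject with candidate transition arrays over sites [s0, s1)
  auto try_sites = [&](int s0, int s1, const double* phiv, const double* gamv,
                       const double* e0v, const double* e1v, double dlp,
                       double* dll_out) {
    double dll = 0.0;
    for (int s = s0; s < s1; ++s) {
      nsll[s] = st.fwd(s, phiv, gamv, expit_(st.th[st.ipsi + st.site_area[s]]),
                       e0v, e1v);
      dll += st.site_w[s] * (nsll[s] - st.sll[s]);
    }
    *dll_out = dll;
    return std::log(unif_rand()) < dlp + dll;
  };

  auto metro_prior = [&](int k, std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    bool ok = std::log(unif_rand()) < dprior(xp, x);
    if (ok) { st.th[k] = xp; ++acc[k]; }
    ad.update(k, ok);
  };

  // update a parameter entering the transition linear predictors.
  // which: 0 = colonization, 1 = persistence; a_only = -1 for all areas.
  auto metro_trans = [&](int k, int which, int a_only,
                         std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    st.th[k] = xp;
    std::vector<double>& tgt = which ? st.phi : st.gam;
    std::vector<double>& ntg = which ? nphi : ngam;
    int a0 = a_only < 0 ? 0 : a_only, a1 = a_only < 0 ? nA : a_only + 1;
    ntg = tgt;
    for (int a = a0; a < a1; ++a)
      for (int t = 0; t < T - 1; ++t)
        ntg[a * (T - 1) + t] =
            expit_(which ? st.phi_lin(a, t) : st.gam_lin(a, t));
    int s0 = st.area_site_start[a0], s1 = st.area_site_start[a1];
    double dll;
    bool ok = try_sites(s0, s1, which ? ntg.data() : st.phi.data(),
                        which ? st.gam.data() : ntg.data(), st.e0.data(),
                        st.e1.data(), dprior(xp, x), &dll);
    if (ok) {
      for (int a = a0; a < a1; ++a)
        for (int t = 0; t < T - 1; ++t)
          tgt[a * (T - 1) + t] = ntg[a * (T - 1) + t];
      for (int s = s0; s < s1; ++s) st.sll[s] = nsll[s];
      st.ll += dll;
      ++acc[k];
    } else {
      st.th[k] = x;
    }
    ad.update(k, ok);
  };

  auto metro_psi1 = [&](int a) {
    int k = st.ipsi + a;
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    st.th[k] = xp;
    double dll;
    bool ok = try_sites(st.area_site_start[a], st.area_site_start[a + 1],
                        st.phi.data(), st.gam.data(), st.e0.data(),
                        st.e1.data(), dlogis_log_(xp) - dlogis_log_(x), &dll);
    if (ok) {
      for (int s = st.area_site_start[a]; s < st.area_site_start[a + 1]; ++s)
        st.sll[s] = nsll[s];
      st.ll += dll;
      ++acc[k];
    } else {
      st.th[k] = x;
    }
    ad.update(k, ok);
  };

  // detection parameter update over sites [s0, s1); t_only = -1 for all years
  auto metro_det = [&](int k, int s0, int s1, int t_only,
                       std::function<double(double, double)> dprior) {
    if (fixed[k]) return;
    ++prop[k];
    double x = st.th[k], xp = x + ad.scale(k) * norm_rand();
    st.th[k] = xp;
    for (int s = s0; s < s1; ++s) {
      int ta = t_only < 0 ? 0 : t_only, tb = t_only < 0 ? T : t_only + 1;
      for (int t = 0; t < T; ++t) {
        int idx = s * T + t;
        if (t >= ta && t < tb) {
          st.comp_emit(s, t, st.th[st.ida], st.th[st.idb], &ne0[idx],
                       &ne1[idx]);
        } else {
          ne0[idx] = st.e0[idx]; ne1[idx] = st.e1[idx];
        }
      }
    }
    double dll;
    bool ok = try_sites(s0, s1, st.phi.data(), st.gam.data(), ne0.data(),
                        ne1.data(), dprior(xp, x), &dll);
    if (ok) {
      for (int s = s0; s < s1; ++s)
        for (int t = 0; t < T; ++t) {
          st.e0[s * T + t] = ne0[s * T + t];
          st.e1[s * T + t] = ne1[s * T + t];
        }
      for (int s = s0; s < s1; ++s) st.sll[s] = nsll[s];
      st.ll += dll;
      ++acc[k];
    } else {
      st.th[k] = x;
    }
    ad.update(k, ok);
  };

  auto dlogis_d = [](double xp, double x) {
    return dlogis_log_(xp) - dlogis_log_(x);
  };
  auto dnorm100_d = [](double xp, double x) {
    return dnorm_log_(xp, 0, 100) - dnorm_log_(x, 0, 100);
  };
  auto re_prior = [&](int ls_idx) {
    return [&, ls_idx](double xp, double x) {
      double sg = std::exp(st.th[ls_idx]);
      return dnorm_log_(xp, 0, sg) - dnorm_log_(x, 0, sg);
    };
  };
  auto sd_update = [&](int ls_idx, int eff0, int n_eff) {
    metro_prior(ls_idx, [&, eff0, n_eff](double xp, double x) {
      double sp = std::exp(xp), sc = std::exp(x);
      double d = lsigma_prior_(xp, prec_conv) - lsigma_prior_(x, prec_conv);
      for (int j = 0; j < n_eff; ++j)
        d += dnorm_log_(st.th[eff0 + j], 0, sp) -
             dnorm_log_(st.th[eff0 + j], 0, sc);
      return d;
    });
  };

  // translation moves along intercept/random-effect ridges: shift an
  // intercept, counter-shift its whole effect block; every logit linear
  // predictor (hence the likelihood and all caches) is unchanged
  NumericVector tr_sc0 = NumericVector::create(0.1, 0.1, 0.1, 0.1, 0.1);
  Adapt tad(5, tr_sc0, target);
  auto translate = [&](int slot, int k, int e0_, int ncnt, int ls_idx) {
    if (fixed[k]) return;
    for (int j = 0; j < ncnt; ++j) if (fixed[e0_ + j]) return;
    double eps = tad.scale(slot) * norm_rand();
    double sg = std::exp(st.th[ls_idx]);
    double d = dlogis_log_(st.th[k] + eps) - dlogis_log_(st.th[k]);
    for (int j = 0; j < ncnt; ++j)
      d += dnorm_log_(st.th[e0_ + j] - eps, 0, sg) -
           dnorm_log_(st.th[e0_ + j], 0, sg);
    bool ok = std::log(unif_rand()) < d;
    if (ok) {
      st.th[k] += eps;
      for (int j = 0; j < ncnt; ++j) st.th[e0_ + j] -= eps;
    }
    tad.update(slot, ok);
  };

  NumericMatrix samp(n_keep, npar);
  int n_total = n_burn + n_keep;
  for (int it = 0; it < n_total; ++it) {
    ad.on = it < n_burn;
    tad.on = it < n_burn;
    for (int a = 0; a < nA; ++a) metro_psi1(a);
    metro_trans(st.ica, 0, -1, dlogis_d);
    metro_trans(st.ipa, 1, -1, dlogis_d);
    if (re_area) {
      for (int a = 0; a < nA; ++a) {
        metro_trans(st.icd + a, 0, a, re_prior(st.ilcsa));
        metro_trans(st.ipd + a, 1, a, re_prior(st.ilpsa));
      }
      sd_update(st.ilcsa, st.icd, nA);
      sd_update(st.ilpsa, st.ipd, nA);
    }
    if (re_year) {
      for (int t = 0; t < T - 1; ++t) {
        metro_trans(st.ict + t, 0, -1, re_prior(st.ilcst));
        metro_trans(st.ipt + t, 1, -1, re_prior(st.ilpst));
      }
      sd_update(st.ilcst, st.ict, T - 1);
      sd_update(st.ilpst, st.ipt, T - 1);
    }
    metro_det(st.ida, 0, nS, -1, dlogis_d);
    metro_det(st.idb, 0, nS, -1, dnorm100_d);
    if (re_det) {
      sd_update(st.ilsp, st.idd, nAY);
      for (int j = 0; j < nAY; ++j) {
        int a = st.ay_area[j], t = st.ay_t[j];
        metro_det(st.idd + j, st.area_site_start[a],
                  st.area_site_start[a + 1], t, re_prior(st.ilsp));
      }
    }
    if (re_area) {
      translate(0, st.ica, st.icd, nA, st.ilcsa);
      translate(1, st.ipa, st.ipd, nA, st.ilpsa);
    }
    if (re_year) {
      translate(2, st.ica, st.ict, T - 1, st.ilcst);
      translate(3, st.ipa, st.ipt, T - 1, st.ilpst);
    }
    if (re_det) translate(4, st.ida, st.idd, nAY, st.ilsp);
    if (it >= n_burn) {
      int row = it - n_burn;
      for (int kk = 0; kk < npar; ++kk) samp(row, kk) = st.th[kk];
      samp(row, st.ilcsa) = std::exp(st.th[st.ilcsa]);
      samp(row, st.ilcst) = std::exp(st.th[st.ilcst]);
      samp(row, st.ilpsa) = std::exp(st.th[st.ilpsa]);
      samp(row, st.ilpst) = std::exp(st.th[st.ilpst]);
      samp(row, st.ilsp) = std::exp(st.th[st.ilsp]);
    }
  }
  NumericVector arate(npar);
  for (int kk = 0; kk < npar; ++kk)
    arate[kk] = prop[kk] ? (double)acc[kk] / prop[kk] : NA_REAL;
  return List::create(_["samples"] = samp, _["accept"] = arate,
                      _["loglik"] = st.ll);
}

// ------------------------------------------------------------------------
// Posterior-predictive site log-likelihoods for held-out wetlands
// ------------------------------------------------------------------------

// For each posterior draw d and held-out site s, the forward-algorithm
// log-likelihood of the site's full history under that draw's parameters.
// psi1/phi/gam are supplied per draw on the probability scale; logp/logq
// give per-record log p and log(1 - p).
// [[Rcpp::export(name = ".dyn_pred_loglik_cpp")]]
NumericMatrix dyn_pred_loglik_cpp(List dat, NumericMatrix psi1,
                                  NumericMatrix phim, NumericMatrix gamm,
                                  NumericMatrix logp, NumericMatrix logq) {
  DynState st(dat, 0, 0, 0);
  int nd = psi1.nrow(), nS = st.nS, T = st.T;
  if (phim.ncol() != st.nA * (T - 1) || gamm.ncol() != st.nA * (T - 1))
    stop("phi/gamma draw matrices have wrong width");
  if (logp.ncol() != st.nR) stop("logp must have one column per record");
  NumericMatrix out(nd, nS);
  for (int d = 0; d < nd; ++d) {
    for (int s = 0; s < nS; ++s) {
      int a = st.site_area[s];
      double f1 = psi1(d, a), f0 = 1.0 - f1, acc = 0.0;
      for (int t = 0; t < T; ++t) {
        if (t > 0) {
          double ph = phim(d, a * (T - 1) + t - 1);
          double ga = gamm(d, a * (T - 1) + t - 1);
          double g1 = f0 * ga + f1 * ph;
          f0 = f0 + f1 - g1;
          f1 = g1;
        }
        int idx = s * T + t, len = st.sy_len[idx];
        if (len) {
          double c = 0.0;
          bool allz = true;
          for (int r = st.sy_off[idx]; r < st.sy_off[idx] + len; ++r) {
            if (st.rec_y[r]) { c += logp(d, r); allz = false; }
            else c += logq(d, r);
          }
          f1 *= std::exp(c);
          if (!allz) f0 = 0.0;
        }
        double sm = f0 + f1;
        if (sm <= 0.0) { acc = R_NegInf; break; }
        if (sm < 1e-12) { acc += std::log(sm); f0 /= sm; f1 /= sm; }
      }
      out(d, s) = R_finite(acc) ? acc + std::log(f0 + f1) : R_NegInf;
    }
  }
  return out;
}
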