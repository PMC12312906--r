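#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Dual-context state-space forward pass.
//
// State x = (x_low, x_high). Per trial:
//   c       = (1, q) on LOW, (q, 1) on HIGH          (c_low first)
//   fc_est  = x . c                (dot variant)  or x[height] (select)
//   e       = dead-zone error of fc_est w.r.t. [h_lower, h_upper]
//   x      += B * e * c            (only when update[t] is true)
// Trials with update[t] == false (missing observations, excluded bouts)
// leave the state untouched.
// ---------------------------------------------------------------------------

static inline double deadzone_error(double fc, double hl, double hu) {
  if (fc > hu) return hu - fc;
  if (fc < hl) return hl - fc;
  return 0.0;
}

static void forward_core(const int *h, const double *hl, const double *hu,
                         int n, double B, double q, double x1l, double x1h,
                         bool select, const int *update,
                         double *fc_est, double *err,
                         double *xl_out, double *xh_out) {
  double xl = x1l, xh = x1h;
  for (int t = 0; t < n; ++t) {
    double cl, ch;
    if (h[t] == 0) { cl = 1.0; ch = q; } else { cl = q; ch = 1.0; }
    double fc = select ? (h[t] == 0 ? xl : xh) : (xl * cl + xh * ch);
    double e = deadzone_error(fc, hl[t], hu[t]);
    if (update[t]) {
      xl += B * e * cl;
      xh += B * e * ch;
    }
    fc_est[t] = fc;
    if (err) err[t] = e;
    if (xl_out) { xl_out[t] = xl; xh_out[t] = xh; }
  }
}

// [[Rcpp::export]]
List forward_sim_cpp(IntegerVector h, NumericVector hl, NumericVector hu,
                     double B, double q, double x1l, double x1h,
                     bool select, LogicalVector update) {
  int n = h.size();
  NumericVector fc(n), err(n), xl(n), xh(n);
  std::vector<int> upd(n);
  for (int t = 0; t < n; ++t) upd[t] = update[t] ? 1 : 0;
  forward_core(INTEGER(h), REAL(hl), REAL(hu), n, B, q, x1l, x1h, select,
               upd.data(), REAL(fc), REAL(err), REAL(xl), REAL(xh));
  return List::create(_["fc_est"] = fc, _["error"] = err,
                      _["x_low"] = xl, _["x_high"] = xh);
}

// Student-t log density with location mu, scale tau, df nu.
static inline double lt_const(double nu, double tau) {
  return R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu)
       - 0.5 * std::log(nu * M_PI) - std::log(tau);
}
static inline double lt_kernel(double r, double nu, double tau) {
  double z = r / tau;
  return -0.5 * (nu + 1.0) * std::log1p(z * z / nu);
}

// ---------------------------------------------------------------------------
// Data layout shared by the sampler and the pointwise log-likelihood:
// trials of all participants concatenated; off[p]..off[p]+len[p]-1 index
// participant p's trials. obs[t] == 1 when fc_obs[t] is a real observation.
// ---------------------------------------------------------------------------

struct Flat {
  const int *h, *obs, *upd;
  const double *hl, *hu, *fc;
  const int *off, *len;
  int n_p, n_trials;
};

static double loglik_p(const Flat &d, int p, const double *fc_est,
                       double tau, double nu) {
  double c0 = lt_const(nu, tau), ll = 0.0;
  const int o = d.off[p], n = d.len[p];
  for (int t = 0; t < n; ++t) {
    if (!d.obs[o + t]) continue;
    ll += c0 + lt_kernel(d.fc[o + t] - fc_est[t], nu, tau);
  }
  return ll;
}

static Flat make_flat(List data) {
  Flat d;
  d.h = INTEGER(as<IntegerVector>(data["h"]));
  d.obs = INTEGER(as<IntegerVector>(data["obs"]));
  d.upd = INTEGER(as<IntegerVector>(data["upd"]));
  d.hl = REAL(as<NumericVector>(data["hl"]));
  d.hu = REAL(as<NumericVector>(data["hu"]));
  d.fc = REAL(as<NumericVector>(data["fc"]));
  d.off = INTEGER(as<IntegerVector>(data["off"]));
  d.len = INTEGER(as<IntegerVector>(data["len"]));
  d.n_p = as<IntegerVector>(data["off"]).size();
  d.n_trials = as<IntegerVector>(data["h"]).size();
  return d;
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Truncated-normal (>= lo) draw via inverse CDF, numerically guarded.
static double rtnorm_lower(double m, double s, double lo) {
  double plo = R::pnorm(lo, m, s, 1, 0);
  if (plo > 1.0 - 1e-12) return lo + 1e-8 * s;
  double u = R::runif(plo, 1.0);
  double x = R::qnorm(u, m, s, 1, 0);
  return x < lo ? lo : x;
}

// ---------------------------------------------------------------------------
// One MCMC chain for the three-level hierarchical model.
//
// model: 0 = FULL (B_p and q_p), 1 = B_ONLY (q = 0), 2 = Q_ONLY (B shared).
// Uses R's RNG; caller seeds per chain. Adaptation (Robbins-Monro on log
// step sizes) runs during burn-in only.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_chain_cpp(List data, List init, List prior, int model, bool select,
                   int n_iter, int burn_in, int thin, double lik_weight) {
  Flat d = make_flat(data);
  const int n_p = d.n_p;
  IntegerVector grp = data["grp"];           // 0-based group per participant
  int n_g = as<int>(data["n_groups"]);
  NumericVector muL = data["mu_low"], sdL = data["sd_low"];
  NumericVector muH = data["mu_high"], sdH = data["sd_high"];

  const double theta_sd = as<double>(prior["theta_sd"]);    // ~31.6
  const double sig_a0 = as<double>(prior["sig_a0"]);        // 1e-3
  const double sig_b0 = as<double>(prior["sig_b0"]);        // 1e-3
  const double tau_sd = as<double>(prior["tau_sd"]);        // half-normal sd
  const double k_sd = as<double>(prior["k_sd"]);
  const double nu_floor = as<double>(prior["nu_floor"]);    // > 1

  // current state
  std::vector<double> b = as<std::vector<double>>(init["b"]);
  std::vector<double> u = as<std::vector<double>>(init["u"]);
  std::vector<double> tau = as<std::vector<double>>(init["tau"]);
  std::vector<double> k = as<std::vector<double>>(init["k"]);
  std::vector<double> x1l = as<std::vector<double>>(init["x1_low"]);
  std::vector<double> x1h = as<std::vector<double>>(init["x1_high"]);
  std::vector<double> thB = as<std::vector<double>>(init["theta_B"]);
  std::vector<double> s2B = as<std::vector<double>>(init["sig2_B"]);
  std::vector<double> thQ = as<std::vector<double>>(init["theta_q"]);
  std::vector<double> s2Q = as<std::vector<double>>(init["sig2_q"]);
  double nu = as<double>(init["nu"]);
  double b_shared = b[0];                    // used when model == 2

  // cached per-participant forward pass and log-likelihood
  std::vector<double> fc_est(d.n_trials), ll(n_p);
  for (int p = 0; p < n_p; ++p) {
    double B = sigmoid(model == 2 ? b_shared : b[p]);
    double q = (model == 1) ? 0.0 : sigmoid(u[p]);
    forward_core(d.h + d.off[p], d.hl + d.off[p], d.hu + d.off[p], d.len[p],
                 B, q, x1l[p], x1h[p], select, d.upd + d.off[p],
                 &fc_est[d.off[p]], nullptr, nullptr, nullptr);
    ll[p] = lik_weight * loglik_p(d, p, &fc_est[d.off[p]], tau[p], nu);
  }

  // adaptive log step sizes
  std::vector<double> ls_blk(n_p, std::log(0.4)), ls_tau(n_p, std::log(0.3));
  double ls_nu = std::log(0.3), ls_bsh = std::log(0.1);
  const double targ_blk = 0.30, targ_sc = 0.44;

  // Haario-style adaptation of the participant-block proposal: running
  // mean/covariance of (b, u, x1_low, x1_high) accumulated during burn-in;
  // proposals use the Cholesky factor of the learned covariance once enough
  // mass has accumulated, a scaled diagonal walk before that.
  const int DB = 4;
  std::vector<double> am_mean(n_p * DB, 0.0), am_cov(n_p * DB * DB, 0.0);
  std::vector<double> am_chol(n_p * DB * DB, 0.0);
  std::vector<int> am_ok(n_p, 0);
  long am_n = 0;
  const double diag_sc[DB] = {0.5, 0.5, 0.02, 0.02};
  auto refresh_chol = [&](int p) {
    // Cholesky of cov + jitter; mark usable on success
    double a[DB][DB];
    double *cv = &am_cov[p * DB * DB];
    double denom = (double)(am_n - 1);
    for (int i = 0; i < DB; ++i)
      for (int j = 0; j < DB; ++j)
        a[i][j] = cv[i * DB + j] / denom + (i == j ? 1e-10 : 0.0);
    double L[DB][DB] = {{0}};
    for (int i = 0; i < DB; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = a[i][j];
        for (int m = 0; m < j; ++m) s -= L[i][m] * L[j][m];
        if (i == j) {
          if (s <= 0) { am_ok[p] = 0; return; }
          L[i][i] = std::sqrt(s);
        } else L[i][j] = s / L[j][j];
      }
    }
    double *out_L = &am_chol[p * DB * DB];
    for (int i = 0; i < DB; ++i)
      for (int j = 0; j < DB; ++j) out_L[i * DB + j] = L[i][j];
    am_ok[p] = 1;
  };

  int n_keep = (n_iter - burn_in) / thin;
  int n_par_groups = model == 2 ? 0 : 2 * n_g;   // theta_B, sigma_B per group
  int n_par_qgrp = model == 1 ? 0 : 2 * n_g;
  int n_bsh = model == 2 ? 1 : 0;
  int n_per_p = 6;                                // B q tau k x1l x1h
  int n_par = n_par_groups + n_par_qgrp + 1 + n_bsh + n_per_p * n_p;
  NumericMatrix out(n_keep, n_par);
  std::vector<double> prop_fc(d.n_trials);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapt = it < burn_in;
    double gain = std::min(0.25, 5.0 / std::sqrt((double)it + 10.0));

    // --- per-participant block: (b, u, x1_low, x1_high), 2 sweeps ---
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int p = 0; p < n_p; ++p) {
      int g = grp[p];
      double st = std::exp(ls_blk[p]);
      double bp = b[p], up = u[p], xl = x1l[p], xh = x1h[p];
      double z[DB], dx[DB];
      for (int i = 0; i < DB; ++i) z[i] = R::norm_rand();
      if (am_ok[p]) {
        const double *L = &am_chol[p * DB * DB];
        for (int i = 0; i < DB; ++i) {
          dx[i] = 0.0;
          for (int j = 0; j <= i; ++j) dx[i] += L[i * DB + j] * z[j];
          dx[i] *= st;
        }
      } else {
        for (int i = 0; i < DB; ++i) dx[i] = st * diag_sc[i] * z[i];
      }
      if (model != 2) bp += dx[0];
      if (model != 1) up += dx[1];
      xl += dx[2];
      xh += dx[3];

      double B = sigmoid(model == 2 ? b_shared : bp);
      double q = (model == 1) ? 0.0 : sigmoid(up);
      forward_core(d.h + d.off[p], d.hl + d.off[p], d.hu + d.off[p],
                   d.len[p], B, q, xl, xh, select, d.upd + d.off[p],
                   &prop_fc[d.off[p]], nullptr, nullptr, nullptr);
      double ll_new = lik_weight * loglik_p(d, p, &prop_fc[d.off[p]],
                                            tau[p], nu);
      double lp_new = 0.0, lp_old = 0.0;
      if (model != 2) {
        lp_new += R::dnorm(bp, thB[g], std::sqrt(s2B[g]), 1);
        lp_old += R::dnorm(b[p], thB[g], std::sqrt(s2B[g]), 1);
      }
      if (model != 1) {
        lp_new += R::dnorm(up, thQ[g], std::sqrt(s2Q[g]), 1);
        lp_old += R::dnorm(u[p], thQ[g], std::sqrt(s2Q[g]), 1);
      }
      lp_new += R::dnorm(xl, k[p] * muL[p], sdL[p], 1)
              + R::dnorm(xh, k[p] * muH[p], sdH[p], 1);
      lp_old += R::dnorm(x1l[p], k[p] * muL[p], sdL[p], 1)
              + R::dnorm(x1h[p], k[p] * muH[p], sdH[p], 1);

      double lacc = ll_new + lp_new - ll[p] - lp_old;
      bool acc = std::log(R::unif_rand()) < lacc;
      if (acc) {
        b[p] = bp; u[p] = up; x1l[p] = xl; x1h[p] = xh; ll[p] = ll_new;
        std::copy(&prop_fc[d.off[p]], &prop_fc[d.off[p]] + d.len[p],
                  &fc_est[d.off[p]]);
      }
      if (adapt) ls_blk[p] += gain * ((acc ? 1.0 : 0.0) - targ_blk);
    }

    // accumulate block statistics and refresh proposal covariances
    if (adapt) {
      ++am_n;
      for (int p = 0; p < n_p; ++p) {
        double x[DB] = {b[p], u[p], x1l[p], x1h[p]};
        double *mn = &am_mean[p * DB], *cv = &am_cov[p * DB * DB];
        double delta[DB];
        for (int i = 0; i < DB; ++i) {
          delta[i] = x[i] - mn[i];
          mn[i] += delta[i] / am_n;
        }
        for (int i = 0; i < DB; ++i)
          for (int j = 0; j < DB; ++j)
            cv[i * DB + j] += delta[i] * (x[j] - mn[j]);
      }
      if (am_n >= 100 && it % 25 == 0)
        for (int p = 0; p < n_p; ++p) {
          int was_ok = am_ok[p];
          refresh_chol(p);
          if (!was_ok && am_ok[p]) ls_blk[p] = std::log(1.19);
        }
    }

    // --- shared learning rate (Q_ONLY) ---
    if (model == 2) {
      double bp = b_shared + std::exp(ls_bsh) * R::norm_rand();
      double B = sigmoid(bp);
      double ll_new_tot = 0.0, ll_old_tot = 0.0;
      for (int p = 0; p < n_p; ++p) {
        forward_core(d.h + d.off[p], d.hl + d.off[p], d.hu + d.off[p],
                     d.len[p], B, sigmoid(u[p]), x1l[p], x1h[p], select,
                     d.upd + d.off[p], &prop_fc[d.off[p]],
                     nullptr, nullptr, nullptr);
        ll_new_tot += lik_weight * loglik_p(d, p, &prop_fc[d.off[p]],
                                            tau[p], nu);
        ll_old_tot += ll[p];
      }
      double lacc = ll_new_tot - ll_old_tot
                  + R::dnorm(bp, 0.0, theta_sd, 1)
                  - R::dnorm(b_shared, 0.0, theta_sd, 1);
      bool acc = std::log(R::unif_rand()) < lacc;
      if (acc) {
        b_shared = bp;
        std::copy(prop_fc.begin(), prop_fc.end(), fc_est.begin());
        for (int p = 0; p < n_p; ++p)
          ll[p] = lik_weight * loglik_p(d, p, &fc_est[d.off[p]], tau[p], nu);
      }
      if (adapt) ls_bsh += gain * ((acc ? 1.0 : 0.0) - targ_sc);
    }

    // --- tau_p: random-walk on log scale, cached residuals ---
    for (int p = 0; p < n_p; ++p) {
      double lt_new = std::log(tau[p]) + std::exp(ls_tau[p]) * R::norm_rand();
      double t_new = std::exp(lt_new);
      double ll_new = lik_weight * loglik_p(d, p, &fc_est[d.off[p]],
                                            t_new, nu);
      // half-normal prior on tau + log-Jacobian of the log transform
      double lacc = ll_new - ll[p]
                  + R::dnorm(t_new, 0.0, tau_sd, 1)
                  - R::dnorm(tau[p], 0.0, tau_sd, 1)
                  + lt_new - std::log(tau[p]);
      bool acc = std::log(R::unif_rand()) < lacc;
      if (acc) { tau[p] = t_new; ll[p] = ll_new; }
      if (adapt) ls_tau[p] += gain * ((acc ? 1.0 : 0.0) - targ_sc);
    }

    // --- k_p: conjugate truncated normal (x1 ~ N(k * mu_base, sd_base)) ---
    for (int p = 0; p < n_p; ++p) {
      double prec = 1.0 / (k_sd * k_sd)
                  + muL[p] * muL[p] / (sdL[p] * sdL[p])
                  + muH[p] * muH[p] / (sdH[p] * sdH[p]);
      double mean = (x1l[p] * muL[p] / (sdL[p] * sdL[p])
                   + x1h[p] * muH[p] / (sdH[p] * sdH[p])) / prec;
      k[p] = rtnorm_lower(mean, std::sqrt(1.0 / prec), 0.0);
    }

    // --- group hyper-parameters: conjugate normal / inverse-gamma ---
    for (int g = 0; g < n_g; ++g) {
      int n_in_g = 0;
      double sb = 0.0, sq = 0.0;
      for (int p = 0; p < n_p; ++p) if (grp[p] == g) {
        ++n_in_g; sb += b[p]; sq += u[p];
      }
      if (n_in_g == 0) continue;
      if (model != 2) {
        double v = 1.0 / (1.0 / (theta_sd * theta_sd) + n_in_g / s2B[g]);
        thB[g] = R::rnorm(v * sb / s2B[g], std::sqrt(v));
        double ss = 0.0;
        for (int p = 0; p < n_p; ++p) if (grp[p] == g)
          ss += (b[p] - thB[g]) * (b[p] - thB[g]);
        s2B[g] = 1.0 / R::rgamma(sig_a0 + 0.5 * n_in_g,
                                 1.0 / (sig_b0 + 0.5 * ss));
      }
      if (model != 1) {
        double v = 1.0 / (1.0 / (theta_sd * theta_sd) + n_in_g / s2Q[g]);
        thQ[g] = R::rnorm(v * sq / s2Q[g], std::sqrt(v));
        double ss = 0.0;
        for (int p = 0; p < n_p; ++p) if (grp[p] == g)
          ss += (u[p] - thQ[g]) * (u[p] - thQ[g]);
        s2Q[g] = 1.0 / R::rgamma(sig_a0 + 0.5 * n_in_g,
                                 1.0 / (sig_b0 + 0.5 * ss));
      }
    }

    // --- nu: shared df, random walk on log scale, floor nu > nu_floor ---
    {
      double ln_new = std::log(nu) + std::exp(ls_nu) * R::norm_rand();
      double nu_new = std::exp(ln_new);
      bool acc = false;
      if (nu_new > nu_floor) {
        double ll_new_tot = 0.0, ll_old_tot = 0.0;
        std::vector<double> ll_new(n_p);
        for (int p = 0; p < n_p; ++p) {
          ll_new[p] = lik_weight * loglik_p(d, p, &fc_est[d.off[p]],
                                            tau[p], nu_new);
          ll_new_tot += ll_new[p];
          ll_old_tot += ll[p];
        }
        // inverse-gamma(a0, b0) prior on nu + log-Jacobian
        double lacc = ll_new_tot - ll_old_tot
                    + (-(sig_a0 + 1.0) * ln_new - sig_b0 / nu_new)
                    - (-(sig_a0 + 1.0) * std::log(nu) - sig_b0 / nu)
                    + ln_new - std::log(nu);
        acc = std::log(R::unif_rand()) < lacc;
        if (acc) { nu = nu_new; ll = ll_new; }
      }
      if (adapt) ls_nu += gain * ((acc ? 1.0 : 0.0) - targ_sc);
    }

    // --- record ---
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      int c = 0;
      if (model != 2) for (int g = 0; g < n_g; ++g) {
        out(kept, c++) = thB[g];
        out(kept, c++) = std::sqrt(s2B[g]);
      }
      if (model != 1) for (int g = 0; g < n_g; ++g) {
        out(kept, c++) = thQ[g];
        out(kept, c++) = std::sqrt(s2Q[g]);
      }
      out(kept, c++) = nu;
      if (model == 2) out(kept, c++) = b_shared;
      for (int p = 0; p < n_p; ++p) {
        out(kept, c++) = sigmoid(model == 2 ? b_shared : b[p]);
        out(kept, c++) = model == 1 ? 0.0 : sigmoid(u[p]);
        out(kept, c++) = tau[p];
        out(kept, c++) = k[p];
        out(kept, c++) = x1l[p];
        out(kept, c++) = x1h[p];
      }
      ++kept;
    }
  }
  return List::create(_["draws"] = out);
}

// ---------------------------------------------------------------------------
// Pointwise log-likelihood of retained draws (for WAIC). draws holds
// natural-scale per-participant parameters laid out as in run_chain_cpp
// output; col_map gives, per participant, the columns of B, q, tau, x1l,
// x1h (0-based), and nu_col the shared df column.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix pointwise_loglik_cpp(List data, NumericMatrix draws,
                                   IntegerMatrix col_map, int nu_col,
                                   bool select) {
  Flat d = make_flat(data);
  int S = draws.nrow();
  // count observed trials
  int n_obs = 0;
  for (int t = 0; t < d.n_trials; ++t) if (d.obs[t]) ++n_obs;
  NumericMatrix out(S, n_obs);
  std::vector<double> fc(d.n_trials);
  for (int s = 0; s < S; ++s) {
    double nu = draws(s, nu_col);
    int j = 0;
    for (int p = 0; p < d.n_p; ++p) {
      double B = draws(s, col_map(p, 0)), q = draws(s, col_map(p, 1));
      double tau = draws(s, col_map(p, 2));
      double xl = draws(s, col_map(p, 3)), xh = draws(s, col_map(p, 4));
      forward_core(d.h + d.off[p], d.hl + d.off[p], d.hu + d.off[p],
                   d.len[p], B, q, xl, xh, select, d.upd + d.off[p],
                   &fc[d.off[p]], nullptr, nullptr, nullptr);
      double c0 = lt_const(nu, tau);
      for (int t = 0; t < d.len[p]; ++t) {
        int i = d.off[p] + t;
        if (!d.obs[i]) continue;
        out(s, j++) = c0 + lt_kernel(d.fc[i] - fc[i], nu, tau);
      }
    }
  }
  return out;
}

// 32-bit FNV-1a hash of raw bytes, hex-encoded (config/data fingerprints).
// [[Rcpp::export]]
std::string fnv1a_cpp(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (int i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  char buf[9];
  snprintf(buf, sizeof(buf), "%08x", h);
  return std::string(buf);
}
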