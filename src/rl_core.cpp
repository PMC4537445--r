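// Core per-trial loops for the softmax delta-rule model family:
// likelihood, pre-update choice probabilities, stage simulation, and the
// random-walk Metropolis-within-Gibbs sampler for the hierarchical model.
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double tau_r, tau_p, tau_c, d_c, tau_l, d_l;
  bool stim_st, side_st;
};

// par6 order fixed package-wide: tau_r, tau_p, tau_c, d_c, tau_l, d_l
Pars make_pars(const double *par6, bool stim_st, bool side_st) {
  Pars p;
  p.tau_r = par6[0]; p.tau_p = par6[1];
  p.tau_c = par6[2]; p.d_c = par6[3];
  p.tau_l = par6[4]; p.d_l = par6[5];
  p.stim_st = stim_st; p.side_st = side_st;
  return p;
}

struct State {
  double v[2], c[2], l[2];
  void zero() { v[0]=v[1]=c[0]=c[1]=l[0]=l[1]=0.0; }
};

// x for each stimulus given side of stimulus 0 (0=left, 1=right)
inline void values(const State &st, int side0, double &x0, double &x1) {
  x0 = st.v[0] + st.c[0] + st.l[side0];
  x1 = st.v[1] + st.c[1] + st.l[1 - side0];
}

inline void update(State &st, int chosen, int chosen_side, double reinf,
                   const Pars &p) {
  double tau = reinf > 0 ? p.tau_r : p.tau_p;
  st.v[chosen] += tau * (reinf - st.v[chosen]);
  if (p.stim_st)
    for (int i = 0; i < 2; ++i)
      st.c[i] += p.tau_c * ((i == chosen ? p.d_c : 0.0) - st.c[i]);
  if (p.side_st)
    for (int i = 0; i < 2; ++i)
      st.l[i] += p.tau_l * ((i == chosen_side ? p.d_l : 0.0) - st.l[i]);
}

struct SubjData {
  std::vector<int> chosen, side0, reset;
  std::vector<double> reinf;
};

SubjData unpack_subject(const List &d) {
  SubjData s;
  IntegerVector ch = d["chosen"], s0 = d["side1"], rs = d["reset"];
  NumericVector rf = d["reinf"];
  int n = ch.size();
  s.chosen.resize(n); s.side0.resize(n); s.reset.resize(n); s.reinf.resize(n);
  for (int t = 0; t < n; ++t) {
    s.chosen[t] = ch[t] - 1;   // R passes 1/2
    s.side0[t] = s0[t] - 1;    // side of stimulus 1 (1=left,2=right)
    s.reset[t] = rs[t];
    s.reinf[t] = rf[t];
  }
  return s;
}

double subj_loglik(const SubjData &d, const Pars &p) {
  State st; st.zero();
  double ll = 0.0;
  int n = (int)d.chosen.size();
  for (int t = 0; t < n; ++t) {
    if (d.reset[t]) { st.v[0]=st.v[1]=0.0; st.c[0]=st.c[1]=0.0; }
    double x0, x1;
    values(st, d.side0[t], x0, x1);
    int ch = d.chosen[t];
    double xc = ch == 0 ? x0 : x1, xo = ch == 0 ? x1 : x0;
    ll += -std::log1p(std::exp(xo - xc));
    int chside = ch == 0 ? d.side0[t] : 1 - d.side0[t];
    update(st, ch, chside, d.reinf[t], p);
  }
  return ll;
}

} // namespace

// Log-likelihood of a recorded trial sequence under one parameterization.
// chosen, side1 are 1/2 coded; reinf is +1/-1; reset marks trials before
// which v and c are zeroed (stage starts that are not reversals).
// [[Rcpp::export]]
double rl_loglik_cpp(IntegerVector chosen, IntegerVector side1,
                     NumericVector reinf, IntegerVector reset,
                     NumericVector par6, bool stim_st, bool side_st) {
  List d = List::create(_["chosen"] = chosen, _["side1"] = side1,
                        _["reset"] = reset, _["reinf"] = reinf);
  SubjData s = unpack_subject(d);
  Pars p = make_pars(REAL(par6), stim_st, side_st);
  return subj_loglik(s, p);
}

// Pre-update choice probabilities, one row per trial: P(stim1), P(stim2).
// [[Rcpp::export]]
NumericMatrix rl_probs_cpp(IntegerVector chosen, IntegerVector side1,
                           NumericVector reinf, IntegerVector reset,
                           NumericVector par6, bool stim_st, bool side_st) {
  List d = List::create(_["chosen"] = chosen, _["side1"] = side1,
                        _["reset"] = reset, _["reinf"] = reinf);
  SubjData s = unpack_subject(d);
  Pars p = make_pars(REAL(par6), stim_st, side_st);
  int n = (int)s.chosen.size();
  NumericMatrix out(n, 2);
  State st; st.zero();
  for (int t = 0; t < n; ++t) {
    if (s.reset[t]) { st.v[0]=st.v[1]=0.0; st.c[0]=st.c[1]=0.0; }
    double x0, x1;
    values(st, s.side0[t], x0, x1);
    double p0 = 1.0 / (1.0 + std::exp(x1 - x0));
    out(t, 0) = p0; out(t, 1) = 1.0 - p0;
    int ch = s.chosen[t];
    int chside = ch == 0 ? s.side0[t] : 1 - s.side0[t];
    update(st, ch, chside, s.reinf[t], p);
  }
  return out;
}

// Simulate one stage: sessions of trials_per_session trials run until a
// session reaches the correct-fraction criterion or max_sessions is hit.
// Side assignment is an exactly balanced shuffled vector per session.
// correct_idx is 1 or 2 (which stimulus is currently "correct").
// [[Rcpp::export]]
List rl_simulate_stage_cpp(NumericVector par6, bool stim_st, bool side_st,
                           int correct_idx, double p_valid,
                           int trials_per_session, double criterion,
                           int max_sessions, NumericVector init_v,
                           NumericVector init_c, NumericVector init_l) {
  Pars p = make_pars(REAL(par6), stim_st, side_st);
  State st;
  st.v[0] = init_v[0]; st.v[1] = init_v[1];
  st.c[0] = init_c[0]; st.c[1] = init_c[1];
  st.l[0] = init_l[0]; st.l[1] = init_l[1];
  int T = trials_per_session, half = T / 2;
  std::vector<int> session, trial, side0v, chosenv;
  std::vector<double> reinfv;
  int n_sessions = 0;
  bool attained = false;
  std::vector<int> sides(T);
  for (int ses = 1; ses <= max_sessions; ++ses) {
    n_sessions = ses;
    for (int i = 0; i < T; ++i) sides[i] = i < half ? 0 : 1;
    for (int i = T - 1; i > 0; --i) { // Fisher-Yates using R's RNG
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(sides[i], sides[j]);
    }
    int n_correct = 0;
    for (int t = 0; t < T; ++t) {
      int s0 = sides[t];
      double x0, x1;
      values(st, s0, x0, x1);
      double p0 = 1.0 / (1.0 + std::exp(x1 - x0));
      int ch = unif_rand() < p0 ? 0 : 1;
      bool is_corr = (ch == correct_idx - 1);
      if (is_corr) ++n_correct;
      double pr = is_corr ? p_valid : 1.0 - p_valid;
      double reinf = unif_rand() < pr ? 1.0 : -1.0;
      int chside = ch == 0 ? s0 : 1 - s0;
      update(st, ch, chside, reinf, p);
      session.push_back(ses);
      trial.push_back(t + 1);
      side0v.push_back(s0 + 1);
      chosenv.push_back(ch + 1);
      reinfv.push_back(reinf);
    }
    if ((double)n_correct / T >= criterion) { attained = true; break; }
  }
  return List::create(
      _["session"] = wrap(session), _["trial"] = wrap(trial),
      _["side1"] = wrap(side0v), _["chosen"] = wrap(chosenv),
      _["reinf"] = wrap(reinfv),
      _["v"] = NumericVector::create(st.v[0], st.v[1]),
      _["c"] = NumericVector::create(st.c[0], st.c[1]),
      _["l"] = NumericVector::create(st.l[0], st.l[1]),
      _["n_sessions"] = n_sessions, _["attained"] = attained);
}

namespace {

// slot codes per fitted parameter: 0 tau (both valences), 1 tau_r, 2 tau_p,
// 3 tau_c, 4 d_c, 5 tau_l, 6 d_l
void theta_to_par6(const double *th, const int *slot, int z, double *par6) {
  for (int i = 0; i < 6; ++i) par6[i] = 0.0;
  for (int j = 0; j < z; ++j) {
    switch (slot[j]) {
      case 0: par6[0] = th[j]; par6[1] = th[j]; break;
      case 1: par6[0] = th[j]; break;
      case 2: par6[1] = th[j]; break;
      case 3: par6[2] = th[j]; break;
      case 4: par6[3] = th[j]; break;
      case 5: par6[4] = th[j]; break;
      case 6: par6[5] = th[j]; break;
    }
  }
}

inline double log_trunc_const(double mu, double sig, bool rate) {
  // log of the truncation mass: rate params live on [0,1], maxima on [0,inf)
  double z;
  if (rate)
    z = R::pnorm(1.0, mu, sig, 1, 0) - R::pnorm(0.0, mu, sig, 1, 0);
  else
    z = R::pnorm(0.0, mu, sig, 0, 0);
  return std::log(z);
}

inline double log_mu_prior(double mu, bool rate, double beta_a, double beta_b,
                           double gam_shape, double gam_scale) {
  return rate ? R::dbeta(mu, beta_a, beta_b, 1)
              : R::dgamma(mu, gam_shape, gam_scale, 1);
}

} // namespace

// Metropolis-within-Gibbs sampler for the hierarchical model:
// theta[s,j] ~ Normal(mu[g(s),j], sigma[j]) truncated to the parameter's
// support; mu rates ~ Beta(beta_a, beta_b); mu maxima ~ Gamma(gam_shape,
// scale gam_scale); sigma ~ half-Cauchy(0, cauchy_scale).
// Proposal scales adapt during warmup only. Returns kept draws and the
// per-draw total data log-likelihood.
// [[Rcpp::export]]
List rl_hier_sampler_cpp(List subj_data, IntegerVector group, int n_groups,
                         bool stim_st, bool side_st, IntegerVector slot,
                         LogicalVector is_rate, NumericMatrix init_theta,
                         NumericMatrix init_mu, NumericVector init_sigma,
                         int warmup, int iter, double beta_a, double beta_b,
                         double gam_shape, double gam_scale,
                         double cauchy_scale, bool prior_only) {
  int S = subj_data.size(), z = slot.size(), G = n_groups;
  std::vector<SubjData> dat(S);
  if (!prior_only)
    for (int s = 0; s < S; ++s) dat[s] = unpack_subject(subj_data[s]);
  std::vector<int> grp(S);
  for (int s = 0; s < S; ++s) grp[s] = group[s] - 1;
  std::vector<int> slt(z);
  for (int j = 0; j < z; ++j) slt[j] = slot[j];

  std::vector<std::vector<double> > theta(S, std::vector<double>(z));
  std::vector<std::vector<double> > mu(G, std::vector<double>(z));
  std::vector<double> sigma(z);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < z; ++j) theta[s][j] = init_theta(s, j);
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < z; ++j) mu[g][j] = init_mu(g, j);
  for (int j = 0; j < z; ++j) sigma[j] = init_sigma[j];

  std::vector<double> ll(S, 0.0);
  double par6[6];
  if (!prior_only)
    for (int s = 0; s < S; ++s) {
      theta_to_par6(&theta[s][0], &slt[0], z, par6);
      ll[s] = subj_loglik(dat[s], make_pars(par6, stim_st, side_st));
    }

  // adaptive proposal scales, tuned during warmup by Robbins-Monro on
  // the Metropolis acceptance probability (target 0.44)
  std::vector<std::vector<double> > st_theta(S, std::vector<double>(z, 0.15));
  std::vector<std::vector<double> > st_mu(G, std::vector<double>(z, 0.15));
  std::vector<double> st_sigma(z, 0.4);
  std::vector<double> st_scale(z, 0.4);
  const double acc_target = 0.44;

  int total = warmup + iter;
  NumericMatrix out_theta(iter, S * z), out_mu(iter, G * z),
      out_sigma(iter, z);
  NumericVector out_ll(iter);

  for (int it = 0; it < total; ++it) {
    double gamma = 0.5 / std::pow(it + 1.0, 0.6);
    // --- subject-level parameters ---
    for (int s = 0; s < S; ++s) {
      int g = grp[s];
      for (int j = 0; j < z; ++j) {
        double cur = theta[s][j];
        double prop = cur + st_theta[s][j] * norm_rand();
        bool ok = is_rate[j] ? (prop >= 0.0 && prop <= 1.0) : (prop >= 0.0);
        if (!ok) {
          if (it < warmup)
            st_theta[s][j] *= std::exp(gamma * (0.0 - acc_target));
          continue;
        }
        double ll_new = 0.0;
        if (!prior_only) {
          double old = theta[s][j];
          theta[s][j] = prop;
          theta_to_par6(&theta[s][0], &slt[0], z, par6);
          ll_new = subj_loglik(dat[s], make_pars(par6, stim_st, side_st));
          theta[s][j] = old;
        }
        double d = (ll_new - ll[s]) +
                   R::dnorm(prop, mu[g][j], sigma[j], 1) -
                   R::dnorm(cur, mu[g][j], sigma[j], 1);
        double alpha = d >= 0 ? 1.0 : std::exp(d);
        if (std::log(unif_rand()) < d) {
          theta[s][j] = prop;
          ll[s] = ll_new;
        }
        if (it < warmup)
          st_theta[s][j] *= std::exp(gamma * (alpha - acc_target));
      }
    }
    // --- group means and shared SDs ---
    // these updates cost no likelihood evaluation, so several repeats per
    // sweep sharpen mixing of the hierarchy for free
    for (int rep = 0; rep < 5; ++rep) {
    for (int g = 0; g < G; ++g) {
      for (int j = 0; j < z; ++j) {
        double cur = mu[g][j];
        double prop = cur + st_mu[g][j] * norm_rand();
        bool ok = is_rate[j] ? (prop > 0.0 && prop < 1.0) : (prop > 0.0);
        if (!ok) {
          if (it < warmup)
            st_mu[g][j] *= std::exp(gamma * (0.0 - acc_target));
          continue;
        }
        double d = log_mu_prior(prop, is_rate[j], beta_a, beta_b, gam_shape,
                                gam_scale) -
                   log_mu_prior(cur, is_rate[j], beta_a, beta_b, gam_shape,
                                gam_scale);
        int ng = 0;
        for (int s = 0; s < S; ++s) {
          if (grp[s] != g) continue;
          ++ng;
          d += R::dnorm(theta[s][j], prop, sigma[j], 1) -
               R::dnorm(theta[s][j], cur, sigma[j], 1);
        }
        d -= ng * (log_trunc_const(prop, sigma[j], is_rate[j]) -
                   log_trunc_const(cur, sigma[j], is_rate[j]));
        double alpha = d >= 0 ? 1.0 : std::exp(d);
        if (std::log(unif_rand()) < d) mu[g][j] = prop;
        if (it < warmup)
          st_mu[g][j] *= std::exp(gamma * (alpha - acc_target));
      }
    }
    // --- shared SDs (log-scale random walk with Jacobian) ---
    for (int j = 0; j < z; ++j) {
      double cur = sigma[j];
      double prop = cur * std::exp(st_sigma[j] * norm_rand());
      double d = std::log(R::dcauchy(prop, 0.0, cauchy_scale, 0)) -
                 std::log(R::dcauchy(cur, 0.0, cauchy_scale, 0)) +
                 std::log(prop) - std::log(cur);
      for (int s = 0; s < S; ++s) {
        int g = grp[s];
        d += R::dnorm(theta[s][j], mu[g][j], prop, 1) -
             R::dnorm(theta[s][j], mu[g][j], cur, 1);
        d -= log_trunc_const(mu[g][j], prop, is_rate[j]) -
             log_trunc_const(mu[g][j], cur, is_rate[j]);
      }
      double alpha = d >= 0 ? 1.0 : std::exp(d);
      if (std::log(unif_rand()) < d) sigma[j] = prop;
      if (it < warmup)
        st_sigma[j] *= std::exp(gamma * (alpha - acc_target));
    }
    } // hyper repeats
    // --- joint scale move: rescale sigma and the subject deviations
    // together (decouples the hierarchical funnel) ---
    for (int j = 0; j < z; ++j) {
      double f = std::exp(st_scale[j] * norm_rand());
      double sig_new = sigma[j] * f;
      bool ok = true;
      std::vector<double> th_new(S);
      for (int s = 0; s < S; ++s) {
        double m = mu[grp[s]][j];
        th_new[s] = m + f * (theta[s][j] - m);
        if (th_new[s] < 0.0 || (is_rate[j] && th_new[s] > 1.0)) {
          ok = false; break;
        }
      }
      double alpha = 0.0;
      if (ok) {
        double d = std::log(R::dcauchy(sig_new, 0.0, cauchy_scale, 0)) -
                   std::log(R::dcauchy(sigma[j], 0.0, cauchy_scale, 0)) +
                   (S + 1) * std::log(f);
        std::vector<double> ll_new(S, 0.0);
        for (int s = 0; s < S; ++s) {
          double m = mu[grp[s]][j];
          d += R::dnorm(th_new[s], m, sig_new, 1) -
               R::dnorm(theta[s][j], m, sigma[j], 1);
          d -= log_trunc_const(m, sig_new, is_rate[j]) -
               log_trunc_const(m, sigma[j], is_rate[j]);
          if (!prior_only) {
            double old = theta[s][j];
            theta[s][j] = th_new[s];
            theta_to_par6(&theta[s][0], &slt[0], z, par6);
            ll_new[s] = subj_loglik(dat[s], make_pars(par6, stim_st, side_st));
            theta[s][j] = old;
            d += ll_new[s] - ll[s];
          }
        }
        alpha = d >= 0 ? 1.0 : std::exp(d);
        if (std::log(unif_rand()) < d) {
          sigma[j] = sig_new;
          for (int s = 0; s < S; ++s) theta[s][j] = th_new[s];
          if (!prior_only) for (int s = 0; s < S; ++s) ll[s] = ll_new[s];
        }
      }
      if (it < warmup)
        st_scale[j] *= std::exp(gamma * (alpha - acc_target));
    }
    // --- record ---
    if (it >= warmup) {
      int k = it - warmup;
      for (int s = 0; s < S; ++s)
        for (int j = 0; j < z; ++j) out_theta(k, s * z + j) = theta[s][j];
      for (int g = 0; g < G; ++g)
        for (int j = 0; j < z; ++j) out_mu(k, g * z + j) = mu[g][j];
      for (int j = 0; j < z; ++j) out_sigma(k, j) = sigma[j];
      double tot = 0.0;
      for (int s = 0; s < S; ++s) tot += ll[s];
      out_ll[k] = tot;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["theta"] = out_theta, _["mu"] = out_mu,
                      _["sigma"] = out_sigma, _["loglik"] = out_ll);
}
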