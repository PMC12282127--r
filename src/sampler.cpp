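#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-segment log-likelihood of the proportional-odds Weibull survival model.
//
// Base survival  S0(t) = exp(-exp(th1) * t^th2)
// Segment odds   S/(1-S) = exp(-eta) * S0/(1-S0),  eta = v_i (+ beta * x_i)
// so             S_i(t) = a*S0 / (1 + (a-1)*S0),   a = exp(-eta)
// and            f_i(t) = a*f0 / (1 + (a-1)*S0)^2, f0 = exp(th1)*th2*t^(th2-1)*S0
//
// eta is clamped to +-30: beyond that the odds factor under- or overflows
// double precision with no change in the ordering of states.
static inline double seg_ll(double eta, int delta, double t, double lt,
                            double th1, double th2, double lth2) {
  if (eta > 30.0) eta = 30.0;
  if (eta < -30.0) eta = -30.0;
  double H = std::exp(th1 + th2 * lt); // cumulative hazard of base law
  if (H > 700.0) H = 700.0;            // S0 underflows; cap keeps ll finite
  double S0 = std::exp(-H);
  double a = std::exp(-eta);
  double l1p = std::log1p((a - 1.0) * S0);
  if (delta == 1) {
    double ll = -eta + th1 + lth2 + (th2 - 1.0) * lt - H - 2.0 * l1p;
    return R_FINITE(ll) ? ll : R_NegInf;
  }
  double ll = -eta - H - l1p;
  return R_FINITE(ll) ? ll : R_NegInf;
}

static double total_ll(const IntegerVector& delta, const NumericVector& t,
                       const NumericVector& lt, const NumericVector& x,
                       const NumericVector& v, double beta,
                       double th1, double th2, double lth2) {
  double s = 0.0;
  int m = delta.size();
  for (int i = 0; i < m; ++i) {
    s += seg_ll(v[i] + beta * x[i], delta[i], t[i], lt[i], th1, th2, lth2);
    if (s == R_NegInf) return R_NegInf;
  }
  return s;
}

// Metropolis-within-Gibbs sampler for one chain.
//
// Single-site random-walk updates for the frailties v_i (acceptance uses the
// segment likelihood plus the prior full conditional: N(0, tau2) under the
// IID prior, N(mean of neighbours, tau2/e_i+) under the ICAR prior), a joint
// random-walk update for (th1, log th2[, beta]) and a conjugate Gamma update
// for the precision tau^-2.  Proposal scales adapt during burn-in only.
// Uses R's RNG, so results are reproducible under set.seed().
//
// adj is a 0-based CSR neighbour list (ptr length m+1, idx concatenated
// neighbours); comp gives the 0-based connected-component id of each segment
// (used for per-component sum-to-zero recentring under ICAR).
// [[Rcpp::export]]
List mcmc_chain(IntegerVector delta, NumericVector t, NumericVector x,
                bool use_beta, IntegerVector adj_ptr, IntegerVector adj_idx,
                bool icar, IntegerVector comp, int ncomp,
                List prior, int iter, int burnin, int thin,
                NumericVector init) {
  int m = delta.size();
  NumericVector lt(m);
  for (int i = 0; i < m; ++i) lt[i] = std::log(t[i]);

  double th1_m = prior["theta1_mean"], th1_s = prior["theta1_sd"];
  double lth2_m = prior["log_theta2_mean"], lth2_s = prior["log_theta2_sd"];
  double beta_m = prior["beta_mean"], beta_s = prior["beta_sd"];
  double prec_a = prior["prec_shape"], prec_b = prior["prec_rate"];

  double th1 = init[0], lth2 = init[1], beta = use_beta ? init[2] : 0.0;
  double prec = init[3];
  double th2 = std::exp(lth2);
  NumericVector v(m);
  for (int i = 0; i < m; ++i) v[i] = init[4 + i];

  // cache per-segment log-likelihood at current state
  NumericVector ll(m);
  for (int i = 0; i < m; ++i)
    ll[i] = seg_ll(v[i] + beta * x[i], delta[i], t[i], lt[i], th1, th2, lth2);

  // adaptive proposal scales
  NumericVector sv(m, 0.5);
  double sg = 0.1;
  IntegerVector acc_v(m);
  int acc_g = 0, try_g = 0;
  long acc_v_post = 0, try_v_post = 0;
  int acc_g_post = 0, try_g_post = 0;

  int nkeep = (iter - burnin) / thin;
  NumericVector d_th1(nkeep), d_th2(nkeep), d_beta(nkeep), d_tau2(nkeep),
      d_ll(nkeep);
  NumericMatrix d_v(nkeep, m);

  // rank of the ICAR improper precision (per-component sum constraint)
  double prec_rank = icar ? (double)(m - ncomp) : (double)m;
  int keep = 0;
  const int batch = 50;

  for (int it = 0; it < iter; ++it) {
    // --- frailty updates (single site) ---
    for (int i = 0; i < m; ++i) {
      double cur = v[i];
      double prop = cur + norm_rand() * sv[i];
      double pll = seg_ll(prop + beta * x[i], delta[i], t[i], lt[i],
                          th1, th2, lth2);
      double dprior;
      if (icar) {
        int e = adj_ptr[i + 1] - adj_ptr[i];
        double nb = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nb += v[adj_idx[k]];
        double mu = e > 0 ? nb / e : 0.0;
        double pe = prec * (e > 0 ? e : 1);
        dprior = -0.5 * pe * ((prop - mu) * (prop - mu) -
                              (cur - mu) * (cur - mu));
      } else {
        dprior = -0.5 * prec * (prop * prop - cur * cur);
      }
      double lr = pll - ll[i] + dprior;
      if (lr >= 0 || std::log(unif_rand()) < lr) {
        v[i] = prop;
        ll[i] = pll;
        acc_v[i]++;
        if (it >= burnin) acc_v_post++;
      }
      if (it >= burnin) try_v_post++;
    }

    // --- per-component sum-to-zero recentring (ICAR identifiability) ---
    if (icar) {
      std::vector<double> cm(ncomp, 0.0);
      std::vector<int> cn(ncomp, 0);
      for (int i = 0; i < m; ++i) { cm[comp[i]] += v[i]; cn[comp[i]]++; }
      for (int c = 0; c < ncomp; ++c) cm[c] /= cn[c];
      bool moved = false;
      for (int i = 0; i < m; ++i) {
        if (cm[comp[i]] != 0.0) { v[i] -= cm[comp[i]]; moved = true; }
      }
      if (moved) {
        for (int i = 0; i < m; ++i)
          ll[i] = seg_ll(v[i] + beta * x[i], delta[i], t[i], lt[i],
                         th1, th2, lth2);
      }
    }

    // --- joint random walk on (th1, log th2 [, beta]) ---
    {
      double p1 = th1 + norm_rand() * sg;
      double p2 = lth2 + norm_rand() * sg;
      double pb = use_beta ? beta + norm_rand() * sg : 0.0;
      double pth2 = std::exp(p2);
      double cur_tot = 0.0;
      for (int i = 0; i < m; ++i) cur_tot += ll[i];
      double prop_tot = total_ll(delta, t, lt, x, v, pb, p1, pth2, p2);
      double dpr =
          -0.5 * ((p1 - th1_m) * (p1 - th1_m) - (th1 - th1_m) * (th1 - th1_m)) /
              (th1_s * th1_s) -
          0.5 * ((p2 - lth2_m) * (p2 - lth2_m) -
                 (lth2 - lth2_m) * (lth2 - lth2_m)) /
              (lth2_s * lth2_s);
      if (use_beta)
        dpr += -0.5 * ((pb - beta_m) * (pb - beta_m) -
                       (beta - beta_m) * (beta - beta_m)) /
               (beta_s * beta_s);
      double lr = prop_tot - cur_tot + dpr;
      try_g++;
      if (it >= burnin) try_g_post++;
      if (R_FINITE(prop_tot) && (lr >= 0 || std::log(unif_rand()) < lr)) {
        th1 = p1; lth2 = p2; th2 = pth2; beta = pb;
        for (int i = 0; i < m; ++i)
          ll[i] = seg_ll(v[i] + beta * x[i], delta[i], t[i], lt[i],
                         th1, th2, lth2);
        acc_g++;
        if (it >= burnin) acc_g_post++;
      }
    }

    // --- conjugate Gamma update for the precision tau^-2 ---
    {
      double q;
      if (icar) {
        q = 0.0; // sum over undirected edges of (v_i - v_j)^2
        for (int i = 0; i < m; ++i)
          for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
            int j = adj_idx[k];
            if (j > i) { double d = v[i] - v[j]; q += d * d; }
          }
      } else {
        q = 0.0;
        for (int i = 0; i < m; ++i) q += v[i] * v[i];
      }
      prec = R::rgamma(prec_a + 0.5 * prec_rank, 1.0 / (prec_b + 0.5 * q));
    }

    // --- burn-in adaptation (Roberts-Rosenthal batch scheme) ---
    if (it < burnin && ((it + 1) % batch == 0)) {
      double step = std::min(0.1, 1.0 / std::sqrt((double)(it + 1) / batch));
      for (int i = 0; i < m; ++i) {
        double rate = (double)acc_v[i] / batch;
        sv[i] *= std::exp(rate > 0.44 ? step : -step);
        if (sv[i] < 1e-3) sv[i] = 1e-3;
        if (sv[i] > 10.0) sv[i] = 10.0;
        acc_v[i] = 0;
      }
      double rg = (double)acc_g / try_g;
      sg *= std::exp(rg > 0.234 ? step : -step);
      if (sg < 1e-4) sg = 1e-4;
      if (sg > 5.0) sg = 5.0;
      acc_g = 0; try_g = 0;
    }

    // --- record ---
    if (it >= burnin && ((it - burnin) % thin == 0) && keep < nkeep) {
      d_th1[keep] = th1;
      d_th2[keep] = th2;
      d_beta[keep] = beta;
      d_tau2[keep] = 1.0 / prec;
      double tot = 0.0;
      for (int i = 0; i < m; ++i) tot += ll[i];
      d_ll[keep] = tot;
      for (int i = 0; i < m; ++i) d_v(keep, i) = v[i];
      keep++;
    }
  }

  return List::create(
      _["theta1"] = d_th1, _["theta2"] = d_th2, _["beta"] = d_beta,
      _["tau2"] = d_tau2, _["loglik"] = d_ll, _["v"] = d_v,
      _["accept_frailty"] = try_v_post > 0 ? (double)acc_v_post / try_v_post
                                           : NA_REAL,
      _["accept_global"] = try_g_post > 0 ? (double)acc_g_post / try_g_post
                                          : NA_REAL);
}

// Total model log-likelihood for fixed parameters (used for DIC and tests).
// [[Rcpp::export]]
double loglik_state(IntegerVector delta, NumericVector t, NumericVector x,
                    NumericVector v, double beta, double th1, double th2) {
  NumericVector lt(t.size());
  for (int i = 0; i < t.size(); ++i) lt[i] = std::log(t[i]);
  return total_ll(delta, t, lt, x, v, beta, th1, th2, std::log(th2));
}

// Population survival curves: for each posterior draw, the segment-averaged
// survival S_bar(t) = mean_i S_i(t) over a time grid.  Returns a
// ndraw x ngrid matrix.
// [[Rcpp::export]]
NumericMatrix population_curves(NumericVector th1, NumericVector th2,
                                NumericVector beta, NumericMatrix v,
                                NumericVector x, NumericVector grid) {
  int nd = th1.size(), ng = grid.size(), m = v.ncol();
  NumericMatrix out(nd, ng);
  for (int d = 0; d < nd; ++d) {
    double e1 = std::exp(th1[d]);
    for (int g = 0; g < ng; ++g) {
      double S0 = std::exp(-e1 * std::pow(grid[g], th2[d]));
      double s = 0.0;
      for (int i = 0; i < m; ++i) {
        double eta = v(d, i) + beta[d] * x[i];
        if (eta > 30.0) eta = 30.0;
        if (eta < -30.0) eta = -30.0;
        double a = std::exp(-eta);
        s += a * S0 / (1.0 + (a - 1.0) * S0);
      }
      out(d, g) = s / m;
    }
  }
  return out;
}
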