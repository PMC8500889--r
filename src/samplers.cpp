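#include <Rcpp.h>
using namespace Rcpp;

// Exemplar-model predictions and adaptive Metropolis-within-Gibbs samplers for
// the original exemplar model and its latent-mixture extension.  Similarities
// are powers of s in the number of mismatching cues; predictions divide out
// s^(min mismatch) per probe so weights stay in [0,1] and the s -> 0 limit
// (mean criterion over minimally mismatching exemplars) is reached without
// underflow.

static const double LOG_2PI = 1.8378770664093454836;

// predictions for all probes at one s value.
// mism: n_probe x n_ex mismatch counts, rowmin: per-probe minimum mismatch.
static void predict_at_s(const IntegerMatrix &mism, const IntegerVector &rowmin,
                         const NumericVector &crit, double s, int dmax,
                         std::vector<double> &out) {
  std::vector<double> powtab(dmax + 1);
  powtab[0] = 1.0;
  for (int d = 1; d <= dmax; ++d) powtab[d] = powtab[d - 1] * s;
  const int n = mism.nrow(), k = mism.ncol();
  for (int i = 0; i < n; ++i) {
    double num = 0.0, den = 0.0;
    const int mm = rowmin[i];
    for (int j = 0; j < k; ++j) {
      const double w = powtab[mism(i, j) - mm];
      den += w;
      num += w * crit[j];
    }
    out[i] = num / den; // den >= 1 by construction
  }
}

static IntegerVector row_mins(const IntegerMatrix &m) {
  IntegerVector out(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    int mn = m(i, 0);
    for (int j = 1; j < m.ncol(); ++j) if (m(i, j) < mn) mn = m(i, j);
    out[i] = mn;
  }
  return out;
}

static int max_entry(const IntegerMatrix &m) {
  int mx = 0;
  for (int i = 0; i < m.length(); ++i) if (m[i] > mx) mx = m[i];
  return mx;
}

// reflect a proposal into [0, 1]
static double reflect01(double x) {
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
  return x;
}

static double ldnorm_prec(double y, double mu, double tau) {
  const double r = y - mu;
  return 0.5 * (std::log(tau) - LOG_2PI) - 0.5 * tau * r * r;
}

static double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  const double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// batch adaptation of a random-walk scale toward acceptance in [0.25, 0.6]
static void adapt_scale(double &sd, int accepted, int batch) {
  const double r = (double)accepted / (double)batch;
  if (r < 0.05)      sd /= 5.0;
  else if (r < 0.15) sd /= 3.0;
  else if (r < 0.25) sd /= 1.5;
  else if (r > 0.85) sd *= 5.0;
  else if (r > 0.70) sd *= 3.0;
  else if (r > 0.60) sd *= 1.5;
  if (sd < 1e-12) sd = 1e-12;
  if (sd > 5.0)   sd = 5.0;
}

// [[Rcpp::export]]
List mcmc_original_cpp(IntegerMatrix mism, NumericVector crit, NumericVector y,
                       int chains, int draws, int burn_in, int adapt, int thin,
                       double tau_shape, double tau_rate) {
  const int n = y.size();
  const IntegerVector rowmin = row_mins(mism);
  const int dmax = max_entry(mism);
  NumericMatrix s_out(draws, chains), tau_out(draws, chains);
  NumericVector prop_sd_out(chains), acc_out(chains);
  std::vector<double> pred(n);

  for (int ch = 0; ch < chains; ++ch) {
    double s = R::runif(0.05, 0.95);
    predict_at_s(mism, rowmin, crit, s, dmax, pred);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) { const double r = y[i] - pred[i]; sse += r * r; }
    double tau = 1.0;
    double sd = 0.1;
    int acc_batch = 0, batch_n = 0, acc_total = 0, n_after = 0;
    const int total = adapt + burn_in + draws * thin;
    std::vector<double> pred_prop(n);

    for (int it = 0; it < total; ++it) {
      // tau | s  (conjugate gamma in the precision)
      tau = R::rgamma(tau_shape + 0.5 * n, 1.0 / (tau_rate + 0.5 * sse));
      // s | tau  (random walk with reflection at the bounds)
      const double s_prop = reflect01(s + R::norm_rand() * sd);
      predict_at_s(mism, rowmin, crit, s_prop, dmax, pred_prop);
      double sse_prop = 0.0;
      for (int i = 0; i < n; ++i) { const double r = y[i] - pred_prop[i]; sse_prop += r * r; }
      if (std::log(R::unif_rand()) < -0.5 * tau * (sse_prop - sse)) {
        s = s_prop; sse = sse_prop;
        ++acc_batch;
        if (it >= adapt) ++acc_total;
      }
      ++batch_n;
      if (it >= adapt) ++n_after;
      if (it < adapt && batch_n == 50) {
        adapt_scale(sd, acc_batch, batch_n);
        acc_batch = 0; batch_n = 0;
      }
      const int post = it - adapt - burn_in;
      if (post >= 0 && (post + 1) % thin == 0) {
        const int d = post / thin;
        s_out(d, ch) = s;
        tau_out(d, ch) = tau;
      }
    }
    prop_sd_out[ch] = sd;
    acc_out[ch] = n_after > 0 ? (double)acc_total / n_after : NA_REAL;
  }
  return List::create(_["s"] = s_out, _["tau"] = tau_out,
                      _["prop_sd"] = prop_sd_out, _["accept_rate"] = acc_out);
}

// Latent-mixture sampler with explicit data augmentation: the per-trial
// recall indicators z_t are sampled from their full conditionals, after
// which phi (Beta) and the precisions (Gamma) have conjugate updates and
// only s needs a Metropolis step.  The marginal posterior over
// (s, phi, tau0, tau1) is identical to marginalizing z out, but the
// conjugate updates also mix well when the recall component is nearly
// empty and tau1 is prior-dominated.
// [[Rcpp::export]]
List mcmc_mixture_cpp(IntegerMatrix mism, NumericVector crit, NumericVector y,
                      LogicalVector trained, NumericVector ct,
                      int chains, int draws, int burn_in, int adapt, int thin,
                      double tau_shape, double tau_rate) {
  const int n = y.size();
  const IntegerVector rowmin = row_mins(mism);
  const int dmax = max_entry(mism);
  NumericMatrix s_out(draws, chains), phi_out(draws, chains),
                tau0_out(draws, chains), tau1_out(draws, chains);
  NumericVector prop_sd_out(chains), acc_out(chains);
  std::vector<double> pred(n), pred_prop(n);
  std::vector<int> z(n, 0);

  for (int ch = 0; ch < chains; ++ch) {
    double s = R::runif(0.05, 0.95), phi = R::runif(0.05, 0.95);
    double tau0 = 1.0, tau1 = 1.0;
    predict_at_s(mism, rowmin, crit, s, dmax, pred);
    double sd = 0.1;
    int acc_batch = 0, batch_n = 0;
    long acc_total = 0, n_after = 0;
    const int total = adapt + burn_in + draws * thin;

    for (int it = 0; it < total; ++it) {
      // z_t | rest for trained trials (posterior mixture responsibility)
      int n1 = 0;
      double sse0 = 0.0, sse1 = 0.0;
      const double lphi = std::log(phi), l1mphi = std::log1p(-phi);
      for (int i = 0; i < n; ++i) {
        const double r0 = y[i] - pred[i];
        if (trained[i]) {
          const double la = lphi + ldnorm_prec(y[i], ct[i], tau1);
          const double lb = l1mphi + ldnorm_prec(y[i], pred[i], tau0);
          const double resp = 1.0 / (1.0 + std::exp(lb - la));
          z[i] = (R::unif_rand() < resp) ? 1 : 0;
          if (z[i] == 1) {
            const double r1 = y[i] - ct[i];
            sse1 += r1 * r1;
            ++n1;
          } else {
            sse0 += r0 * r0;
          }
        } else {
          z[i] = 0;
          sse0 += r0 * r0;
        }
      }
      int n_trained = 0;
      for (int i = 0; i < n; ++i) if (trained[i]) ++n_trained;
      // phi | z  (uniform prior = Beta(1, 1))
      phi = R::rbeta(1.0 + n1, 1.0 + n_trained - n1);
      if (phi <= 0) phi = 1e-12;
      if (phi >= 1) phi = 1 - 1e-12;
      // precisions | z  (conjugate gamma)
      const int n0 = n - n1;
      tau0 = R::rgamma(tau_shape + 0.5 * n0, 1.0 / (tau_rate + 0.5 * sse0));
      tau1 = R::rgamma(tau_shape + 0.5 * n1, 1.0 / (tau_rate + 0.5 * sse1));
      // s | z, tau0  (random walk on the judgment-component likelihood)
      {
        const double s_p = reflect01(s + R::norm_rand() * sd);
        predict_at_s(mism, rowmin, crit, s_p, dmax, pred_prop);
        double sse0_cur = 0.0, sse0_prop = 0.0;
        for (int i = 0; i < n; ++i) {
          if (z[i] == 0) {
            const double rc = y[i] - pred[i], rp = y[i] - pred_prop[i];
            sse0_cur += rc * rc;
            sse0_prop += rp * rp;
          }
        }
        if (std::log(R::unif_rand()) < -0.5 * tau0 * (sse0_prop - sse0_cur)) {
          s = s_p;
          pred.swap(pred_prop);
          ++acc_batch;
          if (it >= adapt) ++acc_total;
        }
      }
      ++batch_n;
      if (it >= adapt) ++n_after;
      if (it < adapt && batch_n == 50) {
        adapt_scale(sd, acc_batch, batch_n);
        acc_batch = 0; batch_n = 0;
      }
      const int post = it - adapt - burn_in;
      if (post >= 0 && (post + 1) % thin == 0) {
        const int d = post / thin;
        s_out(d, ch) = s;
        phi_out(d, ch) = phi;
        tau0_out(d, ch) = tau0;
        tau1_out(d, ch) = tau1;
      }
    }
    prop_sd_out[ch] = sd;
    acc_out[ch] = n_after > 0 ? (double)acc_total / n_after : NA_REAL;
  }
  return List::create(_["s"] = s_out, _["phi"] = phi_out,
                      _["tau0"] = tau0_out, _["tau1"] = tau1_out,
                      _["prop_sd"] = prop_sd_out, _["accept_rate"] = acc_out);
}

// [[Rcpp::export]]
NumericMatrix predict_draws_cpp(NumericVector s_draws, IntegerMatrix mism,
                                NumericVector crit) {
  const int nd = s_draws.size(), n = mism.nrow();
  const IntegerVector rowmin = row_mins(mism);
  const int dmax = max_entry(mism);
  NumericMatrix out(nd, n);
  std::vector<double> pred(n);
  for (int d = 0; d < nd; ++d) {
    predict_at_s(mism, rowmin, crit, s_draws[d], dmax, pred);
    for (int i = 0; i < n; ++i) out(d, i) = pred[i];
  }
  return out;
}

// Per-draw conditional density of phi at 0 given the other parameters:
//   p(phi = 0 | theta, D) = prod_t f0_t / Int_0^1 prod_t [phi f1_t + (1-phi) f0_t] dphi
// with the integral over the Uniform(0,1) prior done by Gauss-Legendre
// quadrature (the integrand is a polynomial of degree n_trained in phi, so
// the quadrature is exact for enough nodes).  Untrained trials cancel.
// Returns the vector of per-draw log conditional densities.
// [[Rcpp::export]]
NumericVector phi_cond_logdens_cpp(NumericVector s_draws, NumericVector tau0_draws,
                                   NumericVector tau1_draws, IntegerMatrix mism_tr,
                                   NumericVector crit, NumericVector y_tr,
                                   NumericVector ct_tr, NumericVector gl_nodes,
                                   NumericVector gl_wts) {
  const int nd = s_draws.size(), nt = y_tr.size(), nk = gl_nodes.size();
  const IntegerVector rowmin = row_mins(mism_tr);
  const int dmax = max_entry(mism_tr);
  NumericVector out(nd);
  std::vector<double> pred(nt), lf0(nt), lf1(nt), lnode(nk);
  std::vector<double> lphi(nk), l1mphi(nk), lw(nk);
  for (int k = 0; k < nk; ++k) {
    lphi[k] = std::log(gl_nodes[k]);
    l1mphi[k] = std::log1p(-gl_nodes[k]);
    lw[k] = std::log(gl_wts[k]);
  }
  for (int d = 0; d < nd; ++d) {
    predict_at_s(mism_tr, rowmin, crit, s_draws[d], dmax, pred);
    double lnum = 0.0;
    for (int t = 0; t < nt; ++t) {
      lf0[t] = ldnorm_prec(y_tr[t], pred[t], tau0_draws[d]);
      lf1[t] = ldnorm_prec(y_tr[t], ct_tr[t], tau1_draws[d]);
      lnum += lf0[t];
    }
    double lint = R_NegInf;
    for (int k = 0; k < nk; ++k) {
      double lk = lw[k];
      for (int t = 0; t < nt; ++t)
        lk += lse2(lphi[k] + lf1[t], l1mphi[k] + lf0[t]);
      lint = lse2(lint, lk);
    }
    out[d] = lnum - lint;
  }
  return out;
}

// Posterior mixture responsibilities P(z_t = 1 | theta_d, y_t) per draw and
// trained trial.
// [[Rcpp::export]]
NumericMatrix responsibilities_cpp(NumericVector s_draws, NumericVector phi_draws,
                                   NumericVector tau0_draws, NumericVector tau1_draws,
                                   IntegerMatrix mism_tr, NumericVector crit,
                                   NumericVector y_tr, NumericVector ct_tr) {
  const int nd = s_draws.size(), nt = y_tr.size();
  const IntegerVector rowmin = row_mins(mism_tr);
  const int dmax = max_entry(mism_tr);
  NumericMatrix out(nd, nt);
  std::vector<double> pred(nt);
  for (int d = 0; d < nd; ++d) {
    predict_at_s(mism_tr, rowmin, crit, s_draws[d], dmax, pred);
    const double lphi = std::log(phi_draws[d]), l1mphi = std::log1p(-phi_draws[d]);
    for (int t = 0; t < nt; ++t) {
      const double la = lphi + ldnorm_prec(y_tr[t], ct_tr[t], tau1_draws[d]);
      const double lb = l1mphi + ldnorm_prec(y_tr[t], pred[t], tau0_draws[d]);
      out(d, t) = 1.0 / (1.0 + std::exp(lb - la));
    }
  }
  return out;
}
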