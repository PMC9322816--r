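// Data-augmented adaptive Metropolis-within-Gibbs sampler for the
// SPINGARCH(1,1) hierarchy.
//
// State: latent U = X + eps (n x T), CAR field X (n x T), and
// theta = (eta, kappa, sigma, sigma_eps); zeta fixed.
//   - U(s,t): scalar random-walk Metropolis; the intensity at site s is
//     replayed forward from t (the recursion carries U into all later
//     lambdas at the same site), so one proposal costs O(T - t).
//   - X(s,t): exact Gibbs — product of the CAR full conditional
//     N(mu_c, sigma^2) and the noise likelihood N(U(s,t), sigma_eps^2).
//   - (eta, kappa): joint RW on (logit(eta+kappa), logit(eta/(eta+kappa))).
//   - sigma, sigma_eps: RW on the log scale.
// Proposal scales adapt by Robbins-Monro during burn-in only.
//
// lambda_0 policy: lambda_0 = exp(alpha_1 + sigma_eps^2/2) / (1-eta-kappa),
// Y_0 := lambda_0 (its expectation); both depend on theta and are replayed
// whenever (eta, kappa, sigma_eps) move.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Poisson log-pmf term without the lgamma constant; -Inf on overflow
static inline double pois_term(double y, double lam) {
  if (!(lam > 0.0) || lam > 1e250 || !R_finite(lam)) return R_NegInf;
  return y * std::log(lam) - lam;
}

struct Sampler {
  int n, T;
  IntegerMatrix Y;
  NumericMatrix alpha;
  double zeta;
  std::vector< std::vector<int> > nb;      // neighbour indices per site
  std::vector< std::vector<double> > nbw;  // matching scaled weights
  double sum_log_1mz;                      // sum_j log(1 - zeta*chi_j)

  // priors
  double eta_a, eta_b, kap_a, kap_b, sig_scale, se_scale;

  // state
  NumericMatrix X, U, lam;
  NumericVector lam0;
  double eta, kappa, sigma, sigma_eps;
  bool fix_ek, fix_sigma, fix_se;
  double lgam_const;

  void compute_lam0() {
    double c = 1.0 - eta - kappa;
    for (int s = 0; s < n; ++s)
      lam0[s] = std::exp(alpha(s, 0) + 0.5 * sigma_eps * sigma_eps) / c;
  }

  // replay the full intensity panel into `out`; return count log-lik
  double replay_all(NumericMatrix &out, double eta_, double kappa_,
                    const NumericVector &lam0_) {
    double ll = 0.0;
    for (int s = 0; s < n; ++s) {
      double lp = lam0_[s], yp = lam0_[s];
      for (int t = 0; t < T; ++t) {
        double l = std::exp(U(s, t)) + eta_ * yp + kappa_ * lp;
        out(s, t) = l;
        ll += pois_term(Y(s, t), l);
        lp = l; yp = Y(s, t);
      }
    }
    return ll;
  }

  double count_loglik_current() {
    double ll = 0.0;
    for (int s = 0; s < n; ++s)
      for (int t = 0; t < T; ++t) ll += pois_term(Y(s, t), lam(s, t));
    return ll;
  }

  // CAR quadratic form sum_t dev'(I - zeta*W)dev with dev = X - alpha
  double car_quadform() {
    double qf = 0.0;
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < n; ++s) {
        double d = X(s, t) - alpha(s, t);
        double wsum = 0.0;
        const std::vector<int> &js = nb[s];
        const std::vector<double> &ws = nbw[s];
        for (size_t k = 0; k < js.size(); ++k)
          wsum += ws[k] * (X(js[k], t) - alpha(js[k], t));
        qf += d * (d - zeta * wsum);
      }
    }
    return qf;
  }

  double car_loglik(double sig, double qf) {
    if (sig <= 0.0) return R_NegInf;
    double nT = (double)n * T;
    return -0.5 * nT * LOG2PI +
           0.5 * T * (-n * 2.0 * std::log(sig) + sum_log_1mz) -
           qf / (2.0 * sig * sig);
  }

  double eps_sse() {
    double s2 = 0.0;
    for (int s = 0; s < n; ++s)
      for (int t = 0; t < T; ++t) {
        double e = U(s, t) - X(s, t);
        s2 += e * e;
      }
    return s2;
  }

  double eps_loglik(double se, double sse) {
    if (se <= 0.0) return R_NegInf;
    double nT = (double)n * T;
    return -0.5 * nT * LOG2PI - nT * std::log(se) - sse / (2.0 * se * se);
  }

  double log_prior_theta(double eta_, double kappa_, double sig,
                         double se) {
    double lp = 0.0;
    if (!fix_ek) {
      if (eta_ <= 0.0 || kappa_ <= 0.0 || eta_ + kappa_ >= 1.0) return R_NegInf;
      lp += R::dbeta(eta_, eta_a, eta_b, 1) +
            R::dbeta(kappa_, kap_a, kap_b, 1);
    }
    if (!fix_sigma)
      lp += std::log(2.0) + R::dcauchy(sig, 0.0, sig_scale, 1);
    if (!fix_se)
      lp += std::log(2.0) + R::dcauchy(se, 0.0, se_scale, 1);
    return lp;
  }
};

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix Y, NumericMatrix alpha, NumericMatrix W,
                   NumericVector eigvals, double zeta, List prior,
                   int n_iter, int burn_in, int thin, NumericVector init,
                   bool fix_ek, bool fix_sigma, bool fix_se,
                   NumericMatrix U_init, int theta_reps = 5) {
  Sampler sp;
  sp.n = Y.nrow(); sp.T = Y.ncol();
  sp.Y = Y; sp.alpha = alpha; sp.zeta = zeta;
  sp.eta_a = prior["eta_a"]; sp.eta_b = prior["eta_b"];
  sp.kap_a = prior["kappa_a"]; sp.kap_b = prior["kappa_b"];
  sp.sig_scale = prior["sigma_scale"]; sp.se_scale = prior["sigma_eps_scale"];
  sp.fix_ek = fix_ek; sp.fix_sigma = fix_sigma; sp.fix_se = fix_se;

  const int n = sp.n, T = sp.T;
  sp.nb.resize(n); sp.nbw.resize(n);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < n; ++j)
      if (W(s, j) != 0.0) { sp.nb[s].push_back(j); sp.nbw[s].push_back(W(s, j)); }
  sp.sum_log_1mz = 0.0;
  for (int j = 0; j < n; ++j) sp.sum_log_1mz += std::log(1.0 - zeta * eigvals[j]);

  sp.eta = init[0]; sp.kappa = init[1];
  sp.sigma = init[2]; sp.sigma_eps = init[3];
  const bool sigma_zero = fix_sigma && sp.sigma == 0.0;

  sp.X = NumericMatrix(n, T); sp.U = NumericMatrix(n, T);
  sp.lam = NumericMatrix(n, T); sp.lam0 = NumericVector(n);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < T; ++t) {
      sp.X(s, t) = alpha(s, t);
      sp.U(s, t) = U_init(s, t);
    }
  sp.lgam_const = 0.0;
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < T; ++t) sp.lgam_const -= R::lgammafn(Y(s, t) + 1.0);

  sp.compute_lam0();
  double count_ll = sp.replay_all(sp.lam, sp.eta, sp.kappa, sp.lam0);
  if (!R_finite(count_ll))
    stop("non-finite count log-likelihood at initialization");

  // adaptive proposal scales
  double sc_u = 0.5, sc_ek = 0.3, sc_s = 0.3, sc_se = 0.2, sc_shift = 0.5;
  long acc_u = 0, try_u = 0, acc_ek = 0, acc_s = 0, acc_se = 0;
  // 1'(I - zeta*W)1, for the slice-level shift move
  double q11 = 0.0;
  for (int s = 0; s < n; ++s) {
    double wr = 0.0;
    for (size_t k = 0; k < sp.nbw[s].size(); ++k) wr += sp.nbw[s][k];
    q11 += 1.0 - zeta * wr;
  }

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, 5);
  std::vector<double> lam_work(T);
  RNGScope scope;
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const double gam = (iter <= burn_in) ? std::min(0.05, 2.0 / std::sqrt((double)iter)) : 0.0;

    // ---- latent sweep -------------------------------------------------
    const double se2 = sp.sigma_eps * sp.sigma_eps;
    const double s2 = sp.sigma * sp.sigma;
    double acc_frac = 0.0; long prop_cnt = 0;
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < n; ++s) {
        // (a) RW on U(s,t): likelihood along site s from t, plus eps prior
        double u_old = sp.U(s, t);
        double u_new = u_old + sc_u * norm_rand();
        double lp_prev = (t == 0) ? sp.lam0[s] : sp.lam(s, t - 1);
        double yp = (t == 0) ? sp.lam0[s] : (double)sp.Y(s, t - 1);
        double delta = 0.0;
        double lp = lp_prev;
        // replay with the proposal
        for (int u = t; u < T; ++u) {
          double expU = (u == t) ? std::exp(u_new) : std::exp(sp.U(s, u));
          double l = expU + sp.eta * yp + sp.kappa * lp;
          lam_work[u] = l;
          delta += pois_term(sp.Y(s, u), l) - pois_term(sp.Y(s, u), sp.lam(s, u));
          lp = l; yp = sp.Y(s, u);
        }
        double e_old = u_old - sp.X(s, t), e_new = u_new - sp.X(s, t);
        delta += (e_old * e_old - e_new * e_new) / (2.0 * se2);
        ++try_u; ++prop_cnt;
        if (R_finite(delta) && std::log(unif_rand()) < delta) {
          sp.U(s, t) = u_new;
          for (int u = t; u < T; ++u) sp.lam(s, u) = lam_work[u];
          count_ll += delta - (e_old * e_old - e_new * e_new) / (2.0 * se2);
          ++acc_u; acc_frac += 1.0;
        }
        // (b) Gibbs on X(s,t) given U (skipped when sigma == 0: X = alpha)
        if (!sigma_zero) {
          double mu_c = sp.alpha(s, t);
          const std::vector<int> &js = sp.nb[s];
          const std::vector<double> &ws = sp.nbw[s];
          double wsum = 0.0;
          for (size_t k = 0; k < js.size(); ++k)
            wsum += ws[k] * (sp.X(js[k], t) - sp.alpha(js[k], t));
          mu_c += sp.zeta * wsum;
          double prec = 1.0 / s2 + 1.0 / se2;
          double m = (mu_c / s2 + sp.U(s, t) / se2) / prec;
          sp.X(s, t) = m + norm_rand() / std::sqrt(prec);
        }
      }
      // slice-level shift on X_t: at zeta near 1 the CAR prior is nearly
      // flat along the constant direction, which sitewise Gibbs walks
      // slowly; this move trades the CAR term against the noise term
      // (U fixed, counts untouched).
      if (!sigma_zero) {
        double c = sc_shift * norm_rand();
        double s1 = 0.0, esum = 0.0;
        for (int s = 0; s < n; ++s) {
          double d = sp.X(s, t) - sp.alpha(s, t);
          double wsum = 0.0;
          for (size_t k = 0; k < sp.nb[s].size(); ++k)
            wsum += sp.nbw[s][k] * (sp.X(sp.nb[s][k], t) - sp.alpha(sp.nb[s][k], t));
          s1 += d - zeta * wsum;
          esum += sp.U(s, t) - sp.X(s, t);
        }
        double delta = -(2.0 * c * s1 + c * c * q11) / (2.0 * s2) +
                       (2.0 * c * esum - n * c * c) / (2.0 * se2);
        bool acc = R_finite(delta) && std::log(unif_rand()) < delta;
        if (acc) for (int s = 0; s < n; ++s) sp.X(s, t) += c;
        if (gam > 0.0) sc_shift *= std::exp(gam * ((acc ? 1.0 : 0.0) - 0.44));
      }
    }
    if (gam > 0.0 && prop_cnt > 0)
      sc_u *= std::exp(gam * (acc_frac / prop_cnt - 0.44));

    // ---- theta block (repeated: cheap relative to the latent sweep,
    //      and (eta,kappa) mixes slowly with a single hit) -------------
    double qf_cache = (!sp.fix_sigma) ? sp.car_quadform() : 0.0;
    double sse_cache = (!sp.fix_se) ? sp.eps_sse() : 0.0;
    for (int rep = 0; rep < theta_reps; ++rep) {

    // ---- (eta, kappa) -------------------------------------------------
    if (!sp.fix_ek) {
      double ssum = sp.eta + sp.kappa, rr = sp.eta / ssum;
      double ts = logit(ssum), tr = logit(rr);
      double ts_n = ts + sc_ek * norm_rand();
      double tr_n = tr + sc_ek * norm_rand();
      double s_n = invlogit(ts_n), r_n = invlogit(tr_n);
      double eta_n = s_n * r_n, kap_n = s_n * (1.0 - r_n);
      NumericVector lam0_n(n);
      double c_n = 1.0 - eta_n - kap_n;
      for (int s = 0; s < n; ++s)
        lam0_n[s] = std::exp(sp.alpha(s, 0) + 0.5 * se2) / c_n;
      NumericMatrix lam_n(n, T);
      double cll_n = sp.replay_all(lam_n, eta_n, kap_n, lam0_n);
      double logJ_n = 2.0 * std::log(s_n) + std::log(1.0 - s_n) +
                      std::log(r_n) + std::log(1.0 - r_n);
      double logJ_o = 2.0 * std::log(ssum) + std::log(1.0 - ssum) +
                      std::log(rr) + std::log(1.0 - rr);
      double delta = cll_n - count_ll +
        R::dbeta(eta_n, sp.eta_a, sp.eta_b, 1) - R::dbeta(sp.eta, sp.eta_a, sp.eta_b, 1) +
        R::dbeta(kap_n, sp.kap_a, sp.kap_b, 1) - R::dbeta(sp.kappa, sp.kap_a, sp.kap_b, 1) +
        logJ_n - logJ_o;
      bool acc = R_finite(delta) && std::log(unif_rand()) < delta;
      if (acc) {
        sp.eta = eta_n; sp.kappa = kap_n;
        sp.lam0 = lam0_n; sp.lam = lam_n; count_ll = cll_n;
        ++acc_ek;
      }
      if (gam > 0.0) sc_ek *= std::exp(gam * ((acc ? 1.0 : 0.0) - 0.30));
    }

    // ---- sigma (CAR scale), log-RW ------------------------------------
    if (!sp.fix_sigma) {
      double qf = qf_cache;
      double sig_n = sp.sigma * std::exp(sc_s * norm_rand());
      double delta = sp.car_loglik(sig_n, qf) - sp.car_loglik(sp.sigma, qf) +
        (std::log(2.0) + R::dcauchy(sig_n, 0.0, sp.sig_scale, 1)) -
        (std::log(2.0) + R::dcauchy(sp.sigma, 0.0, sp.sig_scale, 1)) +
        std::log(sig_n) - std::log(sp.sigma);
      bool acc = R_finite(delta) && std::log(unif_rand()) < delta;
      if (acc) { sp.sigma = sig_n; ++acc_s; }
      if (gam > 0.0) sc_s *= std::exp(gam * ((acc ? 1.0 : 0.0) - 0.44));
    }

    // ---- sigma_eps, log-RW (moves lambda_0, so the counts too) --------
    if (!sp.fix_se) {
      double sse = sse_cache;
      double se_n = sp.sigma_eps * std::exp(sc_se * norm_rand());
      NumericVector lam0_n(n);
      double c = 1.0 - sp.eta - sp.kappa;
      for (int s = 0; s < n; ++s)
        lam0_n[s] = std::exp(sp.alpha(s, 0) + 0.5 * se_n * se_n) / c;
      NumericMatrix lam_n(n, T);
      double cll_n = sp.replay_all(lam_n, sp.eta, sp.kappa, lam0_n);
      double delta = cll_n - count_ll +
        sp.eps_loglik(se_n, sse) - sp.eps_loglik(sp.sigma_eps, sse) +
        R::dcauchy(se_n, 0.0, sp.se_scale, 1) -
        R::dcauchy(sp.sigma_eps, 0.0, sp.se_scale, 1) +
        std::log(se_n) - std::log(sp.sigma_eps);
      bool acc = R_finite(delta) && std::log(unif_rand()) < delta;
      if (acc) {
        sp.sigma_eps = se_n; sp.lam0 = lam0_n; sp.lam = lam_n;
        count_ll = cll_n; ++acc_se;
      }
      if (gam > 0.0) sc_se *= std::exp(gam * ((acc ? 1.0 : 0.0) - 0.44));
    }

    } // theta_reps

    // ---- retain -------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      double qf = sigma_zero ? 0.0 : sp.car_quadform();
      double car_ll = sigma_zero ? 0.0 : sp.car_loglik(sp.sigma, qf);
      double lp = count_ll + sp.lgam_const + car_ll +
        sp.eps_loglik(sp.sigma_eps, sp.eps_sse()) +
        sp.log_prior_theta(sp.eta, sp.kappa, sp.sigma, sp.sigma_eps);
      out(kept, 0) = sp.eta; out(kept, 1) = sp.kappa;
      out(kept, 2) = sp.sigma; out(kept, 3) = sp.sigma_eps;
      out(kept, 4) = lp;
      ++kept;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["samples"] = out,
    _["acc_u"] = (double)acc_u / std::max(1L, try_u),
    _["acc_ek"] = (double)acc_ek / ((double)n_iter * theta_reps),
    _["acc_sigma"] = (double)acc_s / ((double)n_iter * theta_reps),
    _["acc_sigma_eps"] = (double)acc_se / ((double)n_iter * theta_reps),
    _["scales"] = NumericVector::create(sc_u, sc_ek, sc_s, sc_se));
}
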