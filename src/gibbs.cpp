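#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Half-Cauchy(0, scale) log density up to a constant.
static double hc_logpdf(double s, double scale) {
  double r = s / scale;
  return -std::log1p(r * r);
}

// Log conditional of theta = log(sigma) given a quadratic form q = sum of
// squared (whitened) effects and m = number of effects:
//   p(sigma | .) propto sigma^-m exp(-q / (2 sigma^2)) * HC(sigma; scale)
// plus the Jacobian of the log transform (+theta).
static double logpost_th(double th, double q, double m, double scale) {
  double s = std::exp(th);
  return -m * th - q / (2.0 * s * s) + hc_logpdf(s, scale) + th;
}

// Univariate stepping-out slice sampler on theta = log(sigma).
static double slice_logsigma(double th0, double q, double m, double scale) {
  const double w = 1.0;
  const int maxstep = 100;
  double f0 = logpost_th(th0, q, m, scale);
  double logy = f0 + std::log(R::runif(0.0, 1.0));
  double L = th0 - w * R::runif(0.0, 1.0);
  double Rb = L + w;
  int j = maxstep;
  while (j-- > 0 && logpost_th(L, q, m, scale) > logy) L -= w;
  j = maxstep;
  while (j-- > 0 && logpost_th(Rb, q, m, scale) > logy) Rb += w;
  for (int it = 0; it < 200; ++it) {
    double th1 = L + R::runif(0.0, 1.0) * (Rb - L);
    if (logpost_th(th1, q, m, scale) >= logy) return th1;
    if (th1 < th0) L = th1; else Rb = th1;
  }
  return th0;
}

// Non-centered conditional for sigma: with the whitened effects held
// fixed, the data likelihood is Gaussian in sigma:
//   log p(sigma | .) = s1 * sigma - s2 * sigma^2 / 2 + log HC(sigma)
// (on theta = log sigma, with Jacobian).  Interweaving this with the
// centered update breaks the funnel between effects and their SD.
static double logpost_th_nc(double th, double s1, double s2, double scale) {
  double s = std::exp(th);
  return s1 * s - 0.5 * s2 * s * s + hc_logpdf(s, scale) + th;
}

static double slice_logsigma_nc(double th0, double s1, double s2,
                                double scale) {
  const double w = 1.0;
  const int maxstep = 100;
  double f0 = logpost_th_nc(th0, s1, s2, scale);
  double logy = f0 + std::log(R::runif(0.0, 1.0));
  double L = th0 - w * R::runif(0.0, 1.0);
  double Rb = L + w;
  int j = maxstep;
  while (j-- > 0 && logpost_th_nc(L, s1, s2, scale) > logy) L -= w;
  j = maxstep;
  while (j-- > 0 && logpost_th_nc(Rb, s1, s2, scale) > logy) Rb += w;
  for (int it = 0; it < 200; ++it) {
    double th1 = L + R::runif(0.0, 1.0) * (Rb - L);
    if (logpost_th_nc(th1, s1, s2, scale) >= logy) return th1;
    if (th1 < th0) L = th1; else Rb = th1;
  }
  return th0;
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::rnorm(0.0, 1.0);
  return z;
}

// One MCMC chain for the Gaussian phylogenetic meta-analytic model
//   y_k ~ N(x_k' beta + a_{sp(k)} + u_{sp(k)} + b_{st(k)}, se2_k)
//   a ~ MVN(0, sig_p^2 C), u_i ~ N(0, sig_s^2), b_g ~ N(0, tau^2)
//   beta_j ~ N(0, prior_beta_sd_j^2), SDs ~ half-Cauchy(0, hc_scale)
// The full location block theta = (beta, a, u, b) is conditionally
// Gaussian and is drawn jointly (exact block-Gibbs update: the data part
// of its normal equations is constant and only the prior precision blocks
// change with the SDs), which avoids the slow mixing that one-at-a-time
// updates suffer from the intercept/species-effect confounding.  The log
// SDs get stepping-out slice updates.  sigma_fixed entries, when not NA,
// freeze an SD at that value (0 switches the effect block off) -- used
// for conjugate closed-form checks.  Uses R's RNG: seed with set.seed()
// before calling.
// [[Rcpp::export]]
List gibbs_phylo_meta_cpp(const arma::vec& y, const arma::vec& se2,
                          const arma::mat& X,
                          const arma::ivec& sp, const arma::ivec& st,
                          const arma::mat& Cinv,
                          int n_iter, int n_warmup,
                          const arma::vec& prior_beta_sd,
                          double hc_scale,
                          NumericVector sigma_fixed) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int S = Cinv.n_rows;
  const int G = arma::max(st) + 1;

  arma::vec w = 1.0 / se2;

  const bool fix_p = !NumericVector::is_na(sigma_fixed[0]);
  const bool fix_s = !NumericVector::is_na(sigma_fixed[1]);
  const bool fix_t = !NumericVector::is_na(sigma_fixed[2]);
  double sig_p = fix_p ? sigma_fixed[0] : hc_scale;
  double sig_s = fix_s ? sigma_fixed[1] : hc_scale;
  double tau   = fix_t ? sigma_fixed[2] : hc_scale;
  const bool use_a = !(fix_p && sig_p == 0.0);
  const bool use_u = !(fix_s && sig_s == 0.0);
  const bool use_b = !(fix_t && tau == 0.0);

  // design Z = [X | A-block | U-block | B-block] restricted to active blocks
  const int oa = p;
  const int ou = oa + (use_a ? S : 0);
  const int ob = ou + (use_u ? S : 0);
  const int D  = ob + (use_b ? G : 0);

  arma::mat M0(D, D, arma::fill::zeros);     // Z' W Z
  arma::vec rhs(D, arma::fill::zeros);       // Z' W y
  {
    arma::mat XtW = X.t() * arma::diagmat(w);
    M0.submat(0, 0, p - 1, p - 1) = XtW * X;
    rhs.subvec(0, p - 1) = XtW * y;
    for (int k = 0; k < n; ++k) {
      const int i = sp(k), g = st(k);
      const double wk = w(k);
      for (int j = 0; j < p; ++j) {
        const double xw = X(k, j) * wk;
        if (use_a) { M0(j, oa + i) += xw; M0(oa + i, j) += xw; }
        if (use_u) { M0(j, ou + i) += xw; M0(ou + i, j) += xw; }
        if (use_b) { M0(j, ob + g) += xw; M0(ob + g, j) += xw; }
      }
      if (use_a) { M0(oa + i, oa + i) += wk; rhs(oa + i) += wk * y(k); }
      if (use_u) { M0(ou + i, ou + i) += wk; rhs(ou + i) += wk * y(k); }
      if (use_b) { M0(ob + g, ob + g) += wk; rhs(ob + g) += wk * y(k); }
      if (use_a && use_u) { M0(oa + i, ou + i) += wk; M0(ou + i, oa + i) += wk; }
      if (use_a && use_b) { M0(oa + i, ob + g) += wk; M0(ob + g, oa + i) += wk; }
      if (use_u && use_b) { M0(ou + i, ob + g) += wk; M0(ob + g, ou + i) += wk; }
    }
  }
  arma::vec prior_beta_prec = 1.0 / arma::square(prior_beta_sd);

  arma::vec theta(D, arma::fill::zeros);
  arma::vec a(S, arma::fill::zeros), u(S, arma::fill::zeros),
            b(G, arma::fill::zeros);

  const int n_keep = n_iter - n_warmup;
  arma::mat beta_d(n_keep, p), a_d(n_keep, S), u_d(n_keep, S),
            b_d(n_keep, G);
  arma::vec sigp_d(n_keep), sigs_d(n_keep), tau_d(n_keep);
  arma::mat ll_d(n_keep, n);

  const double LOG2PI = std::log(2.0 * M_PI);

  for (int it = 0; it < n_iter; ++it) {
    // (beta, a, u, b) | SDs  -- joint Gaussian draw
    arma::mat A = M0;
    for (int j = 0; j < p; ++j) A(j, j) += prior_beta_prec(j);
    if (use_a)
      A.submat(oa, oa, oa + S - 1, oa + S - 1) += Cinv / (sig_p * sig_p);
    if (use_u)
      for (int i = 0; i < S; ++i) A(ou + i, ou + i) += 1.0 / (sig_s * sig_s);
    if (use_b)
      for (int g = 0; g < G; ++g) A(ob + g, ob + g) += 1.0 / (tau * tau);
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs));
    theta = mu + arma::solve(arma::trimatu(L.t()), rnorm_vec(D));

    arma::vec beta = theta.subvec(0, p - 1);
    if (use_a) a = theta.subvec(oa, oa + S - 1); else a.zeros();
    if (use_u) u = theta.subvec(ou, ou + S - 1); else u.zeros();
    if (use_b) b = theta.subvec(ob, ob + G - 1); else b.zeros();

    // SDs | effects
    if (!fix_p && use_a) {
      double q = arma::dot(a, Cinv * a);
      sig_p = std::exp(slice_logsigma(std::log(sig_p), q, S, hc_scale));
    }
    if (!fix_s && use_u) {
      double q = arma::dot(u, u);
      sig_s = std::exp(slice_logsigma(std::log(sig_s), q, S, hc_scale));
    }
    if (!fix_t && use_b) {
      double q = arma::dot(b, b);
      tau = std::exp(slice_logsigma(std::log(tau), q, G, hc_scale));
    }

    // interweaved non-centered SD updates (whitened effects held fixed)
    if ((!fix_p && use_a) || (!fix_s && use_u) || (!fix_t && use_b)) {
      arma::vec xb = X * theta.subvec(0, p - 1);
      if (!fix_p && use_a) {
        arma::vec at = a / sig_p;
        double s1 = 0.0, s2 = 0.0;
        for (int k = 0; k < n; ++k) {
          double r = y(k) - xb(k) - u(sp(k)) - b(st(k));
          s1 += w(k) * r * at(sp(k));
          s2 += w(k) * at(sp(k)) * at(sp(k));
        }
        sig_p = std::exp(slice_logsigma_nc(std::log(sig_p), s1, s2, hc_scale));
        a = at * sig_p;
        if (use_a) theta.subvec(oa, oa + S - 1) = a;
      }
      if (!fix_s && use_u) {
        arma::vec ut = u / sig_s;
        double s1 = 0.0, s2 = 0.0;
        for (int k = 0; k < n; ++k) {
          double r = y(k) - xb(k) - a(sp(k)) - b(st(k));
          s1 += w(k) * r * ut(sp(k));
          s2 += w(k) * ut(sp(k)) * ut(sp(k));
        }
        sig_s = std::exp(slice_logsigma_nc(std::log(sig_s), s1, s2, hc_scale));
        u = ut * sig_s;
        if (use_u) theta.subvec(ou, ou + S - 1) = u;
      }
      if (!fix_t && use_b) {
        arma::vec bt = b / tau;
        double s1 = 0.0, s2 = 0.0;
        for (int k = 0; k < n; ++k) {
          double r = y(k) - xb(k) - a(sp(k)) - u(sp(k));
          s1 += w(k) * r * bt(st(k));
          s2 += w(k) * bt(st(k)) * bt(st(k));
        }
        tau = std::exp(slice_logsigma_nc(std::log(tau), s1, s2, hc_scale));
        b = bt * tau;
        if (use_b) theta.subvec(ob, ob + G - 1) = b;
      }
    }

    if (it >= n_warmup) {
      const int j = it - n_warmup;
      beta_d.row(j) = beta.t();
      a_d.row(j) = a.t();
      u_d.row(j) = u.t();
      b_d.row(j) = b.t();
      sigp_d(j) = sig_p; sigs_d(j) = sig_s; tau_d(j) = tau;
      arma::vec xb = X * beta;
      for (int k = 0; k < n; ++k) {
        double e = y(k) - xb(k) - a(sp(k)) - u(sp(k)) - b(st(k));
        ll_d(j, k) = -0.5 * (LOG2PI + std::log(se2(k)) + e * e / se2(k));
      }
    }
  }

  return List::create(_["beta"] = beta_d, _["a"] = a_d, _["u"] = u_d,
                      _["b"] = b_d, _["sigma_p"] = sigp_d,
                      _["sigma_s"] = sigs_d, _["tau"] = tau_d,
                      _["loglik"] = ll_d);
}
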