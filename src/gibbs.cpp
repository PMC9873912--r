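// Blocked Gibbs sampler for the hierarchical trend model.
//
// Model, per record i:
//   y_i ~ Normal(mu_i, sigma^2 / w_i + se2_i)        (quantitative)
//   y_i latent, restricted to (L_i, U_i)             (interval-censored)
//   mu_i = alpha + sum_j beta_j X_ij + u_genus + u_species + u_subregion + u_country
//   beta_j = gamma_j * b_j for selectable terms (Kuo-Mallick), b_j otherwise
//   X columns: main covariates (some latent with Normal(m, s^2) measurement
//   error from imputation) followed by pairwise products (interactions).
//
// Updates: truncated-normal draws for censored responses; conjugate normal
// split for the se2 measurement-error component; joint multivariate-normal
// draw of (alpha, included slopes); marginalized Bernoulli updates for the
// inclusion indicators (b integrated out, which sidesteps the classic
// Kuo-Mallick pseudo-prior mixing problem); conjugate normal draws for
// random-intercept levels and latent covariate cells (mu is linear in each
// latent cell, so conditionals stay normal even inside interactions);
// Makalic-Schmidt inverse-gamma augmentation for half-Cauchy sd priors.
//
// All randomness comes from R's RNG, so set.seed() on the R side makes a
// chain exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rtruncnorm1(double mu, double sd, double lo, double hi) {
  double a = R::pnorm(lo, mu, sd, 1, 0);
  double b = R::pnorm(hi, mu, sd, 1, 0);
  if (b - a < 1e-14) {
    // interval mass underflows: clamp the mean into the interval
    double m = mu;
    if (m < lo) m = lo;
    if (m > hi) m = hi;
    return m;
  }
  double u = R::runif(a, b);
  double x = R::qnorm(u, mu, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List gibbs_chain_cpp(NumericVector y0,
                     IntegerVector is_cens,
                     NumericMatrix lim,
                     NumericMatrix Xmain0,
                     IntegerVector mis_row,
                     IntegerVector mis_col,
                     NumericVector mis_mean,
                     NumericVector mis_sd,
                     IntegerMatrix int_pairs,
                     IntegerVector selectable,
                     IntegerVector pinned,
                     List group_idx,
                     IntegerVector n_levels,
                     NumericVector w,
                     NumericVector se2,
                     double slope_sd, double intercept_sd, double incl_prob,
                     double sigma_scale, double re_scale,
                     int n_iter, int n_burn, int thin, bool do_select) {
  const int N  = Xmain0.nrow();
  const int Pm = Xmain0.ncol();
  const int Pi = int_pairs.nrow();
  const int P  = Pm + Pi;
  const int G  = group_idx.size();
  const int Nmis = mis_row.size();

  // full design: main columns then interactions
  arma::mat X(N, P);
  for (int j = 0; j < Pm; ++j)
    for (int i = 0; i < N; ++i) X(i, j) = Xmain0(i, j);
  for (int k = 0; k < Pi; ++k) {
    int a = int_pairs(k, 0), bcol = int_pairs(k, 1);
    for (int i = 0; i < N; ++i) X(i, Pm + k) = X(i, a) * X(i, bcol);
  }

  // interactions touching each main column (for latent-cell updates)
  std::vector< std::vector<int> > ints_of(Pm), other_of(Pm);
  for (int k = 0; k < Pi; ++k) {
    int a = int_pairs(k, 0), bcol = int_pairs(k, 1);
    ints_of[a].push_back(k);  other_of[a].push_back(bcol);
    if (bcol != a) { ints_of[bcol].push_back(k); other_of[bcol].push_back(a); }
  }
  // missing cells grouped by column
  std::vector< std::vector<int> > mis_of_col(Pm);
  for (int m = 0; m < Nmis; ++m) mis_of_col[mis_col[m]].push_back(m);

  std::vector<arma::uvec> gidx(G);
  for (int g = 0; g < G; ++g) {
    IntegerVector iv = group_idx[g];
    arma::uvec uv(iv.size());
    for (int i = 0; i < (int)iv.size(); ++i) uv[i] = iv[i];
    gidx[g] = uv;
  }

  // arma views over the weight vector for vectorised expressions
  arma::vec wv(w.begin(), N, false);

  // state
  arma::vec y(N), f(N, arma::fill::zeros), z(N);
  for (int i = 0; i < N; ++i) y[i] = y0[i];
  z = y;
  double alpha = 0.0;
  arma::vec b(P, arma::fill::zeros);
  arma::ivec gam(P, arma::fill::ones);           // core terms stay 1 throughout
  arma::vec beta(P, arma::fill::zeros);
  arma::vec eta(N, arma::fill::zeros);
  arma::vec re_sum(N, arma::fill::zeros);
  std::vector<arma::vec> u(G);
  arma::vec sd2g(G, arma::fill::ones), ag(G, arma::fill::ones);
  for (int g = 0; g < G; ++g) u[g] = arma::vec(n_levels[g], arma::fill::zeros);
  double sigma2 = arma::var(z);
  if (!(sigma2 > 1e-8)) sigma2 = 1.0;
  double a_sig = 1.0;
  bool any_se2 = false;
  for (int i = 0; i < N; ++i) if (se2[i] > 0) { any_se2 = true; break; }

  const double prior_prec_b = 1.0 / (slope_sd * slope_sd);
  const double prior_prec_a = 1.0 / (intercept_sd * intercept_sd);
  const double log_odds_prior = std::log(incl_prob) - std::log1p(-incl_prob);

  // storage
  int n_keep = 0;
  for (int it = 0; it < n_iter; ++it)
    if (it >= n_burn && ((it - n_burn) % thin == 0)) ++n_keep;
  int Ku = 0;
  for (int g = 0; g < G; ++g) Ku += n_levels[g];
  int n_cens = 0;
  for (int i = 0; i < N; ++i) if (is_cens[i]) ++n_cens;
  NumericMatrix S_alpha(n_keep, 1), S_b(n_keep, P), S_gam(n_keep, P),
      S_sigma(n_keep, 1), S_sd(n_keep, G), S_u(n_keep, Ku),
      S_ylat(n_keep, n_cens), S_xmis(n_keep, Nmis);

  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- latent censored responses -------------------------------------
    for (int i = 0; i < N; ++i) {
      if (!is_cens[i]) continue;
      double mu_i = alpha + eta[i] + re_sum[i];
      double sd_i = std::sqrt(sigma2 / w[i] + se2[i]);
      y[i] = rtruncnorm1(mu_i, sd_i, lim(i, 0), lim(i, 1));
      z[i] = y[i] - f[i];
    }
    // --- measurement-error split for records with a trend-fit se -------
    if (any_se2) {
      for (int i = 0; i < N; ++i) {
        if (se2[i] <= 0) continue;
        double res = y[i] - alpha - eta[i] - re_sum[i];
        double prec = 1.0 / se2[i] + w[i] / sigma2;
        double mean = (res * w[i] / sigma2) / prec;
        f[i] = mean + R::norm_rand() / std::sqrt(prec);
        z[i] = y[i] - f[i];
      }
    }
    // --- joint draw of intercept + included slopes ---------------------
    {
      std::vector<int> act;
      for (int j = 0; j < P; ++j) if (gam[j] == 1) act.push_back(j);
      int q = 1 + (int)act.size();
      arma::mat A(N, q);
      A.col(0).ones();
      for (int c = 1; c < q; ++c) A.col(c) = X.col(act[c - 1]);
      arma::vec sw = wv / sigma2;
      arma::mat Aw = A.each_col() % sw;
      arma::mat Prec = A.t() * Aw;
      Prec(0, 0) += prior_prec_a;
      for (int c = 1; c < q; ++c) Prec(c, c) += prior_prec_b;
      arma::vec rhs = Aw.t() * (z - re_sum);
      arma::mat R = arma::chol(Prec);            // upper: Prec = R'R
      arma::vec mean = arma::solve(arma::trimatu(R),
                       arma::solve(arma::trimatl(R.t()), rhs));
      arma::vec zr(q);
      for (int c = 0; c < q; ++c) zr[c] = R::norm_rand();
      arma::vec th = mean + arma::solve(arma::trimatu(R), zr);
      alpha = th[0];
      for (int c = 1; c < q; ++c) { b[act[c - 1]] = th[c]; beta[act[c - 1]] = th[c]; }
      eta = X * beta;
    }
    // --- Kuo-Mallick indicators (b_j marginalized out) -----------------
    if (do_select) {
      arma::vec r = z - alpha - eta - re_sum;
      for (int j = 0; j < P; ++j) {
        if (!selectable[j]) continue;
        arma::vec xj = X.col(j);
        arma::vec rj = r + beta[j] * xj;
        double Sxx = arma::accu(wv % xj % xj) / sigma2;
        double Sxr = arma::accu(wv % xj % rj) / sigma2;
        double Pj = prior_prec_b + Sxx;
        double mj = Sxr / Pj;
        int g;
        if (pinned[j]) {
          g = 1;
        } else {
          double lo = log_odds_prior +
            0.5 * (std::log(prior_prec_b) - std::log(Pj)) + 0.5 * mj * mj * Pj;
          double p1 = 1.0 / (1.0 + std::exp(-lo));
          g = (R::unif_rand() < p1) ? 1 : 0;
        }
        double bj = g ? (mj + R::norm_rand() / std::sqrt(Pj))
                      : (R::norm_rand() * slope_sd);
        double beta_new = g ? bj : 0.0;
        gam[j] = g; b[j] = bj;
        r = rj - beta_new * xj;
        eta += (beta_new - beta[j]) * xj;
        beta[j] = beta_new;
      }
    }
    // --- random intercepts ---------------------------------------------
    for (int g = 0; g < G; ++g) {
      int K = n_levels[g];
      // remove this group's current contribution so re_sum holds the
      // up-to-date values of all other groups
      for (int i = 0; i < N; ++i) re_sum[i] -= u[g][gidx[g][i]];
      arma::vec sw_sum(K, arma::fill::zeros), sr_sum(K, arma::fill::zeros);
      for (int i = 0; i < N; ++i) {
        int k = gidx[g][i];
        double resid = z[i] - alpha - eta[i] - re_sum[i];
        sw_sum[k] += w[i] / sigma2;
        sr_sum[k] += w[i] * resid / sigma2;
      }
      for (int k = 0; k < K; ++k) {
        double prec = 1.0 / sd2g[g] + sw_sum[k];
        double mean = sr_sum[k] / prec;
        u[g][k] = mean + R::norm_rand() / std::sqrt(prec);
      }
      for (int i = 0; i < N; ++i) re_sum[i] += u[g][gidx[g][i]];
    }
    // --- variance components (half-Cauchy via inverse-gamma mixture) ---
    for (int g = 0; g < G; ++g) {
      int K = n_levels[g];
      double rate = 1.0 / ag[g] + 0.5 * arma::accu(u[g] % u[g]);
      sd2g[g] = rinvgamma(0.5 * (K + 1), rate);
      ag[g] = rinvgamma(1.0, 1.0 / (re_scale * re_scale) + 1.0 / sd2g[g]);
    }
    {
      arma::vec e = z - alpha - eta - re_sum;
      double rate = 1.0 / a_sig + 0.5 * arma::accu(wv % e % e);
      sigma2 = rinvgamma(0.5 * (N + 1), rate);
      a_sig = rinvgamma(1.0, 1.0 / (sigma_scale * sigma_scale) + 1.0 / sigma2);
    }
    // --- latent covariate cells (imputation measurement error) ---------
    for (int j = 0; j < Pm; ++j) {
      const std::vector<int>& cells = mis_of_col[j];
      if (cells.empty()) continue;
      for (size_t cidx = 0; cidx < cells.size(); ++cidx) {
        int m = cells[cidx];
        int i = mis_row[m];
        double c = beta[j];
        for (size_t t = 0; t < ints_of[j].size(); ++t)
          c += beta[Pm + ints_of[j][t]] * X(i, other_of[j][t]);
        double e_i = z[i] - alpha - eta[i] - re_sum[i];
        double xold = X(i, j);
        double pr = e_i + c * xold;
        double s2 = mis_sd[m] * mis_sd[m];
        double prec = 1.0 / s2 + c * c * w[i] / sigma2;
        double mean = (mis_mean[m] / s2 + c * w[i] * pr / sigma2) / prec;
        double xnew = mean + R::norm_rand() / std::sqrt(prec);
        // update design row and eta incrementally
        double d_eta = beta[j] * (xnew - xold);
        X(i, j) = xnew;
        for (size_t t = 0; t < ints_of[j].size(); ++t) {
          int k = ints_of[j][t];
          double old_int = X(i, Pm + k);
          double new_int = X(i, int_pairs(k, 0)) * X(i, int_pairs(k, 1));
          X(i, Pm + k) = new_int;
          d_eta += beta[Pm + k] * (new_int - old_int);
        }
        eta[i] += d_eta;
      }
    }
    // --- store ----------------------------------------------------------
    if (it >= n_burn && ((it - n_burn) % thin == 0)) {
      S_alpha(keep, 0) = alpha;
      for (int j = 0; j < P; ++j) { S_b(keep, j) = b[j]; S_gam(keep, j) = gam[j]; }
      S_sigma(keep, 0) = std::sqrt(sigma2);
      for (int g = 0; g < G; ++g) S_sd(keep, g) = std::sqrt(sd2g[g]);
      int off = 0;
      for (int g = 0; g < G; ++g) {
        for (int k = 0; k < n_levels[g]; ++k) S_u(keep, off + k) = u[g][k];
        off += n_levels[g];
      }
      int cc = 0;
      for (int i = 0; i < N; ++i) if (is_cens[i]) S_ylat(keep, cc++) = y[i];
      for (int m = 0; m < Nmis; ++m) S_xmis(keep, m) = X(mis_row[m], mis_col[m]);
      ++keep;
    }
  }

  return List::create(_["alpha"] = S_alpha, _["b"] = S_b, _["gamma"] = S_gam,
                      _["sigma"] = S_sigma, _["sd_re"] = S_sd, _["u"] = S_u,
                      _["ylat"] = S_ylat, _["xmis"] = S_xmis);
}
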