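#include <Rcpp.h>
using namespace Rcpp;

// Single-site full conditionals of the whole-genome regression Gibbs
// sampler. All draws use R's RNG, so set.seed() in R makes chains
// bit-identical.

// marker effect: beta_l | rest ~ N(c * x'e, sigma_eps2 * c),
// c = 1 / (x'x + sigma_eps2 / sigma_beta2); x'e has beta_l's own
// contribution restored.
static inline double draw_beta_cond(double xtx, double xte,
                                    double sigma_eps2, double sigma_beta2) {
  double c = 1.0 / (xtx + sigma_eps2 / sigma_beta2);
  return R::rnorm(c * xte, std::sqrt(sigma_eps2 * c));
}

// flat-prior fixed effect: alpha_j | rest ~ N(w'e / w'w, sigma_eps2 / w'w)
static inline double draw_fixed_cond(double wtw, double wte,
                                     double sigma_eps2) {
  return R::rnorm(wte / wtw, std::sqrt(sigma_eps2 / wtw));
}

// scaled-inverse-chi-square(df, scale): df * scale / chisq_df
static inline double draw_scaled_inv_chi2(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
NumericVector cpp_rscaled_inv_chi2(int n, double df, double scale) {
  if (df <= 0 || scale <= 0) stop("df and scale must be positive");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_scaled_inv_chi2(df, scale);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rbeta_conditional(int n, double xtx, double xte,
                                    double sigma_eps2, double sigma_beta2) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_beta_cond(xtx, xte, sigma_eps2, sigma_beta2);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rfixed_conditional(int n, double wtw, double wte,
                                     double sigma_eps2) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_fixed_cond(wtw, wte, sigma_eps2);
  return out;
}

// variance update: scaled-inv-chi2(df0 + m, (ss + df0*scale0) / (df0 + m))
// [[Rcpp::export]]
NumericVector cpp_rvariance_conditional(int n, double ss, double m,
                                        double df0, double scale0) {
  NumericVector out(n);
  double df = df0 + m;
  double scale = (ss + df0 * scale0) / df;
  for (int i = 0; i < n; ++i) out[i] = draw_scaled_inv_chi2(df, scale);
  return out;
}

// Full Gibbs sampler.
// W: n x q fixed-effect design (first column the intercept), flat priors.
// X: n x L centered marker matrix (may have 0 columns).
// Residuals are updated incrementally after every single-site draw.
// fix_sb2 / fix_se2 < 0 mean "sample"; >= 0 clamp the variance (used by
// oracle tests against the ridge / mixed-model-equations solution).
// [[Rcpp::export]]
List cpp_wgr_gibbs(NumericVector y, NumericMatrix W, NumericMatrix X,
                   double df_beta, double scale_beta,
                   double df_eps, double scale_eps,
                   int n_iter, int burn_in, int thin,
                   double fix_sb2, double fix_se2,
                   bool save_beta) {
  const int n = y.size();
  const int q = W.ncol();
  const int L = X.ncol();
  const int n_keep = (n_iter - burn_in) / thin;

  std::vector<double> wtw(q), xtx(L);
  for (int j = 0; j < q; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }
  for (int l = 0; l < L; ++l) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, l) * X(i, l);
    xtx[l] = s;
  }

  std::vector<double> alpha(q, 0.0), beta(L, 0.0), e(y.begin(), y.end());
  double sb2 = (fix_sb2 >= 0) ? fix_sb2
             : (L > 0 ? df_beta * scale_beta / (df_beta + 2.0) : 1.0);
  double se2 = (fix_se2 >= 0) ? fix_se2
             : df_eps * scale_eps / (df_eps + 2.0);

  NumericMatrix alpha_chain(n_keep, q);
  NumericVector sb2_chain(n_keep), se2_chain(n_keep);
  NumericVector beta_mean(L);
  NumericMatrix beta_chain(save_beta ? n_keep : 0, save_beta ? L : 0);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, scalar-wise
    for (int j = 0; j < q; ++j) {
      double* wj = &W(0, j);
      double old = alpha[j], wte = 0;
      for (int i = 0; i < n; ++i) wte += wj[i] * (e[i] + old * wj[i]);
      double neu = draw_fixed_cond(wtw[j], wte, se2);
      double d = neu - old;
      for (int i = 0; i < n; ++i) e[i] -= d * wj[i];
      alpha[j] = neu;
    }
    // marker effects
    double ss_beta = 0;
    for (int l = 0; l < L; ++l) {
      double* xl = &X(0, l);
      double old = beta[l], xte = 0;
      for (int i = 0; i < n; ++i) xte += xl[i] * (e[i] + old * xl[i]);
      double neu = draw_beta_cond(xtx[l], xte, se2, sb2);
      double d = neu - old;
      for (int i = 0; i < n; ++i) e[i] -= d * xl[i];
      beta[l] = neu;
      ss_beta += neu * neu;
    }
    // marker-effect variance
    if (L > 0 && fix_sb2 < 0) {
      double df = df_beta + L;
      sb2 = draw_scaled_inv_chi2(df, (ss_beta + df_beta * scale_beta) / df);
    }
    // residual variance
    if (fix_se2 < 0) {
      double ee = 0;
      for (int i = 0; i < n; ++i) ee += e[i] * e[i];
      double df = df_eps + n;
      se2 = draw_scaled_inv_chi2(df, (ee + df_eps * scale_eps) / df);
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < q; ++j) alpha_chain(kept, j) = alpha[j];
      sb2_chain[kept] = sb2;
      se2_chain[kept] = se2;
      for (int l = 0; l < L; ++l) {
        beta_mean[l] += beta[l];
        if (save_beta) beta_chain(kept, l) = beta[l];
      }
      ++kept;
    }
  }
  if (n_keep > 0)
    for (int l = 0; l < L; ++l) beta_mean[l] /= n_keep;

  return List::create(_["alpha_chain"] = alpha_chain,
                      _["sigma_beta2_chain"] = sb2_chain,
                      _["sigma_eps2_chain"] = se2_chain,
                      _["beta_postmean"] = beta_mean,
                      _["beta_chain"] = beta_chain,
                      _["n_kept"] = kept);
}
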