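// Gibbs samplers for univariate and bivariate BayesC whole-genome regression.
// All random draws use R's RNG so results are reproducible via set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// sample variance (denominator n-1) of an arma vector
static double svar(const arma::vec &x) {
  const double n = (double)x.n_elem;
  if (n < 2.0) return 0.0;
  const double m = arma::mean(x);
  return arma::dot(x - m, x - m) / (n - 1.0);
}

// draw from scaled inverse chi-square: (df * scale) / chisq_df expressed as
// sum-of-squares form: ss / chisq_df
static double rinvchisq_ss(double ss, double df) {
  return ss / R::rchisq(df);
}

// Univariate BayesC Gibbs sampler.
// y: phenotype (n); X: fixed-effect design (n x p, may have 0 cols);
// W: marker dosages (n x m); pi: prior exclusion probability;
// nu: prior df for both scaled inv-chi2 priors; s_alpha, s_eps: prior scales;
// update_var: sample the two variances (FALSE fixes them at the s_* args'
// companion start values); nr: replication count in the h2 formula.
// [[Rcpp::export]]
List bayesc_gibbs_cpp(const arma::vec &y, const arma::mat &X,
                      const arma::mat &W, double pi_excl, double nu,
                      double s_alpha, double s_eps, bool update_var,
                      double sigma2_alpha_start, double sigma2_eps_start,
                      int n_iter, int burn_in, int thin, double nr,
                      bool keep_alpha) {
  const int n = y.n_elem, p = X.n_cols, m = W.n_cols;
  const int n_keep = (n_iter - burn_in) / thin;

  arma::vec b(p, arma::fill::zeros);
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec e = y;  // residual, maintained incrementally
  double s2a = sigma2_alpha_start, s2e = sigma2_eps_start;

  arma::vec xtx(p), wtw(m);
  for (int c = 0; c < p; ++c) xtx(c) = arma::dot(X.col(c), X.col(c));
  for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  arma::vec pip_count(m, arma::fill::zeros), alpha_sum(m, arma::fill::zeros);
  arma::vec chain_s2a(n_keep), chain_s2e(n_keep), chain_s2g(n_keep),
      chain_h2(n_keep), chain_ninc(n_keep);
  arma::mat chain_b(n_keep, p > 0 ? p : 1, arma::fill::zeros);
  arma::mat chain_alpha;
  if (keep_alpha) chain_alpha.set_size(n_keep, m);

  const bool all_in = (pi_excl <= 0.0), all_out = (pi_excl >= 1.0);
  const double log_prior_odds =
      (all_in || all_out) ? 0.0 : std::log((1.0 - pi_excl) / pi_excl);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior, one coordinate at a time
    for (int c = 0; c < p; ++c) {
      const double bold = b(c);
      const double rhs = arma::dot(X.col(c), e) + xtx(c) * bold;
      const double mu = rhs / xtx(c);
      const double bnew = mu + std::sqrt(s2e / xtx(c)) * norm_rand();
      b(c) = bnew;
      e += X.col(c) * (bold - bnew);
    }

    // marker effects with spike-and-slab prior
    int n_inc = 0;
    for (int j = 0; j < m; ++j) {
      const double aold = alpha(j);
      const double c2 = wtw(j);
      double anew = 0.0;
      if (c2 > 0.0 && !all_out) {
        const double rhs = arma::dot(W.col(j), e) + c2 * aold;
        const double v1 = c2 * s2a + s2e;
        bool include;
        if (all_in) {
          include = true;
        } else {
          const double log_bf =
              0.5 * (rhs * rhs * s2a / (s2e * v1)) - 0.5 * std::log(v1 / s2e);
          const double log_odds = log_prior_odds + log_bf;
          const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
          include = (unif_rand() < p1);
        }
        if (include) {
          const double lhs = c2 + s2e / s2a;
          anew = rhs / lhs + std::sqrt(s2e / lhs) * norm_rand();
          ++n_inc;
        }
      }
      if (anew != aold) e += W.col(j) * (aold - anew);
      alpha(j) = anew;
    }

    if (update_var) {
      const double ssa = arma::dot(alpha, alpha) + nu * s_alpha;
      s2a = rinvchisq_ss(ssa, nu + (double)n_inc);
      const double sse = arma::dot(e, e) + nu * s_eps;
      s2e = rinvchisq_ss(sse, nu + (double)n);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      arma::vec g = W * alpha;
      const double s2g = svar(g);
      chain_s2a(kept) = s2a;
      chain_s2e(kept) = s2e;
      chain_s2g(kept) = s2g;
      chain_h2(kept) = s2g / (s2g + s2e / nr);
      chain_ninc(kept) = (double)n_inc;
      for (int c = 0; c < p; ++c) chain_b(kept, c) = b(c);
      if (keep_alpha) chain_alpha.row(kept) = alpha.t();
      for (int j = 0; j < m; ++j) {
        if (alpha(j) != 0.0) pip_count(j) += 1.0;
        alpha_sum(j) += alpha(j);
      }
      ++kept;
    }
  }

  List out = List::create(
      _["pip"] = pip_count / (double)kept,
      _["post_mean_alpha"] = alpha_sum / (double)kept,
      _["chain_sigma2_alpha"] = chain_s2a, _["chain_sigma2_eps"] = chain_s2e,
      _["chain_sigma2_g"] = chain_s2g, _["chain_h2"] = chain_h2,
      _["chain_n_included"] = chain_ninc, _["chain_fixed"] = chain_b,
      _["n_retained"] = kept);
  if (keep_alpha) out["chain_alpha"] = chain_alpha;
  return out;
}

// 2x2 symmetric inverse via closed form
static arma::mat inv2(const arma::mat &S) {
  const double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
  arma::mat I(2, 2);
  I(0, 0) = S(1, 1) / det;
  I(1, 1) = S(0, 0) / det;
  I(0, 1) = I(1, 0) = -S(0, 1) / det;
  return I;
}

// Wishart draw, Bartlett decomposition, R RNG; S is the scale matrix.
static arma::mat rwish2(double df, const arma::mat &S) {
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverse-Wishart draw with scale S, df nu (X^-1 ~ W(nu, S^-1)); jittered
// retry on Cholesky failure, failure count accumulated in jitter_count.
static arma::mat riwish2(double nu, const arma::mat &S, int &jitter_count) {
  arma::mat Sinv = inv2((S + S.t()) / 2.0);
  for (int attempt = 0; attempt < 6; ++attempt) {
    arma::mat Si = Sinv;
    if (attempt > 0) {
      ++jitter_count;
      Si.diag() += std::pow(10.0, attempt - 9.0) * arma::trace(Sinv) / 2.0;
    }
    arma::mat Lok;
    if (!arma::chol(Lok, Si, "lower")) continue;
    arma::mat Wdraw(2, 2, arma::fill::zeros);
    {
      arma::mat A(2, 2, arma::fill::zeros);
      A(0, 0) = std::sqrt(R::rchisq(nu));
      A(1, 1) = std::sqrt(R::rchisq(nu - 1.0));
      A(1, 0) = norm_rand();
      arma::mat LA = Lok * A;
      Wdraw = LA * LA.t();
    }
    arma::mat out;
    if (arma::inv_sympd(out, Wdraw)) return (out + out.t()) / 2.0;
  }
  stop("inverse-Wishart draw failed after jittered retries");
}

// Bivariate BayesC Gibbs sampler with per-marker 4-category inclusion
// indicators delta in {(0,0),(0,1),(1,0),(1,1)}.
// Y: n x 2; X: n x p; W: n x m; log_delta_prior: length-4 (order 00,01,10,11);
// nu_w: inverse-Wishart df for both covariance priors; S_alpha, S_eps: scale
// matrices; nr: replication count for per-trait h2.
// [[Rcpp::export]]
List bayesc_biv_gibbs_cpp(const arma::mat &Y, const arma::mat &X,
                          const arma::mat &W, const arma::vec &log_delta_prior,
                          double nu_w, const arma::mat &S_alpha,
                          const arma::mat &S_eps, int n_iter, int burn_in,
                          int thin, double nr, const arma::umat &line_rows,
                          bool keep_g) {
  const int n = Y.n_rows, p = X.n_cols, m = W.n_cols;
  const int n_keep = (n_iter - burn_in) / thin;
  const int n_lines = line_rows.n_rows;  // rows of W per line for genetic values

  arma::mat B(p > 0 ? p : 1, 2, arma::fill::zeros);
  arma::mat alpha(m, 2, arma::fill::zeros);
  arma::umat delta(m, 2, arma::fill::zeros);
  arma::mat E = Y;  // residuals per trait
  arma::mat Sa = S_alpha, Se = S_eps;  // current covariance draws

  arma::vec xtx(p), wtw(m);
  for (int c = 0; c < p; ++c) xtx(c) = arma::dot(X.col(c), X.col(c));
  for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  arma::mat pip_count(m, 2, arma::fill::zeros), alpha_sum(m, 2, arma::fill::zeros);
  arma::mat cat_count(m, 4, arma::fill::zeros);
  arma::mat chain_Sa(n_keep, 4), chain_Se(n_keep, 4);
  arma::vec chain_rg(n_keep), chain_rg_Sa(n_keep), chain_h2_1(n_keep),
      chain_h2_2(n_keep);
  arma::cube chain_g;
  if (keep_g) chain_g.set_size(n_lines, 2, n_keep);
  int jitter_count = 0, kept = 0, rg_skipped = 0;

  for (int it = 0; it < n_iter; ++it) {
    arma::mat Om = inv2(Se);

    // fixed effects: per trait, per coordinate, flat prior
    for (int t = 0; t < 2; ++t) {
      const int s = 1 - t;
      for (int c = 0; c < p; ++c) {
        const double bold = B(c, t);
        const double xr = arma::dot(X.col(c), E.col(t)) + xtx(c) * bold;
        const double xes = arma::dot(X.col(c), E.col(s));
        const double mu = (xr + (Om(t, s) / Om(t, t)) * xes) / xtx(c);
        const double sd = std::sqrt(1.0 / (Om(t, t) * xtx(c)));
        const double bnew = mu + sd * norm_rand();
        B(c, t) = bnew;
        E.col(t) += X.col(c) * (bold - bnew);
      }
    }

    // markers: 4-category indicator with beta integrated out
    arma::mat SaInv = inv2(Sa);
    for (int j = 0; j < m; ++j) {
      const double c2 = wtw(j);
      arma::vec aold = alpha.row(j).t();
      // corrected rhs r = W_j' (E + w alpha_old')
      arma::vec r(2);
      r(0) = arma::dot(W.col(j), E.col(0)) + c2 * aold(0);
      r(1) = arma::dot(W.col(j), E.col(1)) + c2 * aold(1);
      arma::vec bvec = Om * r;  // length 2

      arma::vec logw(4);
      logw(0) = log_delta_prior(0);
      // single-trait categories: A={trait 1}=(1,0) index 2; A={trait 2}=(0,1) index 1
      for (int t = 0; t < 2; ++t) {
        const double P = c2 * Om(t, t) + 1.0 / Sa(t, t);
        const int cat = (t == 0) ? 2 : 1;
        logw(cat) = log_delta_prior(cat) - 0.5 * std::log(Sa(t, t) * P) +
                    0.5 * bvec(t) * bvec(t) / P;
      }
      // both traits
      arma::mat P2 = c2 * Om + SaInv;
      arma::mat P2inv = inv2(P2);
      const double detSaP2 =
          (Sa(0, 0) * Sa(1, 1) - Sa(0, 1) * Sa(1, 0)) *
          (P2(0, 0) * P2(1, 1) - P2(0, 1) * P2(1, 0));
      logw(3) = log_delta_prior(3) - 0.5 * std::log(detSaP2) +
                0.5 * arma::as_scalar(bvec.t() * P2inv * bvec);

      const double mx = logw.max();
      arma::vec wgt = arma::exp(logw - mx);
      wgt /= arma::accu(wgt);
      double u = unif_rand(), acc = 0.0;
      int cat = 3;
      for (int k2 = 0; k2 < 4; ++k2) {
        acc += wgt(k2);
        if (u <= acc) { cat = k2; break; }
      }

      arma::vec anew(2, arma::fill::zeros);
      if (cat == 1 || cat == 2) {
        const int t = (cat == 2) ? 0 : 1;
        const double P = c2 * Om(t, t) + 1.0 / Sa(t, t);
        anew(t) = bvec(t) / P + std::sqrt(1.0 / P) * norm_rand();
      } else if (cat == 3) {
        arma::vec mu2 = P2inv * bvec;
        arma::mat L = arma::chol(P2inv, "lower");
        arma::vec z(2);
        z(0) = norm_rand();
        z(1) = norm_rand();
        anew = mu2 + L * z;
      }
      delta(j, 0) = (cat == 2 || cat == 3) ? 1u : 0u;
      delta(j, 1) = (cat == 1 || cat == 3) ? 1u : 0u;
      if (anew(0) != aold(0)) E.col(0) += W.col(j) * (aold(0) - anew(0));
      if (anew(1) != aold(1)) E.col(1) += W.col(j) * (aold(1) - anew(1));
      alpha.row(j) = anew.t();
    }

    // Sigma_alpha: markers with at least one active trait; inactive beta
    // component filled in from its conditional prior given the active one
    arma::mat SS = S_eps;  // placeholder, overwritten below
    SS = S_alpha;
    int n_act = 0;
    for (int j = 0; j < m; ++j) {
      const bool a1 = delta(j, 0) > 0, a2 = delta(j, 1) > 0;
      if (!a1 && !a2) continue;
      arma::vec beta = alpha.row(j).t();
      if (a1 && !a2) {
        const double cm = Sa(1, 0) / Sa(0, 0);
        const double cv = Sa(1, 1) - Sa(1, 0) * Sa(0, 1) / Sa(0, 0);
        beta(1) = cm * beta(0) + std::sqrt(std::max(cv, 0.0)) * norm_rand();
      } else if (a2 && !a1) {
        const double cm = Sa(0, 1) / Sa(1, 1);
        const double cv = Sa(0, 0) - Sa(0, 1) * Sa(1, 0) / Sa(1, 1);
        beta(0) = cm * beta(1) + std::sqrt(std::max(cv, 0.0)) * norm_rand();
      }
      SS += beta * beta.t();
      ++n_act;
    }
    Sa = riwish2(nu_w + (double)n_act, SS, jitter_count);

    // Sigma_eps
    arma::mat SSe = S_eps + E.t() * E;
    Se = riwish2(nu_w + (double)n, SSe, jitter_count);

    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      arma::mat Gplot = W * alpha;  // n x 2 plot-level genetic values
      // line-level genetic values (first plot row per line; identical rows
      // of W within line give identical g)
      arma::mat Gline(n_lines, 2);
      for (int l = 0; l < n_lines; ++l) {
        Gline(l, 0) = Gplot(line_rows(l, 0), 0);
        Gline(l, 1) = Gplot(line_rows(l, 0), 1);
      }
      const double v1 = svar(Gline.col(0)), v2 = svar(Gline.col(1));
      if (v1 > 0.0 && v2 > 0.0) {
        chain_rg(kept) = arma::as_scalar(arma::cor(Gline.col(0), Gline.col(1)));
      } else {
        chain_rg(kept) = NA_REAL;
        ++rg_skipped;
      }
      chain_rg_Sa(kept) = Sa(0, 1) / std::sqrt(Sa(0, 0) * Sa(1, 1));
      const double vg1 = svar(Gplot.col(0)), vg2 = svar(Gplot.col(1));
      chain_h2_1(kept) = vg1 / (vg1 + Se(0, 0) / nr);
      chain_h2_2(kept) = vg2 / (vg2 + Se(1, 1) / nr);
      chain_Sa(kept, 0) = Sa(0, 0); chain_Sa(kept, 1) = Sa(0, 1);
      chain_Sa(kept, 2) = Sa(1, 0); chain_Sa(kept, 3) = Sa(1, 1);
      chain_Se(kept, 0) = Se(0, 0); chain_Se(kept, 1) = Se(0, 1);
      chain_Se(kept, 2) = Se(1, 0); chain_Se(kept, 3) = Se(1, 1);
      if (keep_g) chain_g.slice(kept) = Gline;
      for (int j = 0; j < m; ++j) {
        const bool a1 = delta(j, 0) > 0, a2 = delta(j, 1) > 0;
        if (a1) pip_count(j, 0) += 1.0;
        if (a2) pip_count(j, 1) += 1.0;
        const int cat = (a1 ? 2 : 0) + (a2 ? 1 : 0);
        cat_count(j, cat) += 1.0;
        alpha_sum(j, 0) += alpha(j, 0);
        alpha_sum(j, 1) += alpha(j, 1);
      }
      ++kept;
    }
  }

  List out = List::create(
      _["pip"] = pip_count / (double)kept,
      _["post_mean_alpha"] = alpha_sum / (double)kept,
      _["category_freq"] = cat_count / (double)kept,
      _["chain_Sigma_alpha"] = chain_Sa, _["chain_Sigma_eps"] = chain_Se,
      _["chain_rg"] = chain_rg, _["chain_rg_Sigma_alpha"] = chain_rg_Sa,
      _["chain_h2_trait1"] = chain_h2_1, _["chain_h2_trait2"] = chain_h2_2,
      _["n_retained"] = kept, _["jitter_count"] = jitter_count,
      _["rg_draws_skipped"] = rg_skipped);
  if (keep_g) out["chain_g"] = chain_g;
  return out;
}
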