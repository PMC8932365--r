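// Compiled core of the Metropolis-within-Gibbs sampler for the hierarchical
// coverage trend model:
//
//   y ~ N(X beta_country, tau^2 I),   beta_country ~ N(beta_region, S_r),
//   beta_region ~ N(beta_global, S_g),  beta_global ~ N(0, v0 I),
//   sds ~ Gamma (or half-Cauchy), tau ~ Uniform(0, upper),
//
// with optional country-by-quintile offsets on intercept and year slope.
//
// The hierarchical sds are updated by random-walk Metropolis on the log
// scale against the marginal likelihood with BOTH coefficient levels
// integrated out (everything is Gaussian, so the marginals are available
// through the Woodbury identity with only p x p factorizations); the
// location parameters are then redrawn exactly in one blocked pass
// global -> region -> country. This partially collapsed scheme removes the
// funnel degeneracy the near-improper Gamma sd prior induces in naive
// conditional updates. All randomness flows through R's RNG, so chains are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double SD_FLOOR_C = 1e-9;

static double log_sd_prior_c(double s, int type, double shape, double rate,
                             double hc_scale) {
  if (!(s > SD_FLOOR_C)) return R_NegInf;
  if (type == 0) return R::dgamma(s, shape, 1.0 / rate, 1);
  double z = s / hc_scale;
  return std::log(2.0) - std::log(M_PI * hc_scale * (1.0 + z * z));
}

static vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// Cholesky with escalating scale-aware jitter; near-singular precisions
// arise transiently when a weakly identified sd wanders large under the
// heavy-tailed prior during burn-in
static mat safe_chol(mat A) {
  A = (A + A.t()) / 2.0;
  double base = A.diag().max();
  if (!(base > 0)) base = 1.0;
  mat U;
  for (int t = 0; t < 8; ++t) {
    if (arma::chol(U, A)) return U;
    A.diag() += base * std::pow(10.0, t - 12);
  }
  Rcpp::stop("Cholesky factorization failed");
}

// draw from N(P^{-1} b, P^{-1}) given precision P and linear term b
static vec mvn_prec_draw(const mat &P, const vec &b) {
  mat U = safe_chol(P);                         // upper: U'U = P
  vec mu = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), b,
                                   arma::solve_opts::fast),
                       arma::solve_opts::fast);
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(P.n_rows), arma::solve_opts::fast);
}

// Per-country pieces of A_k^{-1} with A_k = tau2 I + X S_r X':
//   F = X' A^{-1} X,  h = X' A^{-1} y,  yAy = y' A^{-1} y,  ldet = log|A|.
// Computed through the thin-QR factorization X = Q R, for which
// A^{-1} = Q (tau2 I + R S R')^{-1} Q' + (I - Q Q') / tau2, giving
// cancellation-free positive-semidefinite results with only p x p algebra.
struct CountryPiece {
  mat F;
  vec h;
  double yAy;
  double ldet;
};

static CountryPiece country_piece(const mat &Q, const mat &R, const vec &qy,
                                  double yy, int n, const vec &d,
                                  double tau2) {
  int p = R.n_cols;
  mat RS = R;
  RS.each_row() %= (d % d).t();                  // R S
  mat M = RS * R.t();                            // R S R'
  M.diag() += tau2;
  mat U = safe_chol(M);
  mat BR = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), R,
                                   arma::solve_opts::fast),
                       arma::solve_opts::fast);
  vec Bqy = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), qy,
                                    arma::solve_opts::fast),
                        arma::solve_opts::fast);
  CountryPiece cp;
  cp.F = R.t() * BR;
  cp.h = R.t() * Bqy;
  cp.yAy = arma::dot(qy, Bqy) + (yy - arma::dot(qy, qy)) / tau2;
  cp.ldet = (n - p) * std::log(tau2) + 2.0 * arma::sum(arma::log(U.diag()));
  return cp;
}

// marginal log-likelihood of one region's data with both coefficient
// levels integrated out, given the aggregated country pieces
static double region_mll(const mat &F, const vec &h, double yAy, double ldet,
                         int n, const vec &beta_g, const vec &dg) {
  int p = dg.n_elem;
  vec hr = h - F * beta_g;
  double rAr = yAy - 2.0 * arma::dot(beta_g, h) +
    arma::dot(beta_g, F * beta_g);
  mat W = F;
  W.each_col() %= dg;
  W.each_row() %= dg.t();
  W.diag() += 1.0;
  mat U = safe_chol(W);
  vec v = dg % hr;
  vec Wiv = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), v,
                                    arma::solve_opts::fast),
                        arma::solve_opts::fast);
  (void)p;
  return -0.5 * (n * std::log(2.0 * M_PI) + ldet +
                 2.0 * arma::sum(arma::log(U.diag())) + rAr -
                 arma::dot(v, Wiv));
}

// [[Rcpp::export(name = ".sampler_chain_cpp")]]
List sampler_chain_cpp(const arma::vec &y, const arma::mat &X,
                       const arma::ivec &country,      // 1-based
                       const arma::ivec &region_of,    // 1-based, length K
                       const arma::ivec &quintile,     // 1-based or 0
                       List init, List prior, List cfg, List fixed) {
  const int n = y.n_elem, p = X.n_cols;
  const int K = region_of.n_elem;
  const int J = arma::max(region_of);
  const bool quint = arma::max(quintile) > 0;

  // ---- configuration
  const int iterations = cfg["iterations"], burn_in = cfg["burn_in"],
            thin = cfg["thin"];
  const bool adapt = cfg["adapt"];
  const double step_init = cfg["step_init"];
  const double beta_var = prior["beta_var"], sd_shape = prior["sd_shape"],
               sd_rate = prior["sd_rate"], tau_upper = prior["tau_upper"],
               hc_scale = prior["halfcauchy_scale"];
  const int sd_type = prior["sd_type"]; // 0 gamma, 1 half-Cauchy
  const bool fix_rs = fixed["fix_rs"], fix_gs = fixed["fix_gs"],
             fix_tau = fixed["fix_tau"];

  // ---- state
  vec beta_g = as<vec>(init["global_beta"]);
  mat beta_r = as<mat>(init["region_beta"]);     // J x p
  mat beta_c = as<mat>(init["country_beta"]);    // K x p
  mat sd_r = as<mat>(init["region_sd"]);         // J x p
  vec sd_g = as<vec>(init["global_sd"]);
  double tau = init["obs_sd"];
  mat q_int, q_slope;
  double q_sd_int = 0.25, q_sd_slope = 0.05;
  if (quint) {
    q_int = as<mat>(init["q_int"]);
    q_slope = as<mat>(init["q_slope"]);
    q_sd_int = init["q_sd_int"];
    q_sd_slope = init["q_sd_slope"];
  }

  // ---- per-country data blocks
  std::vector<uvec> rows_k(K);
  std::vector<mat> Xk(K), XtXk(K), Qk(K), Rk(K);
  std::vector<vec> yk(K);
  std::vector<uvec> members(J);
  {
    std::vector<std::vector<arma::uword>> tmp(K), mem(J);
    for (int i = 0; i < n; ++i) tmp[country[i] - 1].push_back(i);
    for (int k = 0; k < K; ++k) {
      rows_k[k] = uvec(tmp[k]);
      Xk[k] = X.rows(rows_k[k]);
      XtXk[k] = Xk[k].t() * Xk[k];
      yk[k] = y.elem(rows_k[k]);
      mem[region_of[k] - 1].push_back(k);
      // thin QR, padded with zero rows when a country has fewer
      // observations than coefficients (R then has the same null space)
      mat Xpad = Xk[k];
      if ((int)Xpad.n_rows < p) {
        Xpad = arma::join_cols(Xpad, mat(p - Xpad.n_rows, p,
                                         arma::fill::zeros));
      }
      arma::qr_econ(Qk[k], Rk[k], Xpad);
      Qk[k] = Qk[k].head_rows(Xk[k].n_rows);
    }
    for (int j = 0; j < J; ++j) members[j] = uvec(mem[j]);
  }
  // quintile cell indices within each country's rows
  std::vector<std::vector<uvec>> kq(K);
  if (quint) {
    for (int k = 0; k < K; ++k) {
      std::vector<std::vector<arma::uword>> cells(5);
      for (arma::uword i = 0; i < rows_k[k].n_elem; ++i) {
        cells[quintile[rows_k[k][i]] - 1].push_back(i);
      }
      kq[k].resize(5);
      for (int q = 0; q < 5; ++q) kq[k][q] = uvec(cells[q]);
    }
  }

  // ---- adaptation state and acceptance bookkeeping
  mat ls_rs(J, p, arma::fill::value(std::log(step_init)));
  vec ls_gs(p, arma::fill::value(std::log(step_init)));
  double ls_tau = std::log(step_init), ls_qa = std::log(step_init),
         ls_qb = std::log(step_init);
  double acc_rs = 0, att_rs = 0, acc_gs = 0, att_gs = 0, acc_tau = 0,
         att_tau = 0, acc_q = 0, att_q = 0;
  double burn_rs = 0, burn_gs = 0, burn_tau = 0, burn_q = 0;

  const int n_keep = (iterations - burn_in) / thin;
  int n_par = p + J * p + K * p + J * p + p + 1;
  if (quint) n_par += 2 * K * 5 + 2;
  mat out(n_keep, n_par);
  int keep_i = 0;

  std::vector<CountryPiece> pieces(K);
  std::vector<vec> yadj(K), Xyk(K), qyk(K);
  vec yyk(K);

  for (int it = 1; it <= iterations; ++it) {
    const bool in_burn = it <= burn_in;
    const double gam =
      (adapt && in_burn) ? std::min(0.25, 2.0 / std::sqrt((double)it)) : 0.0;
    const double tau2 = tau * tau;

    // outcome net of quintile offsets, and its cross-products
    for (int k = 0; k < K; ++k) {
      yadj[k] = yk[k];
      if (quint) {
        for (int q = 0; q < 5; ++q) {
          const uvec &cell = kq[k][q];
          for (arma::uword ii = 0; ii < cell.n_elem; ++ii) {
            arma::uword i = cell[ii];
            yadj[k][i] -= q_int(k, q) + q_slope(k, q) * Xk[k](i, 1);
          }
        }
      }
      Xyk[k] = Xk[k].t() * yadj[k];
      qyk[k] = Qk[k].t() * yadj[k];
      yyk[k] = arma::dot(yadj[k], yadj[k]);
      pieces[k] = country_piece(Qk[k], Rk[k], qyk[k], yyk[k],
                                rows_k[k].n_elem,
                                sd_r.row(region_of[k] - 1).t(), tau2);
    }

    // region aggregates and cached marginal log-likelihoods
    std::vector<mat> Fj(J, mat(p, p, arma::fill::zeros));
    std::vector<vec> hj(J, vec(p, arma::fill::zeros));
    vec yAyj(J, arma::fill::zeros), ldetj(J, arma::fill::zeros);
    arma::ivec nj(J, arma::fill::zeros);
    auto aggregate = [&](int j) {
      Fj[j].zeros(); hj[j].zeros(); yAyj[j] = 0; ldetj[j] = 0; nj[j] = 0;
      for (arma::uword m = 0; m < members[j].n_elem; ++m) {
        int k = members[j][m];
        Fj[j] += pieces[k].F;
        hj[j] += pieces[k].h;
        yAyj[j] += pieces[k].yAy;
        ldetj[j] += pieces[k].ldet;
        nj[j] += rows_k[k].n_elem;
      }
    };
    vec mll(J);
    for (int j = 0; j < J; ++j) {
      aggregate(j);
      mll[j] = region_mll(Fj[j], hj[j], yAyj[j], ldetj[j], nj[j], beta_g, sd_g);
    }

    // --- between-country sds: fully collapsed Metropolis, per component
    if (!fix_rs) {
      for (int j = 0; j < J; ++j) {
        for (int c = 0; c < p; ++c) {
          double cur = sd_r(j, c);
          double prop = cur * std::exp(R::norm_rand() *
                                       std::exp(ls_rs(j, c)));
          double lp_prop = log_sd_prior_c(prop, sd_type, sd_shape, sd_rate,
                                          hc_scale);
          bool ok = false;
          if (R_finite(lp_prop)) {
            sd_r(j, c) = prop;
            std::vector<CountryPiece> saved;
            for (arma::uword m = 0; m < members[j].n_elem; ++m) {
              int k = members[j][m];
              saved.push_back(pieces[k]);
              pieces[k] = country_piece(Qk[k], Rk[k], qyk[k], yyk[k],
                                        rows_k[k].n_elem, sd_r.row(j).t(),
                                        tau2);
            }
            aggregate(j);
            double mll_prop = region_mll(Fj[j], hj[j], yAyj[j], ldetj[j],
                                         nj[j], beta_g, sd_g);
            double la = mll_prop + lp_prop + std::log(prop) - mll[j] -
              log_sd_prior_c(cur, sd_type, sd_shape, sd_rate, hc_scale) -
              std::log(cur);
            ok = R_finite(la) && std::log(R::unif_rand()) < la;
            if (ok) {
              mll[j] = mll_prop;
            } else {
              sd_r(j, c) = cur;
              for (arma::uword m = 0; m < members[j].n_elem; ++m) {
                pieces[members[j][m]] = saved[m];
              }
              aggregate(j);
            }
          }
          if (!in_burn) { att_rs += 1; acc_rs += ok; } else burn_rs += ok;
          ls_rs(j, c) += gam * ((ok ? 1.0 : 0.0) - 0.44);
        }
      }
    }

    // --- between-region sds: collapsed Metropolis, per component
    if (!fix_gs) {
      for (int c = 0; c < p; ++c) {
        double cur = sd_g[c];
        double prop = cur * std::exp(R::norm_rand() * std::exp(ls_gs[c]));
        double lp_prop = log_sd_prior_c(prop, sd_type, sd_shape, sd_rate,
                                        hc_scale);
        bool ok = false;
        if (R_finite(lp_prop)) {
          vec sd_g_prop = sd_g;
          sd_g_prop[c] = prop;
          double mll_prop = 0, mll_cur = 0;
          for (int j = 0; j < J; ++j) {
            mll_prop += region_mll(Fj[j], hj[j], yAyj[j], ldetj[j], nj[j],
                                   beta_g, sd_g_prop);
            mll_cur += mll[j];
          }
          double la = mll_prop + lp_prop + std::log(prop) - mll_cur -
            log_sd_prior_c(cur, sd_type, sd_shape, sd_rate, hc_scale) -
            std::log(cur);
          ok = R_finite(la) && std::log(R::unif_rand()) < la;
          if (ok) {
            sd_g = sd_g_prop;
            for (int j = 0; j < J; ++j) {
              mll[j] = region_mll(Fj[j], hj[j], yAyj[j], ldetj[j], nj[j],
                                  beta_g, sd_g);
            }
          }
        }
        if (!in_burn) { att_gs += 1; acc_gs += ok; } else burn_gs += ok;
        ls_gs[c] += gam * ((ok ? 1.0 : 0.0) - 0.44);
      }
    }

    // --- blocked location draw: global mean with both levels integrated
    //     out, then region means (countries integrated out), then country
    //     coefficients -- one exact pass down the hierarchy
    {
      mat prec(p, p, arma::fill::zeros);
      prec.diag() += 1.0 / beta_var;
      vec rhs(p, arma::fill::zeros);
      for (int j = 0; j < J; ++j) {
        mat W = Fj[j];
        W.each_col() %= sd_g;
        W.each_row() %= sd_g.t();
        W.diag() += 1.0;
        mat FD = Fj[j];
        FD.each_row() %= sd_g.t();              // F diag(dg)
        mat U = safe_chol(W);
        mat WiDF = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), FD.t(),
                                           arma::solve_opts::fast),
                               arma::solve_opts::fast);
        prec += Fj[j] - FD * WiDF;
        vec dh = sd_g % hj[j];
        vec Widh = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), dh,
                                           arma::solve_opts::fast),
                               arma::solve_opts::fast);
        rhs += hj[j] - FD * Widh;
      }
      beta_g = mvn_prec_draw(prec, rhs);
    }
    for (int j = 0; j < J; ++j) {
      vec pg = 1.0 / (sd_g % sd_g);
      mat prec = Fj[j];
      prec.diag() += pg;
      vec rhs = hj[j] + pg % beta_g;
      beta_r.row(j) = mvn_prec_draw(prec, rhs).t();
    }
    for (int k = 0; k < K; ++k) {
      int j = region_of[k] - 1;
      vec pr = 1.0 / arma::square(sd_r.row(j).t());
      mat prec = XtXk[k] / tau2;
      prec.diag() += pr;
      vec rhs = Xyk[k] / tau2 + pr % beta_r.row(j).t();
      beta_c.row(k) = mvn_prec_draw(prec, rhs).t();
    }

    // --- quintile extension: shrinkage sds updated by Metropolis against
    //     the marginal likelihood with the offsets integrated out (the
    //     same anti-funnel device as the coefficient-level sds), then one
    //     exact joint draw of (intercept, slope) offsets per cell, then
    //     the sum-to-zero identification sweep
    if (quint) {
      // per-cell residual statistics against the current country predictor
      // cell model: r ~ N(Z c, tau2 I), Z = [1, yr], c ~ N(0, diag(sa2, sb2))
      struct Cell { double n, sy, syr, syr2, sr, sryr, srr; };
      std::vector<Cell> cells;
      cells.reserve(K * 5);
      for (int k = 0; k < K; ++k) {
        vec eta0 = Xk[k] * beta_c.row(k).t();
        for (int q = 0; q < 5; ++q) {
          const uvec &cell = kq[k][q];
          Cell cl = {0, 0, 0, 0, 0, 0, 0};
          cl.n = cell.n_elem;
          for (arma::uword ii = 0; ii < cell.n_elem; ++ii) {
            arma::uword i = cell[ii];
            double r = yk[k][i] - eta0[i];
            double yr = Xk[k](i, 1);
            cl.syr += yr; cl.syr2 += yr * yr;
            cl.sr += r; cl.sryr += r * yr; cl.srr += r * r;
          }
          cells.push_back(cl);
        }
      }
      auto cells_mll = [&](double sa, double sb) {
        double tot = 0;
        vec d = {sa, sb};
        for (const Cell &cl : cells) {
          if (cl.n == 0) continue;
          mat ZtZ = {{cl.n, cl.syr}, {cl.syr, cl.syr2}};
          vec Zr = {cl.sr, cl.sryr};
          mat G = ZtZ;
          G.each_col() %= d;
          G.each_row() %= d.t();
          G.diag() += tau2;
          mat U = safe_chol(G);
          vec v = arma::solve(arma::trimatl(U.t()), d % Zr,
                              arma::solve_opts::fast);
          double ldet = (cl.n - 2) * std::log(tau2) +
            2.0 * arma::sum(arma::log(U.diag()));
          double quad = (cl.srr - arma::dot(v, v)) / tau2;
          tot += -0.5 * (cl.n * std::log(2.0 * M_PI) + ldet + quad);
        }
        return tot;
      };
      double cur_mll = cells_mll(q_sd_int, q_sd_slope);
      // intercept-offset sd
      {
        double prop = q_sd_int * std::exp(R::norm_rand() * std::exp(ls_qa));
        double lp = log_sd_prior_c(prop, sd_type, sd_shape, sd_rate, hc_scale);
        bool ok = false;
        if (R_finite(lp)) {
          double mll_p = cells_mll(prop, q_sd_slope);
          double la = mll_p + lp + std::log(prop) - cur_mll -
            log_sd_prior_c(q_sd_int, sd_type, sd_shape, sd_rate, hc_scale) -
            std::log(q_sd_int);
          ok = R_finite(la) && std::log(R::unif_rand()) < la;
          if (ok) { q_sd_int = prop; cur_mll = mll_p; }
        }
        if (!in_burn) { att_q += 1; acc_q += ok; } else burn_q += ok;
        ls_qa += gam * ((ok ? 1.0 : 0.0) - 0.44);
      }
      // slope-offset sd
      {
        double prop = q_sd_slope * std::exp(R::norm_rand() * std::exp(ls_qb));
        double lp = log_sd_prior_c(prop, sd_type, sd_shape, sd_rate, hc_scale);
        bool ok = false;
        if (R_finite(lp)) {
          double mll_p = cells_mll(q_sd_int, prop);
          double la = mll_p + lp + std::log(prop) - cur_mll -
            log_sd_prior_c(q_sd_slope, sd_type, sd_shape, sd_rate,
                           hc_scale) - std::log(q_sd_slope);
          ok = R_finite(la) && std::log(R::unif_rand()) < la;
          if (ok) { q_sd_slope = prop; cur_mll = mll_p; }
        }
        if (!in_burn) { att_q += 1; acc_q += ok; } else burn_q += ok;
        ls_qb += gam * ((ok ? 1.0 : 0.0) - 0.44);
      }
      // joint conjugate draw of (a, b) per cell, then the sweep
      int ci = 0;
      for (int k = 0; k < K; ++k) {
        for (int q = 0; q < 5; ++q, ++ci) {
          const Cell &cl = cells[ci];
          if (cl.n == 0) {
            q_int(k, q) = R::rnorm(0.0, q_sd_int);
            q_slope(k, q) = R::rnorm(0.0, q_sd_slope);
            continue;
          }
          mat P = {{cl.n / tau2 + 1.0 / (q_sd_int * q_sd_int),
                    cl.syr / tau2},
                   {cl.syr / tau2,
                    cl.syr2 / tau2 + 1.0 / (q_sd_slope * q_sd_slope)}};
          vec b2 = {cl.sr / tau2, cl.sryr / tau2};
          vec drw = mvn_prec_draw(P, b2);
          q_int(k, q) = drw[0];
          q_slope(k, q) = drw[1];
        }
        double am = arma::mean(q_int.row(k));
        double bm = arma::mean(q_slope.row(k));
        q_int.row(k) -= am;
        q_slope.row(k) -= bm;
        beta_c(k, 0) += am;
        beta_c(k, 1) += bm;
      }
    }

    // --- observation noise sd: log-scale walk under the Uniform prior
    if (!fix_tau) {
      double ss = 0;
      for (int k = 0; k < K; ++k) {
        vec res = yk[k] - Xk[k] * beta_c.row(k).t();
        if (quint) {
          for (int q = 0; q < 5; ++q) {
            const uvec &cell = kq[k][q];
            for (arma::uword ii = 0; ii < cell.n_elem; ++ii) {
              arma::uword i = cell[ii];
              res[i] -= q_int(k, q) + q_slope(k, q) * Xk[k](i, 1);
            }
          }
        }
        ss += arma::dot(res, res);
      }
      double cur = tau;
      double prop = cur * std::exp(R::norm_rand() * std::exp(ls_tau));
      bool ok = false;
      if (prop < tau_upper && prop > 0) {
        double la = (-n * std::log(prop) - ss / (2 * prop * prop) +
                     std::log(prop)) -
          (-n * std::log(cur) - ss / (2 * cur * cur) + std::log(cur));
        ok = R_finite(la) && std::log(R::unif_rand()) < la;
        if (ok) tau = prop;
      }
      if (!in_burn) { att_tau += 1; acc_tau += ok; } else burn_tau += ok;
      ls_tau += gam * ((ok ? 1.0 : 0.0) - 0.44);
    }

    // --- record (pack order matches the R-side layout: column-major)
    if (!in_burn && (it - burn_in) % thin == 0) {
      int pos = 0;
      arma::rowvec row(n_par);
      for (int c = 0; c < p; ++c) row[pos++] = beta_g[c];
      for (int c = 0; c < p; ++c)
        for (int j = 0; j < J; ++j) row[pos++] = beta_r(j, c);
      for (int c = 0; c < p; ++c)
        for (int k = 0; k < K; ++k) row[pos++] = beta_c(k, c);
      for (int c = 0; c < p; ++c)
        for (int j = 0; j < J; ++j) row[pos++] = sd_r(j, c);
      for (int c = 0; c < p; ++c) row[pos++] = sd_g[c];
      row[pos++] = tau;
      if (quint) {
        for (int q = 0; q < 5; ++q)
          for (int k = 0; k < K; ++k) row[pos++] = q_int(k, q);
        for (int q = 0; q < 5; ++q)
          for (int k = 0; k < K; ++k) row[pos++] = q_slope(k, q);
        row[pos++] = q_sd_int;
        row[pos++] = q_sd_slope;
      }
      out.row(keep_i++) = row;
    }
  }

  return List::create(
    _["draws"] = out,
    _["acceptance"] = NumericVector::create(
      _["region_sd"] = att_rs > 0 ? acc_rs / att_rs : NA_REAL,
      _["global_sd"] = att_gs > 0 ? acc_gs / att_gs : NA_REAL,
      _["tau"] = att_tau > 0 ? acc_tau / att_tau : NA_REAL,
      _["q_sd"] = att_q > 0 ? acc_q / att_q : NA_REAL),
    _["burn_accept"] = NumericVector::create(
      _["region_sd"] = burn_rs, _["global_sd"] = burn_gs,
      _["tau"] = burn_tau, _["q_sd"] = burn_q));
}

// ---------------------------------------------------------------------------
// Hierarchical logistic sampler for the individual-level determinant model:
//   y_i ~ Bernoulli(logit^{-1}(x_i' beta + u[country_i])),
//   beta_j ~ N(0, v0), u_k ~ N(0, s_u^2), s_u ~ sd prior.
// All blocks are adaptive random-walk Metropolis on the log-posterior.
// Dummy columns are centered internally (which decorrelates them from the
// intercept; the recorded draws are mapped back to the 0/1 coding), and the
// country-intercept mean is swept into the global intercept each iteration.

static double log1pexp_c(double x) {
  if (x > 33.0) return x;
  if (x > 18.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".logistic_chain_cpp")]]
List logistic_chain_cpp(const arma::vec &y, const arma::mat &X,
                        const arma::ivec &country, const arma::vec &beta0,
                        const arma::mat &prop_chol, List prior, List cfg) {
  const int n = y.n_elem, p = X.n_cols;
  const int K = arma::max(country);
  const int iterations = cfg["iterations"], burn_in = cfg["burn_in"],
            thin = cfg["thin"];
  const bool adapt = cfg["adapt"];
  const double beta_var = prior["beta_var"], sd_shape = prior["sd_shape"],
               sd_rate = prior["sd_rate"], hc_scale = prior["halfcauchy_scale"];
  const int sd_type = prior["sd_type"];

  vec b = beta0;
  vec u(K, arma::fill::zeros);
  double s_u = 0.3;

  std::vector<uvec> rows_k(K);
  {
    std::vector<std::vector<arma::uword>> tmp(K);
    for (int i = 0; i < n; ++i) tmp[country[i] - 1].push_back(i);
    for (int k = 0; k < K; ++k) rows_k[k] = uvec(tmp[k]);
  }

  vec eta = X * b;
  for (int i = 0; i < n; ++i) eta[i] += u[country[i] - 1];
  vec ll(n);
  for (int i = 0; i < n; ++i) ll[i] = y[i] * eta[i] - log1pexp_c(eta[i]);

  // global log step for the joint shaped proposal; 2.38/sqrt(p) is the
  // usual random-walk scaling for a matched proposal shape
  double ls_b = std::log(2.38 / std::sqrt((double)p));
  vec ls_u(K, arma::fill::value(std::log(0.1)));
  double ls_s = std::log(0.3);
  double acc_b = 0, att_b = 0, acc_u = 0, att_u = 0, acc_s = 0, att_s = 0;
  double burn_b = 0, burn_u = 0, burn_s = 0;

  const int n_keep = (iterations - burn_in) / thin;
  mat out(n_keep, p + K + 1);
  int keep_i = 0;
  vec eta_new(n), ll_new(n);

  for (int it = 1; it <= iterations; ++it) {
    const bool in_burn = it <= burn_in;
    const double gam =
      (adapt && in_burn) ? std::min(0.25, 2.0 / std::sqrt((double)it)) : 0.0;

    // fixed effects: one joint random-walk Metropolis step, shaped by the
    // Cholesky factor of the maximum-likelihood covariance
    {
      vec z = rnorm_vec(p);
      vec delta = std::exp(ls_b) * (prop_chol * z);
      vec eta_d = X * delta;
      double cur_sum = 0, new_sum = 0;
      for (int i = 0; i < n; ++i) {
        double e = eta[i] + eta_d[i];
        eta_new[i] = e;
        ll_new[i] = y[i] * e - log1pexp_c(e);
        cur_sum += ll[i];
        new_sum += ll_new[i];
      }
      double la = new_sum - cur_sum;
      for (int j = 0; j < p; ++j) {
        la += R::dnorm(b[j] + delta[j], 0.0, std::sqrt(beta_var), 1) -
          R::dnorm(b[j], 0.0, std::sqrt(beta_var), 1);
      }
      bool ok = R_finite(la) && std::log(R::unif_rand()) < la;
      if (ok) {
        b += delta;
        eta.swap(eta_new);
        ll.swap(ll_new);
      }
      if (!in_burn) { att_b += 1; acc_b += ok; } else burn_b += ok;
      ls_b += gam * ((ok ? 1.0 : 0.0) - 0.234);
    }

    // country intercepts, then sweep their mean into the intercept
    for (int k = 0; k < K; ++k) {
      double delta = R::norm_rand() * std::exp(ls_u[k]);
      const uvec &r = rows_k[k];
      double cur_sum = 0, new_sum = 0;
      for (arma::uword ii = 0; ii < r.n_elem; ++ii) {
        arma::uword i = r[ii];
        double e = eta[i] + delta;
        cur_sum += ll[i];
        new_sum += y[i] * e - log1pexp_c(e);
      }
      double la = new_sum - cur_sum +
        R::dnorm(u[k] + delta, 0.0, s_u, 1) - R::dnorm(u[k], 0.0, s_u, 1);
      bool ok = R_finite(la) && std::log(R::unif_rand()) < la;
      if (ok) {
        u[k] += delta;
        for (arma::uword ii = 0; ii < r.n_elem; ++ii) {
          arma::uword i = r[ii];
          eta[i] += delta;
          ll[i] = y[i] * eta[i] - log1pexp_c(eta[i]);
        }
      }
      if (!in_burn) { att_u += 1; acc_u += ok; } else burn_u += ok;
      ls_u[k] += gam * ((ok ? 1.0 : 0.0) - 0.44);
    }
    double um = arma::mean(u);
    u -= um;
    b[0] += um;   // eta is unchanged by the sweep

    // random-intercept sd
    {
      double prop = s_u * std::exp(R::norm_rand() * std::exp(ls_s));
      double lp_prop = log_sd_prior_c(prop, sd_type, sd_shape, sd_rate,
                                      hc_scale);
      bool ok = false;
      if (R_finite(lp_prop)) {
        double ssu = arma::dot(u, u);
        double la = -K * std::log(prop) - ssu / (2 * prop * prop) + lp_prop +
          std::log(prop) + K * std::log(s_u) + ssu / (2 * s_u * s_u) -
          log_sd_prior_c(s_u, sd_type, sd_shape, sd_rate, hc_scale) -
          std::log(s_u);
        ok = R_finite(la) && std::log(R::unif_rand()) < la;
        if (ok) s_u = prop;
      }
      if (!in_burn) { att_s += 1; acc_s += ok; } else burn_s += ok;
      ls_s += gam * ((ok ? 1.0 : 0.0) - 0.44);
    }

    if (!in_burn && (it - burn_in) % thin == 0) {
      arma::rowvec row(p + K + 1);
      for (int j = 0; j < p; ++j) row[j] = b[j];
      for (int k = 0; k < K; ++k) row[p + k] = u[k];
      row[p + K] = s_u;
      out.row(keep_i++) = row;
    }
  }

  return List::create(
    _["draws"] = out,
    _["acceptance"] = NumericVector::create(
      _["beta"] = att_b > 0 ? acc_b / att_b : NA_REAL,
      _["u"] = att_u > 0 ? acc_u / att_u : NA_REAL,
      _["sigma_country"] = att_s > 0 ? acc_s / att_s : NA_REAL),
    _["burn_accept"] = NumericVector::create(
      _["beta"] = burn_b, _["u"] = burn_u, _["sigma_country"] = burn_s));
}
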