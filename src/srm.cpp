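#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the combined stochastic block +
// social relations model on one zone's ordered pairs:
//
//   logit P(Y_ij = 1) = w_ij . beta + s_i + r_j + d_ij
//
// where w_ij stacks the block-offset indicators (preference and optionally
// gender), focal / target covariates and dyad covariates; (s_i, r_i) are
// bivariate-normal sender/receiver effects with SDs sigma_s, sigma_r and
// correlation rho_sr; (d_ij, d_ji) are dyad effects with common SD sigma_d
// and reciprocity correlation rho_d.  In reports mode, Y is latent and each
// side's statement about a pair is observed through sensitivity lambda1 and
// false-positive rate lambda0 (Beta priors, conjugate updates).
//
// Rows of W are dyad-major: rows 2d and 2d+1 are the ordered pairs (i, j)
// and (j, i) of unordered dyad d.  Proposal scales adapt toward 0.44 (scalar
// blocks) during burn-in and freeze afterwards.
// [[Rcpp::export]]
List srm_mcmc_cpp(NumericMatrix W, IntegerVector row_i, IntegerVector row_j,
                  IntegerVector y_obs, IntegerVector nobs, IntegerVector npos,
                  bool reports_mode, bool dyad_effects,
                  double beta_prior_sd, double sd_prior_scale,
                  double l1_a, double l1_b, double l0_a, double l0_b,
                  int iter, int burn, int thin, NumericVector beta_init) {
  const int R = W.nrow(), p = W.ncol();
  const int D = R / 2;
  int n = 0;
  for (int r = 0; r < R; ++r) n = std::max(n, std::max(row_i[r], row_j[r]) + 1);

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> s(n, 0.0), rr(n, 0.0), dy(R, 0.0);
  double sig_s = 0.3, sig_r = 0.3, rho_sr = 0.0, sig_d = 0.3, rho_d = 0.0;
  double lambda1 = 0.8, lambda0 = 0.01;

  std::vector<int> y(R, 0);
  if (reports_mode) {
    for (int r = 0; r < R; ++r) y[r] = npos[r] > 0 ? 1 : 0;
  } else {
    for (int r = 0; r < R; ++r) y[r] = y_obs[r];
  }

  // cached linear predictor
  std::vector<double> lin(R, 0.0);
  auto recompute_lin = [&]() {
    for (int r = 0; r < R; ++r) {
      double v = 0.0;
      for (int k = 0; k < p; ++k) v += W(r, k) * beta[k];
      lin[r] = v + s[row_i[r]] + rr[row_j[r]] + dy[r];
    }
  };
  recompute_lin();

  std::vector<std::vector<int>> rows_focal(n), rows_target(n);
  for (int r = 0; r < R; ++r) {
    rows_focal[row_i[r]].push_back(r);
    rows_target[row_j[r]].push_back(r);
  }

  auto ll_row = [&](int r, double l) {
    // log Bernoulli(y | plogis(l)), numerically stable
    return y[r] ? -std::log1p(std::exp(-l)) : -std::log1p(std::exp(l));
  };
  auto ll_rows = [&](const std::vector<int>& rows, double delta_who,
                     int who_is_focal, int node) {
    (void)who_is_focal; (void)node;
    double acc = 0.0;
    for (int r : rows) acc += ll_row(r, lin[r] + delta_who) - ll_row(r, lin[r]);
    return acc;
  };

  auto bvn_lpdf = [](double a, double b, double sa, double sb, double rho) {
    double z = a * a / (sa * sa) - 2.0 * rho * a * b / (sa * sb) +
               b * b / (sb * sb);
    return -std::log(sa) - std::log(sb) - 0.5 * std::log(1.0 - rho * rho) -
           z / (2.0 * (1.0 - rho * rho));
  };

  // adaptive proposal scales
  std::vector<double> sc_beta(p, 0.1);
  double sc_s = 0.3, sc_r = 0.3, sc_d = 0.4, sc_var = 0.2;
  auto adapt = [](double& sc, double acc_p, int it) {
    sc *= std::exp((acc_p - 0.44) / std::sqrt((double)it + 1.0));
    sc = std::min(std::max(sc, 1e-3), 10.0);
  };

  int keep = iter / thin;
  int extra = 7;  // sig_s sig_r rho_sr sig_d rho_d lambda1 lambda0
  NumericMatrix draws(keep, p + extra);
  NumericMatrix re_mean(n, 2);
  int k = 0;

  for (int it = 0; it < burn + iter; ++it) {
    bool adapting = it < burn;

    // --- beta, per coordinate with cached lin ---
    for (int kk = 0; kk < p; ++kk) {
      double prop = beta[kk] + norm_rand() * sc_beta[kk];
      double delta = prop - beta[kk];
      double dll = 0.0;
      for (int r = 0; r < R; ++r) {
        if (W(r, kk) != 0.0)
          dll += ll_row(r, lin[r] + delta * W(r, kk)) - ll_row(r, lin[r]);
      }
      dll += R::dnorm(prop, 0.0, beta_prior_sd, 1) -
             R::dnorm(beta[kk], 0.0, beta_prior_sd, 1);
      double apr = std::min(1.0, std::exp(dll));
      if (unif_rand() < apr) {
        for (int r = 0; r < R; ++r)
          if (W(r, kk) != 0.0) lin[r] += delta * W(r, kk);
        beta[kk] = prop;
      }
      if (adapting) adapt(sc_beta[kk], apr, it);
    }

    // --- sender effects ---
    double acc_s = 0.0;
    for (int i = 0; i < n; ++i) {
      double prop = s[i] + norm_rand() * sc_s;
      double dll = ll_rows(rows_focal[i], prop - s[i], 1, i);
      dll += bvn_lpdf(prop, rr[i], sig_s, sig_r, rho_sr) -
             bvn_lpdf(s[i], rr[i], sig_s, sig_r, rho_sr);
      double apr = std::min(1.0, std::exp(dll));
      acc_s += apr;
      if (unif_rand() < apr) {
        for (int r : rows_focal[i]) lin[r] += prop - s[i];
        s[i] = prop;
      }
    }
    if (adapting) adapt(sc_s, acc_s / n, it);

    // --- receiver effects ---
    double acc_r = 0.0;
    for (int i = 0; i < n; ++i) {
      double prop = rr[i] + norm_rand() * sc_r;
      double dll = ll_rows(rows_target[i], prop - rr[i], 0, i);
      dll += bvn_lpdf(s[i], prop, sig_s, sig_r, rho_sr) -
             bvn_lpdf(s[i], rr[i], sig_s, sig_r, rho_sr);
      double apr = std::min(1.0, std::exp(dll));
      acc_r += apr;
      if (unif_rand() < apr) {
        for (int r : rows_target[i]) lin[r] += prop - rr[i];
        rr[i] = prop;
      }
    }
    if (adapting) adapt(sc_r, acc_r / n, it);

    // --- sender/receiver covariance ---
    for (int which = 0; which < 3; ++which) {
      double cur = which == 0 ? std::log(sig_s)
                 : which == 1 ? std::log(sig_r) : std::atanh(rho_sr);
      double prop = cur + norm_rand() * sc_var;
      double ns = which == 0 ? std::exp(prop) : sig_s;
      double nr = which == 1 ? std::exp(prop) : sig_r;
      double nrho = which == 2 ? std::tanh(prop) : rho_sr;
      double dll = 0.0;
      for (int i = 0; i < n; ++i)
        dll += bvn_lpdf(s[i], rr[i], ns, nr, nrho) -
               bvn_lpdf(s[i], rr[i], sig_s, sig_r, rho_sr);
      if (which < 2) {
        double so = which == 0 ? sig_s : sig_r, sn = std::exp(prop);
        // half-Normal(sd_prior_scale) prior on the SD + log Jacobian
        dll += (-sn * sn + so * so) / (2.0 * sd_prior_scale * sd_prior_scale)
               + (prop - cur);
      } else {
        // uniform prior on rho, Jacobian of atanh transform
        dll += std::log(1.0 - nrho * nrho) - std::log(1.0 - rho_sr * rho_sr);
      }
      if (std::log(unif_rand()) < dll) {
        sig_s = ns; sig_r = nr; rho_sr = nrho;
      }
    }

    // --- dyad effects (pairwise) ---
    if (dyad_effects) {
      double acc_d = 0.0;
      for (int d = 0; d < D; ++d) {
        int rA = 2 * d, rB = 2 * d + 1;
        double pA = dy[rA] + norm_rand() * sc_d;
        double pB = dy[rB] + norm_rand() * sc_d;
        double dll = ll_row(rA, lin[rA] + pA - dy[rA]) - ll_row(rA, lin[rA]) +
                     ll_row(rB, lin[rB] + pB - dy[rB]) - ll_row(rB, lin[rB]);
        dll += bvn_lpdf(pA, pB, sig_d, sig_d, rho_d) -
               bvn_lpdf(dy[rA], dy[rB], sig_d, sig_d, rho_d);
        double apr = std::min(1.0, std::exp(dll));
        acc_d += apr;
        if (unif_rand() < apr) {
          lin[rA] += pA - dy[rA]; lin[rB] += pB - dy[rB];
          dy[rA] = pA; dy[rB] = pB;
        }
      }
      if (adapting) adapt(sc_d, acc_d / D, it);

      // --- dyad covariance ---
      for (int which = 0; which < 2; ++which) {
        double cur = which == 0 ? std::log(sig_d) : std::atanh(rho_d);
        double prop = cur + norm_rand() * sc_var;
        double nd = which == 0 ? std::exp(prop) : sig_d;
        double nrho = which == 1 ? std::tanh(prop) : rho_d;
        double dll = 0.0;
        for (int d = 0; d < D; ++d)
          dll += bvn_lpdf(dy[2 * d], dy[2 * d + 1], nd, nd, nrho) -
                 bvn_lpdf(dy[2 * d], dy[2 * d + 1], sig_d, sig_d, rho_d);
        if (which == 0) {
          dll += (-nd * nd + sig_d * sig_d) /
                   (2.0 * sd_prior_scale * sd_prior_scale) + (prop - cur);
        } else {
          dll += std::log(1.0 - nrho * nrho) - std::log(1.0 - rho_d * rho_d);
        }
        if (std::log(unif_rand()) < dll) { sig_d = nd; rho_d = nrho; }
      }
    }

    // --- latent ties and reporting rates (reports mode) ---
    if (reports_mode) {
      long pos1 = 0, tot1 = 0, pos0 = 0, tot0 = 0;
      for (int r = 0; r < R; ++r) {
        double p1 = 1.0 / (1.0 + std::exp(-lin[r]));
        double lw1 = std::log(p1), lw0 = std::log1p(-p1);
        if (nobs[r] > 0) {
          if (npos[r] > 0) {
            lw1 += npos[r] * std::log(lambda1);
            lw0 += npos[r] * std::log(lambda0);
          }
          if (nobs[r] - npos[r] > 0) {
            lw1 += (nobs[r] - npos[r]) * std::log1p(-lambda1);
            lw0 += (nobs[r] - npos[r]) * std::log1p(-lambda0);
          }
        }
        double pr1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
        y[r] = unif_rand() < pr1 ? 1 : 0;
        if (y[r]) { pos1 += npos[r]; tot1 += nobs[r]; }
        else      { pos0 += npos[r]; tot0 += nobs[r]; }
      }
      lambda1 = R::rbeta(l1_a + pos1, l1_b + (tot1 - pos1));
      lambda0 = R::rbeta(l0_a + pos0, l0_b + (tot0 - pos0));
    }

    if (it >= burn && (it - burn) % thin == 0 && k < keep) {
      for (int kk = 0; kk < p; ++kk) draws(k, kk) = beta[kk];
      draws(k, p + 0) = sig_s; draws(k, p + 1) = sig_r;
      draws(k, p + 2) = rho_sr; draws(k, p + 3) = sig_d;
      draws(k, p + 4) = rho_d; draws(k, p + 5) = lambda1;
      draws(k, p + 6) = lambda0;
      for (int i = 0; i < n; ++i) {
        re_mean(i, 0) += s[i] / keep; re_mean(i, 1) += rr[i] / keep;
      }
      ++k;
    }
  }
  return List::create(_["draws"] = draws, _["random_effects"] = re_mean);
}
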