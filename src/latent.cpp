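#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the latent directed network behind double-sampled
// name-generator reports.
//
// Model: each unordered dyad {i,j} has latent (Y_ij, Y_ji) with prior
//   P(y_ij, y_ji) proportional to exp(a (y_ij + y_ji) + m y_ij y_ji),
// where a is the network density log-odds (Gaussian prior centred on the
// logit of the configured prior tie probability) and m the mutuality
// log-odds (Gaussian prior centred at zero).  Each eligible reporter's
// statement about an ordered pair is Bernoulli(lambda1) if the latent tie
// exists and Bernoulli(lambda0) otherwise; lambda1, lambda0 carry Beta
// priors and are conjugately updated.  Only dyads with at least one
// eligible reporter are sampled; dyads with none contribute nothing to the
// likelihood and their posterior equals the prior (handled analytically on
// the R side, using the retained draws of a and m).
//
// Per active dyad d (i < j): nobs_ij / npos_ij are the number of eligible
// statements and positive statements about the ordered pair (i, j), and
// likewise for (j, i).
// [[Rcpp::export]]
List latent_gibbs_cpp(IntegerVector nobs_ij, IntegerVector npos_ij,
                      IntegerVector nobs_ji, IntegerVector npos_ji,
                      double a_init, double a_prior_mean, double a_prior_sd,
                      double m_init, double m_sd,
                      double l1_a, double l1_b, double l0_a, double l0_b,
                      double lambda1_init, double lambda0_init,
                      bool fix_lambda, bool fix_m, bool fix_a,
                      int iter, int burn, double prop_sd) {
  const int D = nobs_ij.size();
  double lambda1 = lambda1_init, lambda0 = lambda0_init;
  double m = m_init, a = a_init;
  std::vector<int> yij(D, 0), yji(D, 0);
  std::vector<double> rho_ij(D, 0.0), rho_ji(D, 0.0);
  NumericMatrix draws(iter, 4);
  int mh_acc = 0;

  // Degenerate fixed-rate limits: a positive report with lambda0 = 0 makes
  // the no-tie state impossible (guard -1e100); a missed report with
  // lambda1 = 1 makes the tie state impossible too, but with a weaker guard
  // (-1e50), so that in the joint noiseless limit positive evidence wins and
  // the estimate converges to the union of reports.
  auto loglik_side = [&](int y, int nobs, int npos) {
    if (nobs == 0) return 0.0;
    double p = y ? lambda1 : lambda0;
    double lp = 0.0;
    if (npos > 0) lp += (p <= 0.0) ? -1e100 : npos * std::log(p);
    if (nobs - npos > 0)
      lp += (p >= 1.0) ? -1e50 : (nobs - npos) * std::log(1.0 - p);
    return lp;
  };

  auto log_z = [](double aa, double mm) {
    return std::log(1.0 + 2.0 * std::exp(aa) + std::exp(2.0 * aa + mm));
  };

  for (int it = 0; it < burn + iter; ++it) {
    long n11 = 0, n_tie = 0;
    long pos1 = 0, tot1 = 0, pos0 = 0, tot0 = 0;
    for (int d = 0; d < D; ++d) {
      double w[4];
      int s1[4] = {0, 1, 0, 1};  // y_ij per state
      int s2[4] = {0, 0, 1, 1};  // y_ji per state
      double wmax = -1e300;
      for (int s = 0; s < 4; ++s) {
        w[s] = a * (s1[s] + s2[s]) + m * (s1[s] * s2[s]) +
               loglik_side(s1[s], nobs_ij[d], npos_ij[d]) +
               loglik_side(s2[s], nobs_ji[d], npos_ji[d]);
        if (w[s] > wmax) wmax = w[s];
      }
      double tot = 0.0;
      for (int s = 0; s < 4; ++s) { w[s] = std::exp(w[s] - wmax); tot += w[s]; }
      double u = unif_rand() * tot, c = 0.0;
      int pick = 3;
      for (int s = 0; s < 4; ++s) { c += w[s]; if (u <= c) { pick = s; break; } }
      yij[d] = s1[pick]; yji[d] = s2[pick];
      n11 += yij[d] * yji[d];
      n_tie += yij[d] + yji[d];
      if (yij[d]) { pos1 += npos_ij[d]; tot1 += nobs_ij[d]; }
      else        { pos0 += npos_ij[d]; tot0 += nobs_ij[d]; }
      if (yji[d]) { pos1 += npos_ji[d]; tot1 += nobs_ji[d]; }
      else        { pos0 += npos_ji[d]; tot0 += nobs_ji[d]; }
    }
    if (!fix_lambda) {
      lambda1 = R::rbeta(l1_a + pos1, l1_b + (tot1 - pos1));
      lambda0 = R::rbeta(l0_a + pos0, l0_b + (tot0 - pos0));
    }
    // joint dyad-prior log-posterior in (a, m) given the latent ties
    auto logpost = [&](double aa, double mm) {
      return R::dnorm(aa, a_prior_mean, a_prior_sd, 1) +
             R::dnorm(mm, 0.0, m_sd, 1) +
             aa * n_tie + mm * n11 - D * log_z(aa, mm);
    };
    if (!fix_m || !fix_a) {
      double ap = fix_a ? a : a + norm_rand() * prop_sd;
      double mp = fix_m ? m : m + norm_rand() * prop_sd;
      if (std::log(unif_rand()) < logpost(ap, mp) - logpost(a, m)) {
        a = ap; m = mp; ++mh_acc;
      }
    }
    if (it >= burn) {
      for (int d = 0; d < D; ++d) { rho_ij[d] += yij[d]; rho_ji[d] += yji[d]; }
      draws(it - burn, 0) = lambda1;
      draws(it - burn, 1) = lambda0;
      draws(it - burn, 2) = m;
      draws(it - burn, 3) = a;
    }
  }
  for (int d = 0; d < D; ++d) { rho_ij[d] /= iter; rho_ji[d] /= iter; }
  return List::create(_["rho_ij"] = NumericVector(rho_ij.begin(), rho_ij.end()),
                      _["rho_ji"] = NumericVector(rho_ji.begin(), rho_ji.end()),
                      _["draws"] = draws,
                      _["mh_acceptance"] = (fix_m && fix_a) ? NA_REAL
                                                : (double)mh_acc / (burn + iter));
}
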