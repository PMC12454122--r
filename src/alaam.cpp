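#include <Rcpp.h>
using namespace Rcpp;

// Systematic-scan Gibbs sampler for the autologistic actor-attribute model.
//
// The full conditional for node i is
//   logit P(y_i = 1 | y_-i) = eta_i + sum_s theta_s * sum_{j in N_s(i)} y_j
//                                   + theta_tri * #{(j,k) in Tri(i): y_j y_k = 1}
// where eta_i collects all node-constant change statistics (intercept,
// activity, popularity, covariates), N_s(i) is the neighbour set of node i
// under contagion statistic s (direct / reciprocal / indirect / closed
// indirect, all precomputed on the fixed network), and Tri(i) lists the
// symmetrized triangles at i for the transitive statistic.
//
// nbr: list of CSR structures, one per pairwise contagion statistic, each a
//      list(ptr = int[n+1], idx = int[m]) with 0-based indices.
// tri: list(ptr = int[n+1], j = int[m], k = int[m]) or empty list.
//
// Runs burn_sweeps full sweeps, then records n_draws states thin sweeps
// apart (thin = 0 records the state reached after burn-in, then after every
// subsequent call of 1 sweep -- used for a single terminal draw).
// [[Rcpp::export]]
IntegerMatrix alaam_gibbs_cpp(NumericVector eta, List nbr,
                              NumericVector theta_cont, List tri,
                              double theta_tri, IntegerVector y0,
                              int burn_sweeps, int n_draws, int thin) {
  const int n = eta.size();
  const int n_stat = theta_cont.size();
  std::vector<int> y(y0.begin(), y0.end());

  std::vector<const int*> ptrs(n_stat), idxs(n_stat);
  std::vector<IntegerVector> keep_alive;
  for (int s = 0; s < n_stat; ++s) {
    List st = nbr[s];
    IntegerVector p = st["ptr"], ix = st["idx"];
    keep_alive.push_back(p); keep_alive.push_back(ix);
    ptrs[s] = INTEGER(p); idxs[s] = INTEGER(ix);
  }
  bool has_tri = tri.size() > 0;
  const int *tptr = nullptr, *tj = nullptr, *tk = nullptr;
  IntegerVector tp, tjv, tkv;
  if (has_tri) {
    tp = tri["ptr"]; tjv = tri["j"]; tkv = tri["k"];
    tptr = INTEGER(tp); tj = INTEGER(tjv); tk = INTEGER(tkv);
  }

  IntegerMatrix draws(n_draws, n);
  auto sweep = [&]() {
    for (int i = 0; i < n; ++i) {
      double lg = eta[i];
      for (int s = 0; s < n_stat; ++s) {
        if (theta_cont[s] == 0.0) continue;
        int acc = 0;
        for (int e = ptrs[s][i]; e < ptrs[s][i + 1]; ++e) acc += y[idxs[s][e]];
        lg += theta_cont[s] * acc;
      }
      if (has_tri && theta_tri != 0.0) {
        int acc = 0;
        for (int e = tptr[i]; e < tptr[i + 1]; ++e) acc += y[tj[e]] * y[tk[e]];
        lg += theta_tri * acc;
      }
      double p1 = 1.0 / (1.0 + std::exp(-lg));
      y[i] = (unif_rand() < p1) ? 1 : 0;
    }
  };

  for (int b = 0; b < burn_sweeps; ++b) sweep();
  for (int d = 0; d < n_draws; ++d) {
    if (d > 0 || thin > 0) {
      int reps = (d == 0) ? thin : std::max(thin, 1);
      for (int t = 0; t < reps; ++t) sweep();
    }
    for (int i = 0; i < n; ++i) draws(d, i) = y[i];
  }
  return draws;
}
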