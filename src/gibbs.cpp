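#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for Bayesian microbial source tracking of a single
// sink community. Known sources k have fixed taxon count profiles m[,k],
// smoothed by a per-taxon pseudocount alpha1; the unknown source accumulates
// its taxon counts from the current latent assignments, smoothed by alpha2.
// A sequence token i with taxon x_i is reassigned with probability
//   P(z_i = k) ∝ phi_k(x_i) * (n_k + beta)
// where phi is the (smoothed) taxon distribution of source k and n_k the
// sink's current assignment totals excluding token i. Uses R's RNG, so
// set.seed() in R makes the sampler deterministic.
//
// tokens: 0-based taxon index per sequence; source_counts: taxa x K.
// Returns a matrix with one row per retained draw (restarts * n_draws) and
// K + 1 columns of assignment proportions (known sources then unknown).
// [[Rcpp::export]]
NumericMatrix st_gibbs_sink(IntegerVector tokens, IntegerMatrix source_counts,
                            double alpha1, double alpha2, double beta,
                            int burnin, int n_draws, int spacing,
                            int restarts) {
  const int N = tokens.size();
  const int T = source_counts.nrow();
  const int K = source_counts.ncol();
  const int S = K + 1;  // last index = unknown

  // fixed smoothed profiles of the known sources
  std::vector<double> phi(static_cast<size_t>(K) * T);
  for (int k = 0; k < K; ++k) {
    double total = 0.0;
    for (int t = 0; t < T; ++t) total += source_counts(t, k);
    const double denom = total + alpha1 * T;
    for (int t = 0; t < T; ++t)
      phi[static_cast<size_t>(k) * T + t] =
          (source_counts(t, k) + alpha1) / denom;
  }

  NumericMatrix draws(restarts * n_draws, S);
  std::vector<int> z(N), n(S), u(T);
  std::vector<double> w(S);
  int row = 0;

  for (int r = 0; r < restarts; ++r) {
    std::fill(n.begin(), n.end(), 0);
    std::fill(u.begin(), u.end(), 0);
    int U = 0;
    for (int i = 0; i < N; ++i) {
      int s = static_cast<int>(unif_rand() * S);
      if (s == S) s = S - 1;
      z[i] = s;
      n[s]++;
      if (s == K) { u[tokens[i]]++; U++; }
    }
    const int sweeps = burnin + n_draws * spacing;
    for (int it = 0; it < sweeps; ++it) {
      for (int i = 0; i < N; ++i) {
        const int t = tokens[i];
        const int old = z[i];
        n[old]--;
        if (old == K) { u[t]--; U--; }
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          w[k] = phi[static_cast<size_t>(k) * T + t] * (n[k] + beta);
          tot += w[k];
        }
        w[K] = (u[t] + alpha2) / (U + alpha2 * T) * (n[K] + beta);
        tot += w[K];
        double pick = unif_rand() * tot;
        int s = 0;
        while (s < K && pick > w[s]) { pick -= w[s]; ++s; }
        z[i] = s;
        n[s]++;
        if (s == K) { u[t]++; U++; }
      }
      const int after = it - burnin + 1;
      if (after > 0 && after % spacing == 0) {
        for (int s = 0; s < S; ++s)
          draws(row, s) = static_cast<double>(n[s]) / N;
        ++row;
      }
    }
  }
  return draws;
}
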