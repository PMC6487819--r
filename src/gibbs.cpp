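#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for mixed-source attribution of one sink.
//
// Each sink read (given as a 0-based taxon index) carries a latent source
// environment among K known sources plus one Unknown environment. Known
// source taxon distributions are informed by the source count table plus
// currently assigned sink reads, smoothed with a Dirichlet(alpha1)
// pseudocount; the Unknown distribution is learned from assignments alone
// with Dirichlet(alpha2); mixing proportions carry a symmetric prior beta.
// Uses R's RNG so set.seed() in R makes runs reproducible.
//
// Returns a (n_draws x K+1) matrix of assignment proportions recorded every
// `thin` sweeps after `burn_in` sweeps.
// [[Rcpp::export]]
NumericMatrix st_gibbs(IntegerVector read_taxa, NumericMatrix source_counts,
                       double alpha1, double alpha2, double beta,
                       int burn_in, int n_draws, int thin) {
  const int n = read_taxa.size();
  const int T = source_counts.nrow();
  const int K = source_counts.ncol();
  const int V = K + 1;  // + Unknown

  NumericVector M(K);
  for (int v = 0; v < K; ++v)
    for (int t = 0; t < T; ++t) M[v] += source_counts(t, v);

  IntegerVector z(n);
  IntegerVector n_env(V);
  IntegerMatrix n_env_taxon(V, T);
  for (int i = 0; i < n; ++i) {
    int v = (int)(unif_rand() * V);
    if (v == V) v = V - 1;
    z[i] = v;
    n_env[v]++;
    n_env_taxon(v, read_taxa[i])++;
  }

  NumericMatrix draws(n_draws, V);
  NumericVector prob(V);
  const int total_sweeps = burn_in + n_draws * thin;
  int rec = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      const int t = read_taxa[i];
      const int v_old = z[i];
      n_env[v_old]--;
      n_env_taxon(v_old, t)--;

      double tot = 0.0;
      for (int v = 0; v < K; ++v) {
        double like = (source_counts(t, v) + n_env_taxon(v, t) + alpha1) /
                      (M[v] + n_env[v] + alpha1 * T);
        prob[v] = like * (n_env[v] + beta);
        tot += prob[v];
      }
      {
        double like = (n_env_taxon(K, t) + alpha2) /
                      (n_env[K] + alpha2 * T);
        prob[K] = like * (n_env[K] + beta);
        tot += prob[K];
      }
      double u = unif_rand() * tot;
      int v_new = 0;
      double acc = prob[0];
      while (u > acc && v_new < V - 1) { ++v_new; acc += prob[v_new]; }
      z[i] = v_new;
      n_env[v_new]++;
      n_env_taxon(v_new, t)++;
    }
    if (sweep >= burn_in && (sweep - burn_in) % thin == thin - 1 && rec < n_draws) {
      for (int v = 0; v < V; ++v) draws(rec, v) = (double)n_env[v] / n;
      ++rec;
    }
  }
  return draws;
}
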