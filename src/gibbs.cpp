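#include <Rcpp.h>
using namespace Rcpp;

// Sequential single-site Gibbs sampler for a binary maximum-entropy model
// with self (h), pairwise (J, dense symmetric) and triplet (K, sparse)
// energies, P(x) ∝ exp(E(x)). One retained sample per full sweep.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".gibbs_sample_cpp")]]
IntegerMatrix gibbs_sample_cpp(NumericVector h, NumericMatrix J,
                               IntegerMatrix trip_idx, NumericVector trip_val,
                               int n_samples, int burn_in,
                               IntegerVector init) {
  const int n = h.size();
  const int m = trip_idx.nrow();
  std::vector<int> x(n);
  for (int i = 0; i < n; ++i) x[i] = init[i] ? 1 : 0;

  // per-site list of triples touching the site, with the two partners
  std::vector< std::vector<int> > site_trip(n);
  for (int t = 0; t < m; ++t) {
    site_trip[trip_idx(t, 0)].push_back(t);
    site_trip[trip_idx(t, 1)].push_back(t);
    site_trip[trip_idx(t, 2)].push_back(t);
  }

  IntegerMatrix out(n_samples, n);
  RNGScope scope;
  const int total = burn_in + n_samples;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double field = h[i];
      for (int j = 0; j < n; ++j) {
        if (x[j]) field += J(i, j);
      }
      const std::vector<int> &tl = site_trip[i];
      for (size_t u = 0; u < tl.size(); ++u) {
        int t = tl[u];
        int a = trip_idx(t, 0), b = trip_idx(t, 1), c = trip_idx(t, 2);
        int p, q;
        if (a == i)      { p = b; q = c; }
        else if (b == i) { p = a; q = c; }
        else             { p = a; q = b; }
        if (x[p] && x[q]) field += trip_val[t];
      }
      double p1 = 1.0 / (1.0 + std::exp(-field));
      x[i] = (unif_rand() < p1) ? 1 : 0;
    }
    if (sweep >= burn_in) {
      int r = sweep - burn_in;
      for (int i = 0; i < n; ++i) out(r, i) = x[i];
    }
  }
  return out;
}
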