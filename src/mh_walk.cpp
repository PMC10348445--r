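#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-Hastings single-flip random walk over binary patterns.
//
// Proposals pick one of the N single-flip neighbours uniformly; a move from
// pattern V_i to V_j is accepted with probability min[1, exp(E(V_i) - E(V_j))].
// Rejected proposals repeat the current pattern. Energies are updated
// incrementally: flipping spin s_k changes the energy by
// 2 s_k (h_k + sum_j J_kj s_j). Uses R's RNG so results are reproducible
// under set.seed().
//
// Returns the full trajectory of pattern codes (length n_steps), with the
// initial pattern at position 1; burn-in removal happens on the R side.
// [[Rcpp::export]]
IntegerVector mh_walk_cpp(NumericVector h, NumericMatrix J, int n_steps,
                          int start_code) {
  const int n = h.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i)
    s[i] = ((start_code >> i) & 1) ? 1 : -1;

  IntegerVector codes(n_steps);
  int code = start_code;
  codes[0] = code;
  for (int t = 1; t < n_steps; ++t) {
    int k = (int)(unif_rand() * n);
    if (k == n) k = n - 1;
    double field = h[k];
    for (int j = 0; j < n; ++j) field += J(k, j) * s[j];
    double dE = 2.0 * s[k] * field; // E(proposed) - E(current)
    if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
      s[k] = -s[k];
      code ^= (1 << k);
    }
    codes[t] = code;
  }
  return codes;
}
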