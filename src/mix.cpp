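#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One swap sweep of the population layer, inspired by Kawasaki dynamics.
//
// Sites are visited in random order. A site that has not yet swapped picks a
// partner uniformly from {itself} + its in-lattice neighbourhood offsets.
// Picking itself marks the site as swapped without movement. If the partner
// has not yet swapped, the two site contents are exchanged and both are
// marked; otherwise nothing happens and the origin stays eligible as a
// later target. `frac` < 1 attempts the sweep on only the first
// ceil(frac * n) sites of the random order (coarse-lattice scaling).
//
// Returns a 1-based permutation p with new_content[site] = old_content[p[site]].
// Site index is (x - 1) * height + y, column-major in x.
// Uses R's RNG so runs are reproducible from set.seed().
// [[Rcpp::export]]
IntegerVector mix_sweep_perm(int width, int height, IntegerMatrix offsets,
                             double frac = 1.0) {
  int n = width * height;
  std::vector<int> cur(n), order(n);
  for (int i = 0; i < n; ++i) { cur[i] = i; order[i] = i; }
  // Fisher-Yates with R's RNG
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int attempts = (frac >= 1.0) ? n : (int)std::ceil(frac * n);
  if (attempts > n) attempts = n;
  std::vector<bool> swapped(n, false);
  int no = offsets.nrow();
  std::vector<int> cand;
  cand.reserve(no + 1);
  for (int t = 0; t < attempts; ++t) {
    int s = order[t];
    if (swapped[s]) continue;
    int x = s / height, y = s % height;
    cand.clear();
    cand.push_back(s);
    for (int k = 0; k < no; ++k) {
      int nx = x + offsets(k, 0), ny = y + offsets(k, 1);
      if (nx >= 0 && nx < width && ny >= 0 && ny < height)
        cand.push_back(nx * height + ny);
    }
    int pick = (int)(unif_rand() * cand.size());
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    int d = cand[pick];
    if (d == s) { swapped[s] = true; continue; }
    if (!swapped[d]) {
      std::swap(cur[s], cur[d]);
      swapped[s] = true;
      swapped[d] = true;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cur[i] + 1;
  return out;
}
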