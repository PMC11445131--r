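// Bootstrap null for largest-connected-component size: repeatedly draw a
// fixed-size edge subset from a parent network and record the LCC gene
// count, using a stamped union-find so per-replicate cost is O(subset).
#include <Rcpp.h>
#include <vector>
#include <numeric>
using namespace Rcpp;

static inline int findRoot(std::vector<int> &parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

// edgeA/edgeB: 0-based vertex indices of the parent's edges.
// Draws use R's RNG (set.seed() upstream controls reproducibility).
// [[Rcpp::export(name = ".lccNullSizes")]]
IntegerVector lccNullSizes(IntegerVector edgeA, IntegerVector edgeB,
                           int nVertices, int subsetSize, int nSims,
                           bool replace) {
  const int m = edgeA.size();
  std::vector<int> idx(m);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<int> parent(nVertices), sz(nVertices), stamp(nVertices, -1);
  std::vector<int> chosen(subsetSize), jswap(subsetSize), touched;
  touched.reserve(2 * subsetSize);
  IntegerVector out(nSims);

  for (int s = 0; s < nSims; ++s) {
    if (replace) {
      for (int t = 0; t < subsetSize; ++t) {
        int j = (int)(unif_rand() * m);
        chosen[t] = j >= m ? m - 1 : j;
      }
    } else {
      for (int t = 0; t < subsetSize; ++t) {
        int j = t + (int)(unif_rand() * (m - t));
        if (j >= m) j = m - 1;
        std::swap(idx[t], idx[j]);
        jswap[t] = j;
        chosen[t] = idx[t];
      }
      for (int t = subsetSize - 1; t >= 0; --t)  // restore idx
        std::swap(idx[t], idx[jswap[t]]);
    }
    touched.clear();
    for (int t = 0; t < subsetSize; ++t) {
      int a = edgeA[chosen[t]], b = edgeB[chosen[t]];
      for (int v : {a, b}) {
        if (stamp[v] != s) {
          stamp[v] = s;
          parent[v] = v;
          sz[v] = 1;
          touched.push_back(v);
        }
      }
      int ra = findRoot(parent, a), rb = findRoot(parent, b);
      if (ra != rb) {
        if (sz[ra] < sz[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        sz[ra] += sz[rb];
      }
    }
    int best = 0;
    for (int v : touched)
      if (parent[v] == v && sz[v] > best) best = sz[v];
    out[s] = best;
  }
  return out;
}
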