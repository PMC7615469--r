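#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of a directed binary graph by edge
// swapping: pick edges (a->b), (c->d) and rewire to (a->d), (c->b).
// Proposals creating a self-loop or duplicating an existing edge are
// rejected and count toward the attempt budget (swapsPerEdge * m
// attempts in total). In- and out-degree sequences are invariant.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".edgeSwapNull")]]
List edgeSwapNull(LogicalMatrix adj, int swapsPerEdge) {
  int n = adj.nrow();
  std::vector<int> from, to;
  from.reserve(1024); to.reserve(1024);
  LogicalMatrix A(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && adj(i, j)) {
        from.push_back(i);
        to.push_back(j);
        A(i, j) = true;
      }
  int m = (int)from.size();
  long attempts = (long)swapsPerEdge * m;
  long realized = 0;
  if (m >= 2) {
    for (long t = 0; t < attempts; ++t) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
      if (a == d || c == b) continue;       // self-loop
      if (A(a, d) || A(c, b)) continue;     // duplicate edge
      A(a, b) = false; A(c, d) = false;
      A(a, d) = true;  A(c, b) = true;
      to[e1] = d; to[e2] = b;
      ++realized;
    }
  }
  return List::create(_["adj"] = A, _["realized"] = realized,
                      _["attempts"] = attempts);
}
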