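#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive template-match counts for Sample Entropy.
//
// Templates u_i = (x_i, ..., x_{i+m-1}), i = 1..N-m.  B counts ordered pairs
// (i, j), i != j, with Chebyshev distance <= r at length m; A counts the same
// pairs at length m+1.  Both counts run over the shared range i, j <= N - m
// (Richman-Moorman convention), so every (m+1)-match is also an m-match and
// A <= B holds by construction.  Matching is inclusive (<= r).
//
// The double loop enumerates unordered pairs and adds 2 per match, which is
// exactly the ordered-pair count; no approximate neighbour search is used.
// [[Rcpp::export(name = ".sampenCounts")]]
List sampenCounts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 2.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 2.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["nTemplates"] = nt);
}
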