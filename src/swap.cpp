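#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap randomization of a binary occupancy matrix: repeatedly
// draw a random 2x2 submatrix and, when it is a checkerboard
// ([[1,0],[0,1]] or [[0,1],[1,0]]), exchange its diagonals.  Row sums
// (plot richness) and column sums (species occupancy) are invariant.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix swap_engine(IntegerMatrix m, int attempts) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  int swaps = 0;
  if (nr < 2 || nc < 2) {
    x.attr("swaps") = swaps;
    return x;
  }
  for (int it = 0; it < attempts; ++it) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;               // distinct rows
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;               // distinct columns
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      x(r1, c1) = 0; x(r2, c2) = 0; x(r1, c2) = 1; x(r2, c1) = 1; ++swaps;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      x(r1, c1) = 1; x(r2, c2) = 1; x(r1, c2) = 0; x(r2, c1) = 0; ++swaps;
    }
  }
  x.attr("swaps") = swaps;
  return x;
}
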