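#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Column-monotone minimum-weight path through a B-scan graph.
//
// Nodes are (row, column) pixels; a path visits exactly one node per column
// with |row(x+1) - row(x)| <= max_step, restricted per column to
// [min_row[x], max_row[x]).  Edge weight between laterally adjacent nodes:
//   w = 2 - (g_a + g_b) + w_min,
// where g is the normalized rectified gradient.  Endpoints are free
// (virtual zero-weight start/end nodes attached to every allowed row of the
// first/last column).
//
// Tie-breaking, fully deterministic: among equal-cost paths prefer the
// smallest total row sum, then the topmost row at the first differing
// column (i.e. the lexicographically smallest row sequence).  Implemented
// as a backward pass over lexicographic (cost, rowsum) values followed by a
// greedy forward reconstruction that prefers the smallest row.
//
// min_row / max_row are 0-based half-open; the returned path is 0-based.

// [[Rcpp::export(name = ".dp_path")]]
List dp_path(NumericMatrix g, IntegerVector min_row, IntegerVector max_row,
             int max_step, double w_min) {
  const int nrow = g.nrow();
  const int ncol = g.ncol();
  const double inf = std::numeric_limits<double>::infinity();

  if ((int)min_row.size() != ncol || (int)max_row.size() != ncol)
    stop("region vectors must have one entry per column");
  for (int x = 0; x < ncol; ++x) {
    if (min_row[x] < 0 || max_row[x] > nrow || min_row[x] >= max_row[x])
      stop("infeasible search region in column %d", x + 1);
  }
  if (max_step < 1) stop("max_step must be >= 1");

  // cost-to-go and rowsum-to-go (both include the node's own column edge /
  // row respectively)
  std::vector<double> V((size_t)nrow * ncol, inf);
  std::vector<double> S((size_t)nrow * ncol, inf);

  for (int r = min_row[ncol - 1]; r < max_row[ncol - 1]; ++r) {
    V[(size_t)(ncol - 1) * nrow + r] = 0.0;
    S[(size_t)(ncol - 1) * nrow + r] = r;
  }

  for (int x = ncol - 2; x >= 0; --x) {
    const double *Vn = &V[(size_t)(x + 1) * nrow];
    const double *Sn = &S[(size_t)(x + 1) * nrow];
    double *Vc = &V[(size_t)x * nrow];
    double *Sc = &S[(size_t)x * nrow];
    for (int r = min_row[x]; r < max_row[x]; ++r) {
      const double base = 2.0 - g(r, x) + w_min;
      int lo = std::max(r - max_step, (int)min_row[x + 1]);
      int hi = std::min(r + max_step, (int)max_row[x + 1] - 1);
      double bestV = inf, bestS = inf;
      for (int r2 = lo; r2 <= hi; ++r2) {
        if (Vn[r2] == inf) continue;
        double v = base - g(r2, x + 1) + Vn[r2];
        double s = r + Sn[r2];
        if (v < bestV || (v == bestV && s < bestS)) {
          bestV = v;
          bestS = s;
        }
      }
      Vc[r] = bestV;
      Sc[r] = bestS;
    }
  }

  // start column: smallest (cost, rowsum, row)
  int r0 = -1;
  double bestV = inf, bestS = inf;
  for (int r = min_row[0]; r < max_row[0]; ++r) {
    double v = V[r], s = S[r];
    if (v < bestV || (v == bestV && s < bestS)) {
      bestV = v;
      bestS = s;
      r0 = r;
    }
  }
  if (r0 < 0 || bestV == inf)
    stop("no feasible path: search regions are disconnected under max_step");

  IntegerVector path(ncol);
  path[0] = r0;
  for (int x = 0; x < ncol - 1; ++x) {
    const double *Vn = &V[(size_t)(x + 1) * nrow];
    const double *Sn = &S[(size_t)(x + 1) * nrow];
    const int r = path[x];
    const double base = 2.0 - g(r, x) + w_min;
    int lo = std::max(r - max_step, (int)min_row[x + 1]);
    int hi = std::min(r + max_step, (int)max_row[x + 1] - 1);
    int pick = -1;
    double pickV = inf, pickS = inf;
    for (int r2 = lo; r2 <= hi; ++r2) {
      if (Vn[r2] == inf) continue;
      double v = base - g(r2, x + 1) + Vn[r2];
      double s = r2 + Sn[r2];
      if (v < pickV || (v == pickV && s < pickS)) {
        pickV = v;
        pickS = s;
        pick = r2;
      }
    }
    path[x + 1] = pick;
  }

  return List::create(_["path"] = path, _["cost"] = bestV);
}
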