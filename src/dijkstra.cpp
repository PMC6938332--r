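#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over an 8-neighbour raster lattice.
// Move cost between adjacent cells = mean of the two cell resistances times
// the centre-to-centre distance (cell_km, times sqrt(2) on diagonals).
// Cells with NA resistance are impassable; source cells start at cost 0.
// Returns accumulated cost and a predecessor grid (1-based linear index in
// column-major order; 0 for sources and unreachable cells).
// [[Rcpp::export]]
List grid_dijkstra(NumericMatrix resistance, LogicalMatrix source) {
  int nr = resistance.nrow(), nc = resistance.ncol();
  double cell_km = 1.0; // caller scales resistance or distances as needed
  NumericMatrix cwd(nr, nc);
  IntegerMatrix pred(nr, nc);
  std::fill(cwd.begin(), cwd.end(), R_PosInf);
  std::fill(pred.begin(), pred.end(), 0);

  typedef std::pair<double, int> QE; // (cost, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (source(i, j)) {
        if (NumericMatrix::is_na(resistance(i, j))) continue;
        cwd(i, j) = 0.0;
        pq.push(QE(0.0, j * nr + i));
      }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sq2 = std::sqrt(2.0);

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first;
    int idx = top.second;
    int i = idx % nr, j = idx / nr;
    if (d > cwd(i, j)) continue; // stale entry
    double ri = resistance(i, j);
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      double rn = resistance(ni, nj);
      if (NumericMatrix::is_na(rn)) continue;
      double dist = (dr[k] != 0 && dc[k] != 0) ? sq2 * cell_km : cell_km;
      double nd = d + 0.5 * (ri + rn) * dist;
      if (nd < cwd(ni, nj)) {
        cwd(ni, nj) = nd;
        pred(ni, nj) = idx + 1;
        pq.push(QE(nd, nj * nr + ni));
      }
    }
  }
  return List::create(_["cwd"] = cwd, _["pred"] = pred);
}
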