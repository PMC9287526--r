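#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point-occlusion kernel.  For each atom i, counts how
// many of the precomputed unit-sphere test points, scaled to the
// augmented radius aug[i] and centred on atom i, lie outside every
// neighbouring atom's augmented sphere.  Neighbour candidate lists
// (1-based, from the R-side spatial grid) are pruned here by the
// exact augmented-sphere overlap test.
// [[Rcpp::export]]
IntegerVector sasa_exposed_counts(NumericMatrix coords, NumericVector aug,
                                  NumericMatrix pts, List neighbors) {
  const int n_atoms = coords.nrow();
  const int n_pts = pts.nrow();
  IntegerVector counts(n_atoms);
  std::vector<char> exposed(n_pts);
  std::vector<double> px(n_pts), py(n_pts), pz(n_pts);

  for (int i = 0; i < n_atoms; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = aug[i];
    IntegerVector cand = neighbors[i];

    // exact overlap pruning
    std::vector<int> close;
    close.reserve(cand.size());
    for (int c = 0; c < cand.size(); ++c) {
      const int j = cand[c] - 1;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double lim = ri + aug[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) close.push_back(j);
    }
    if (close.empty()) {
      counts[i] = n_pts;
      continue;
    }
    for (int p = 0; p < n_pts; ++p) {
      px[p] = xi + ri * pts(p, 0);
      py[p] = yi + ri * pts(p, 1);
      pz[p] = zi + ri * pts(p, 2);
      exposed[p] = 1;
    }
    int alive = n_pts;
    for (size_t c = 0; c < close.size() && alive > 0; ++c) {
      const int j = close[c];
      const double xj = coords(j, 0), yj = coords(j, 1), zj = coords(j, 2);
      const double r2 = aug[j] * aug[j];
      for (int p = 0; p < n_pts; ++p) {
        if (!exposed[p]) continue;
        const double dx = px[p] - xj;
        const double dy = py[p] - yj;
        const double dz = pz[p] - zj;
        if (dx * dx + dy * dy + dz * dz < r2) {
          exposed[p] = 0;
          --alive;
        }
      }
    }
    counts[i] = alive;
  }
  return counts;
}
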