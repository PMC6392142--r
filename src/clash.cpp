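#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Steric clash test: true iff any non-exempt atom pair is closer than
// clash_factor * (r_i + r_j). Exempt pairs: same rigid body (group > 0),
// same residue, or sequence-adjacent residues of the same chain (bonded
// backbone neighbours). Uses a uniform cell list keyed on the maximum
// contact distance, so the cost is near-linear in atom count.

// [[Rcpp::export(name = ".clash_check")]]
bool clash_check(NumericMatrix coords, NumericVector radii,
                 IntegerVector group, IntegerVector chain, IntegerVector resid,
                 double clash_factor) {
  const int n = coords.nrow();
  if (n < 2) return false;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (radii[i] > rmax) rmax = radii[i];
  const double cell = std::max(1e-6, clash_factor * 2.0 * rmax);

  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve(n * 2);
  auto key = [cell](double x, double y, double z) -> long long {
    long long ix = static_cast<long long>(std::floor(x / cell));
    long long iy = static_cast<long long>(std::floor(y / cell));
    long long iz = static_cast<long long>(std::floor(z / cell));
    return ((ix & 0x1FFFFFLL) << 42) | ((iy & 0x1FFFFFLL) << 21) |
           (iz & 0x1FFFFFLL);
  };
  for (int i = 0; i < n; ++i)
    cells[key(coords(i, 0), coords(i, 1), coords(i, 2))].push_back(i);

  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    long long ix = static_cast<long long>(std::floor(xi / cell));
    long long iy = static_cast<long long>(std::floor(yi / cell));
    long long iz = static_cast<long long>(std::floor(zi / cell));
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long k = (((ix + dx) & 0x1FFFFFLL) << 42) |
                        (((iy + dy) & 0x1FFFFFLL) << 21) |
                        ((iz + dz) & 0x1FFFFFLL);
          auto it = cells.find(k);
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            if (group[i] > 0 && group[i] == group[j]) continue;
            if (chain[i] == chain[j] && std::abs(resid[i] - resid[j]) <= 1)
              continue;
            double ddx = xi - coords(j, 0);
            double ddy = yi - coords(j, 1);
            double ddz = zi - coords(j, 2);
            double lim = clash_factor * (radii[i] + radii[j]);
            if (ddx * ddx + ddy * ddy + ddz * ddz < lim * lim) return true;
          }
        }
  }
  return false;
}
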