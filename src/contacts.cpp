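#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Heavy-atom contact count between two selections: number of pairs with
// d(a, b) < cutoff (strictly). Cell-list accelerated: B atoms are binned
// into a grid of cell size = cutoff, each A atom scans its 27 neighbor
// cells. Exactly equivalent to the all-pairs definition.
// [[Rcpp::export(name = ".contact_count_cpp")]]
int contact_count_cpp(NumericMatrix a, NumericMatrix b, double cutoff) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) return 0;
  const double c2 = cutoff * cutoff;

  double lo[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = b(0, d);
    for (int i = 1; i < nb; ++i) if (b(i, d) < lo[d]) lo[d] = b(i, d);
  }
  auto cell_of = [&](double x, double y, double z, int64_t &cx, int64_t &cy,
                     int64_t &cz) {
    cx = (int64_t)std::floor((x - lo[0]) / cutoff);
    cy = (int64_t)std::floor((y - lo[1]) / cutoff);
    cz = (int64_t)std::floor((z - lo[2]) / cutoff);
  };
  auto key_of = [](int64_t cx, int64_t cy, int64_t cz) {
    return (cx & 0x1FFFFF) | ((cy & 0x1FFFFF) << 21) |
           ((cz & 0x1FFFFF) << 42);
  };
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(nb);
  for (int i = 0; i < nb; ++i) {
    int64_t cx, cy, cz;
    cell_of(b(i, 0), b(i, 1), b(i, 2), cx, cy, cz);
    grid[key_of(cx, cy, cz)].push_back(i);
  }
  long count = 0;
  for (int i = 0; i < na; ++i) {
    int64_t cx, cy, cz;
    cell_of(a(i, 0), a(i, 1), a(i, 2), cx, cy, cz);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key_of(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = a(i, 0) - b(j, 0);
            const double ddy = a(i, 1) - b(j, 1);
            const double ddz = a(i, 2) - b(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) ++count;
          }
        }
  }
  return (int)count;
}

// Minimum pairwise distance between two selections (brute force).
// [[Rcpp::export(name = ".min_pair_distance_cpp")]]
double min_pair_distance_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
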