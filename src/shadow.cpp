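// Shadow-map native contacts: atom pairs within a cutoff whose line of sight
// is not occluded by any intervening atom sphere, with sequence-separation,
// bonded-exclusion and trans-domain filters applied.
#include <Rcpp.h>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

static double point_segment_dist(double px, double py, double pz, double ax,
                                 double ay, double az, double bx, double by,
                                 double bz) {
  double abx = bx - ax, aby = by - ay, abz = bz - az;
  double apx = px - ax, apy = py - ay, apz = pz - az;
  double ab2 = abx * abx + aby * aby + abz * abz;
  double t = ab2 > 0 ? (apx * abx + apy * aby + apz * abz) / ab2 : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  double cx = ax + t * abx - px, cy = ay + t * aby - py, cz = az + t * abz - pz;
  return std::sqrt(cx * cx + cy * cy + cz * cz);
}

// domain: 0 means unassigned (linker; treated as compatible with anything).
// excluded: bonded/1-3/1-4 pairs (1-based).
// [[Rcpp::export]]
List cpp_shadow_contacts(NumericMatrix xyz, IntegerVector resid,
                         IntegerVector domain, IntegerMatrix excluded,
                         double cutoff, double shadow_radius,
                         int min_res_sep) {
  int n = xyz.nrow();
  std::unordered_set<long> excl;
  for (int k = 0; k < excluded.nrow(); ++k) {
    int i = excluded(k, 0) - 1, j = excluded(k, 1) - 1;
    if (i > j) std::swap(i, j);
    excl.insert((long)i * n + j);
  }
  std::vector<int> ci, cj;
  std::vector<double> sg;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(resid[i] - resid[j]) < min_res_sep) continue;
      if (domain[i] != 0 && domain[j] != 0 && domain[i] != domain[j]) continue;
      if (excl.count((long)i * n + j)) continue;
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > cutoff) continue;
      bool occluded = false;
      for (int k = 0; k < n && !occluded; ++k) {
        if (k == i || k == j) continue;
        if (point_segment_dist(xyz(k, 0), xyz(k, 1), xyz(k, 2), xyz(i, 0),
                               xyz(i, 1), xyz(i, 2), xyz(j, 0), xyz(j, 1),
                               xyz(j, 2)) < shadow_radius)
          occluded = true;
      }
      if (occluded) continue;
      ci.push_back(i + 1); cj.push_back(j + 1); sg.push_back(d);
    }
  IntegerMatrix pairs(ci.size(), 2);
  for (size_t k = 0; k < ci.size(); ++k) {
    pairs(k, 0) = ci[k]; pairs(k, 1) = cj[k];
  }
  return List::create(_["pairs"] = pairs, _["sigma"] = wrap(sg));
}
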