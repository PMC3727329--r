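#include <Rcpp.h>
using namespace Rcpp;

// Soft-sphere clash penalty over residue beads.
// Pairs on the same chain only count when |i - j| > s_min (local backbone
// geometry naturally dips below the cutoff); pairs on different chains
// always count. Penalty per pair: (cutoff - d) for d < cutoff, or 1 in
// count mode. The distance test runs first: almost all pairs fail it, so
// the exemption test is only paid for near contacts.

// [[Rcpp::export]]
double clash_energy_cpp(NumericMatrix xyz, IntegerVector chain,
                        IntegerVector idx, double cutoff, int s_min,
                        bool count_mode) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        if (chain[i] == chain[j] && std::abs(idx[i] - idx[j]) <= s_min)
          continue;
        e += count_mode ? 1.0 : (cutoff - std::sqrt(d2));
      }
    }
  }
  return e;
}

// Clash energy restricted to pairs with one bead in set A and one in set B
// (used for Metropolis deltas: only moved-vs-fixed pairs change under a
// rigid segment rotation).
// [[Rcpp::export]]
double clash_cross_cpp(NumericMatrix xyz_a, IntegerVector chain_a,
                       IntegerVector idx_a, NumericMatrix xyz_b,
                       IntegerVector chain_b, IntegerVector idx_b,
                       double cutoff, int s_min, bool count_mode) {
  const int na = xyz_a.nrow(), nb = xyz_b.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> ax(na), ay(na), az(na), bx(nb), by(nb), bz(nb);
  for (int i = 0; i < na; ++i) {
    ax[i] = xyz_a(i, 0); ay[i] = xyz_a(i, 1); az[i] = xyz_a(i, 2);
  }
  for (int j = 0; j < nb; ++j) {
    bx[j] = xyz_b(j, 0); by[j] = xyz_b(j, 1); bz[j] = xyz_b(j, 2);
  }
  double e = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const double dx = ax[i] - bx[j], dy = ay[i] - by[j],
                   dz = az[i] - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        if (chain_a[i] == chain_b[j] &&
            std::abs(idx_a[i] - idx_b[j]) <= s_min)
          continue;
        e += count_mode ? 1.0 : (cutoff - std::sqrt(d2));
      }
    }
  }
  return e;
}
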