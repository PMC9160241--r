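// Meuwissen & Luo (1992) style inbreeding coefficients for a topologically
// ordered pedigree (parents before offspring; 0 = unknown parent).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_inbreeding(const IntegerVector& sire,
                             const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    // Mendelian sampling variance scale for animal i
    double di = 1.0;
    if (s > 0) di -= 0.25 * (1.0 + F[s - 1]);
    if (d > 0) di -= 0.25 * (1.0 + F[d - 1]);
    D[i] = di;
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    // A_ii = sum_j L_j^2 * D_j over ancestors j of i (including i)
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * D[j];
      if (sire[j] > 0) L[sire[j] - 1] += 0.5 * lj;
      if (dam[j] > 0) L[dam[j] - 1] += 0.5 * lj;
    }
    F[i] = aii - 1.0;
  }
  F.attr("D") = D;
  return F;
}
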