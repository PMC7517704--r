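#include <Rcpp.h>
#include <map>
#include <functional>
using namespace Rcpp;

// Pedigree inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
//
// sire, dam: 1-based parent indices, 0 for unknown. Individuals must be
// ordered so that parents precede their offspring (index of parent < index
// of child); the R wrapper enforces this.
//
// For each animal i the algorithm accumulates the self-relationship
// a_ii = sum_j L_j^2 D_j over the ancestors j of i, where L_j collects the
// expected genome contribution of j and D_j = 0.5 - 0.25 (F_sj + F_dj) is the
// within-family (Mendelian sampling) variance, with a missing parent
// contributing F = -1. F_i = a_ii - 1.
// [[Rcpp::export]]
NumericVector inbreeding_ml(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  if (dam.size() != n) stop("sire and dam must have equal length");
  NumericVector F(n);
  std::vector<double> Fv(n + 1, 0.0);
  auto Fpar = [&](int p) { return p == 0 ? -1.0 : Fv[p]; };
  for (int i = 1; i <= n; ++i) {
    const int s = sire[i - 1], d = dam[i - 1];
    if (s >= i || d >= i) stop("parents must precede offspring (acyclic pedigree)");
    if (s == 0 || d == 0) { Fv[i] = 0.0; F[i - 1] = 0.0; continue; }
    // traverse ancestors youngest-first, merging contributions
    std::map<int, double, std::greater<int>> L;
    L[i] = 1.0;
    double a = 0.0;
    while (!L.empty()) {
      auto it = L.begin();
      const int j = it->first;
      const double lj = it->second;
      L.erase(it);
      const int sj = sire[j - 1], dj = dam[j - 1];
      if (sj) L[sj] += 0.5 * lj;
      if (dj) L[dj] += 0.5 * lj;
      a += lj * lj * (0.5 - 0.25 * (Fpar(sj) + Fpar(dj)));
    }
    Fv[i] = a - 1.0;
    F[i - 1] = Fv[i];
  }
  return F;
}
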