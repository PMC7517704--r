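#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch gamete formation over a multi-chromosome genetic map.
// Haldane model: crossover count per chromosome is Poisson(length/100), no
// interference; crossover positions uniform on the chromosome; the starting
// haplotype is chosen with probability 1/2, independently per chromosome.
//
// haps:      L x H integer matrix of haplotypes (one column per haplotype,
//            loci in map order down the rows).
// col_a/col_b: 1-based columns of `haps` holding each gamete's parental
//            haplotype pair (one entry per requested gamete).
// pos:       locus positions in cM, relative to the chromosome start.
// chr_first/chr_last: 1-based locus index bounds of each chromosome.
// chr_len:   chromosome lengths in cM.
//
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
IntegerMatrix drop_gametes(const IntegerMatrix& haps,
                           const IntegerVector& col_a,
                           const IntegerVector& col_b,
                           const NumericVector& pos,
                           const IntegerVector& chr_first,
                           const IntegerVector& chr_last,
                           const NumericVector& chr_len) {
  const int L = haps.nrow();
  const int n = col_a.size();
  const int nchr = chr_first.size();
  if (col_b.size() != n) stop("col_a and col_b must have equal length");
  if (pos.size() != L) stop("pos must have one entry per locus");
  IntegerMatrix out(L, n);
  std::vector<double> cx;
  for (int g = 0; g < n; ++g) {
    int ca = col_a[g], cb = col_b[g];
    if (ca < 1 || ca > haps.ncol() || cb < 1 || cb > haps.ncol())
      stop("haplotype column index out of range");
    const int* ha = &haps(0, ca - 1);
    const int* hb = &haps(0, cb - 1);
    int* dst = &out(0, g);
    for (int c = 0; c < nchr; ++c) {
      const int lo = chr_first[c] - 1, hi = chr_last[c] - 1;
      const double len = chr_len[c];
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      const int k = (int) R::rpois(len / 100.0);
      if (k == 0) {
        const int* src = cur ? hb : ha;
        for (int l = lo; l <= hi; ++l) dst[l] = src[l];
      } else {
        cx.resize(k);
        for (int j = 0; j < k; ++j) cx[j] = unif_rand() * len;
        std::sort(cx.begin(), cx.end());
        int j = 0;
        for (int l = lo; l <= hi; ++l) {
          while (j < k && cx[j] < pos[l]) { cur ^= 1; ++j; }
          dst[l] = cur ? hb[l] : ha[l];
        }
      }
    }
  }
  return out;
}
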