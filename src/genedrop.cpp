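#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Drop founder haplotypes down an ordered pedigree. Haplotypes are handled
// transposed (markers x individuals) so each individual is a contiguous
// column. Founders occupy the first columns with both haplotypes filled;
// every non-founder's parents precede it. One meiosis = a
// Poisson(chromosome length in Morgans) number of crossovers placed
// uniformly (Haldane, no interference) and a random starting haplotype per
// chromosome. Uses R's RNG stream so results are reproducible from
// set.seed().
// [[Rcpp::export(name = ".gene_drop")]]
List gene_drop(const IntegerMatrix& founder_pat_t, const IntegerMatrix& founder_mat_t,
               const IntegerVector& sire, const IntegerVector& dam,
               const IntegerVector& chrom_first, const IntegerVector& chrom_last,
               const NumericVector& pos, double chrom_len, int n_total) {
  const int p = founder_pat_t.nrow();
  const int n_founders = founder_pat_t.ncol();
  const int n_chrom = chrom_first.size();
  IntegerMatrix pat(p, n_total), mat(p, n_total);

  for (int i = 0; i < n_founders; ++i) {
    std::copy(founder_pat_t.column(i).begin(), founder_pat_t.column(i).end(),
              pat.column(i).begin());
    std::copy(founder_mat_t.column(i).begin(), founder_mat_t.column(i).end(),
              mat.column(i).begin());
  }

  std::vector<double> cuts;
  auto meiosis = [&](int par, int* out) {
    const int* A = &pat(0, par);
    const int* B = &mat(0, par);
    for (int c = 0; c < n_chrom; ++c) {
      const int j0 = chrom_first[c] - 1, j1 = chrom_last[c] - 1;
      const int k = (int) R::rpois(chrom_len);
      int start = (unif_rand() < 0.5) ? 0 : 1;
      if (k == 0) {
        const int* src = (start == 0) ? A : B;
        std::copy(src + j0, src + j1 + 1, out + j0);
      } else {
        cuts.resize(k);
        for (int t = 0; t < k; ++t) cuts[t] = unif_rand() * chrom_len;
        std::sort(cuts.begin(), cuts.end());
        int seg = 0;
        for (int j = j0; j <= j1; ++j) {
          while (seg < k && cuts[seg] <= pos[j]) ++seg;
          out[j] = ((start + seg) % 2 == 0) ? A[j] : B[j];
        }
      }
    }
  };

  for (int i = n_founders; i < n_total; ++i) {
    meiosis(sire[i] - 1, &pat(0, i));
    meiosis(dam[i] - 1, &mat(0, i));
  }
  return List::create(_["paternal_t"] = pat, _["maternal_t"] = mat);
}
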