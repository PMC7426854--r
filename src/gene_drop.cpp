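#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis + transmission for a block of pedigree rows.
//
// H1/H2 are L x N raw matrices (loci x individuals, so one gamete is a
// contiguous column) holding the paternal/maternal haplotype of every
// individual (0/1 alleles); founder columns must already be filled.
// Columns first_row..last_row (1-based, inclusive) are generated in place,
// in order, so parents must sit on earlier columns. Crossovers follow Haldane:
// per-chromosome count ~ Poisson(map length in Morgans), positions uniform,
// no interference. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
void cpp_gene_drop(RawMatrix H1, RawMatrix H2,
                   IntegerVector sire_row, IntegerVector dam_row,
                   int first_row, int last_row,
                   IntegerVector chr_first, IntegerVector chr_last,
                   NumericVector pos_morgan) {
  const int nchr = chr_first.size();
  RNGScope scope;
  std::vector<double> xo;
  for (int i = first_row - 1; i < last_row; ++i) {
    const int s = sire_row[i] - 1;
    const int d = dam_row[i] - 1;
    if (s < 0 || d < 0)
      stop("gene drop: individual on row %d has a missing parent", i + 1);
    if (s >= i || d >= i)
      stop("gene drop: pedigree rows are not parent-before-offspring at row %d", i + 1);
    for (int rep = 0; rep < 2; ++rep) {  // 0 = gamete from sire, 1 = from dam
      const int p = (rep == 0) ? s : d;
      for (int c = 0; c < nchr; ++c) {
        const int a = chr_first[c] - 1, b = chr_last[c] - 1;
        const double start = pos_morgan[a];
        const double len = pos_morgan[b] - start;
        int cur = (unif_rand() < 0.5) ? 0 : 1;
        int k = (len > 0) ? (int) R::rpois(len) : 0;
        if (k > 0) {
          xo.assign(k, 0.0);
          for (int t = 0; t < k; ++t) xo[t] = start + unif_rand() * len;
          std::sort(xo.begin(), xo.end());
        }
        int t = 0;
        for (int j = a; j <= b; ++j) {
          while (t < k && xo[t] < pos_morgan[j]) { cur ^= 1; ++t; }
          const Rbyte v = (cur == 0) ? H1(j, p) : H2(j, p);
          if (rep == 0) H1(j, i) = v; else H2(j, i) = v;
        }
      }
    }
  }
}
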