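#include <Rcpp.h>
using namespace Rcpp;

// Sample one recombinant gamete per entry of `parent`.
// Haldane model: crossover count per chromosome ~ Poisson(map length in
// Morgans), chiasma positions uniform on the chromosome, no interference;
// the starting phase of each chromosome is chosen at random.
//
// haplo:  (2 * n_ind) x n_loci phased alleles; rows 2i-1, 2i (1-based) hold
//         the two phases of individual i.
// parent: 1-based individual index per requested gamete.
// pos:    within-chromosome genetic position (Morgans) per locus.
// chr_first/chr_last: 1-based first/last locus index of each chromosome.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& haplo, const IntegerVector& parent,
                          const NumericVector& pos, const IntegerVector& chr_first,
                          const IntegerVector& chr_last, const NumericVector& chr_len) {
  const int ng = parent.size(), nchr = chr_len.size();
  IntegerMatrix out(ng, haplo.ncol());
  std::vector<double> bp;
  for (int g = 0; g < ng; ++g) {
    const int r0 = 2 * (parent[g] - 1);
    for (int c = 0; c < nchr; ++c) {
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      const int i0 = chr_first[c] - 1, i1 = chr_last[c] - 1;
      const int k = (int) R::rpois(chr_len[c]);
      if (k == 0) {
        for (int i = i0; i <= i1; ++i) out(g, i) = haplo(r0 + phase, i);
      } else {
        bp.resize(k);
        for (int j = 0; j < k; ++j) bp[j] = unif_rand() * chr_len[c];
        std::sort(bp.begin(), bp.end());
        int b = 0;
        for (int i = i0; i <= i1; ++i) {
          while (b < k && bp[b] < pos[i]) { phase ^= 1; ++b; }
          out(g, i) = haplo(r0 + phase, i);
        }
      }
    }
  }
  return out;
}
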