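#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gametes for a batch of meioses.
//
// h1, h2: 0/1 haplotype matrices (individuals x loci), loci sorted by
// chromosome then position.  pos holds within-chromosome positions in
// Morgans; chr_begin/chr_end delimit each chromosome (0-based, half-open).
// Crossover count per chromosome is Poisson(chromosome length in Morgans),
// crossover positions uniform, no interference (Haldane); the starting
// haplotype of each chromosome is chosen at random, so unlinked chromosomes
// assort independently.  Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& h1, const IntegerMatrix& h2,
                          const IntegerVector& parent,
                          const NumericVector& pos,
                          const IntegerVector& chr_begin,
                          const IntegerVector& chr_end,
                          const NumericVector& chr_len) {
  const int n = parent.size();
  const int L = h1.ncol();
  const int C = chr_begin.size();
  IntegerMatrix out(n, L);
  std::vector<double> xo;
  for (int g = 0; g < n; ++g) {
    const int p = parent[g] - 1;
    for (int c = 0; c < C; ++c) {
      const int b = chr_begin[c], e = chr_end[c];
      const int nxo = (int) R::rpois(chr_len[c]);
      xo.resize(nxo);
      for (int j = 0; j < nxo; ++j) xo[j] = unif_rand() * chr_len[c];
      std::sort(xo.begin(), xo.end());
      int phase = (unif_rand() < 0.5) ? 1 : 0;
      int j = 0;
      for (int m = b; m < e; ++m) {
        while (j < nxo && xo[j] <= pos[m]) { phase ^= 1; ++j; }
        out(g, m) = phase ? h2(p, m) : h1(p, m);
      }
    }
  }
  return out;
}
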