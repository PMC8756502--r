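#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right longest-exact-match copying of a (possibly masked)
// target haplotype from a set of reference haplotypes. At the current
// unmasked position the reference haplotype sharing the longest identical
// run (over unmasked sites, within the chromosome) wins the run; its
// genetic length (site weights, cM) is credited to that haplotype's
// population, ties split equally. When every reference mismatches at the
// current site (run length 0) all references tie at 0 and the single
// site's weight is split over all of them.
//
// target: 0/1 with NA at masked sites; ref: R x L; pop: 1-based population
// index per reference row; w: per-site cM weight; chrom: integer
// chromosome code per site.
// [[Rcpp::export]]
NumericVector paint_copying_cpp(IntegerVector target, IntegerMatrix ref,
                                IntegerVector pop, int npop,
                                NumericVector w, IntegerVector chrom) {
  const int L = target.size();
  const int R = ref.nrow();
  std::vector<int> idx;
  idx.reserve(L);
  for (int j = 0; j < L; ++j)
    if (target[j] != NA_INTEGER) idx.push_back(j);
  NumericVector out(npop);
  const int n = (int)idx.size();
  std::vector<int> runlen(R);
  int i = 0;
  while (i < n) {
    int best = 0;
    const int ch = chrom[idx[i]];
    for (int r = 0; r < R; ++r) {
      int l = 0;
      while (i + l < n && chrom[idx[i + l]] == ch &&
             ref(r, idx[i + l]) == target[idx[i + l]])
        ++l;
      runlen[r] = l;
      if (l > best) best = l;
    }
    const int adv = best > 0 ? best : 1;
    double wsum = 0.0;
    for (int s = 0; s < adv; ++s) wsum += w[idx[i + s]];
    int nwin = 0;
    for (int r = 0; r < R; ++r) if (runlen[r] == best) ++nwin;
    for (int r = 0; r < R; ++r)
      if (runlen[r] == best) out[pop[r] - 1] += wsum / nwin;
    i += adv;
  }
  return out;
}
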