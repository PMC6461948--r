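#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gamete sampling for a batch of meioses.
//
// h1, h2: parental haplotype matrices (individuals x loci, alleles 0/1).
// parent: 1-based row index of the parent for each gamete.
// rswitch: per-locus probability of switching chromatid relative to the
//   previous locus. Interval j (locus j-1 -> j) carries the Haldane
//   recombination fraction; the first locus of every linkage group carries
//   0.5, which makes the starting chromatid of each group an independent
//   fair coin (flipping the running parity with probability 1/2 yields a
//   uniform independent start, so no explicit reset is needed at group
//   boundaries).
//
// The switch events at a locus are iid Bernoulli(r) across gametes. They
// are sampled column-wise: a Binomial(n, r) count of switching gametes
// followed by a uniform distinct subset of rows (equivalent to n
// independent Bernoulli draws, but O(n r) RNG calls), falling back to the
// direct Bernoulli sweep when r is large. Column-wise processing also
// keeps all matrix access sequential in memory.
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sample_gametes_cpp(const IntegerMatrix& h1,
                                 const IntegerMatrix& h2,
                                 const IntegerVector& parent,
                                 const NumericVector& rswitch) {
  const int n = parent.size();
  const int np = h1.nrow();
  const int L = h1.ncol();
  if (h2.ncol() != L || h2.nrow() != np || rswitch.size() != L)
    stop("haplotype matrices and switch probabilities are misaligned");
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) {
    p[i] = parent[i] - 1;
    if (p[i] < 0 || p[i] >= np) stop("parent index out of range");
  }
  IntegerMatrix out(n, L);
  std::vector<unsigned char> cur(n, 0); // 0 -> copy from h1, 1 -> from h2
  std::vector<unsigned char> hit(n, 0); // scratch for distinct-row sampling
  std::vector<int> rows;
  rows.reserve(64);
  const int* c1 = h1.begin();
  const int* c2 = h2.begin();
  int* o = out.begin();
  for (int j = 0; j < L; ++j, c1 += np, c2 += np, o += n) {
    const double r = rswitch[j];
    if (r >= 0.2) {
      for (int i = 0; i < n; ++i)
        if (unif_rand() < r) cur[i] ^= 1;
    } else if (r > 0.0) {
      const int k = (int) R::rbinom((double) n, r);
      rows.clear();
      while ((int) rows.size() < k) {
        int i = (int) (unif_rand() * n);
        if (i >= n) i = n - 1;
        if (!hit[i]) { hit[i] = 1; rows.push_back(i); }
      }
      for (int i : rows) { cur[i] ^= 1; hit[i] = 0; }
    }
    for (int i = 0; i < n; ++i)
      o[i] = cur[i] ? c2[p[i]] : c1[p[i]];
  }
  return out;
}
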