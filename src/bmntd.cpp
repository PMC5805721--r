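#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for all sample pairs.
//
// P: samples x OTUs relative-abundance matrix (rows sum to 1)
// D: OTU x OTU patristic distance matrix
// ord: integer permutation of OTU indices (1-based), applied to D's
//      rows/columns -- equivalent to shuffling OTU identities across the
//      tips of the phylogeny, the taxa-shuffle null.
//
// For a pair (A, B):
//   bMNTD = 0.5 * ( sum_i pA_i * min_{j in B} d(i, j)
//                 + sum_j pB_j * min_{i in A} d(j, i) )
// Shared OTUs have nearest-taxon distance 0 (a taxon is its own nearest
// neighbour in the other community).
// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix P, NumericMatrix D, IntegerVector ord) {
  const int ns = P.nrow();
  const int no = P.ncol();
  if (D.nrow() != no || D.ncol() != no)
    stop("distance matrix does not match OTU count");
  if (ord.size() != no)
    stop("permutation length does not match OTU count");

  // presence lists per sample
  std::vector< std::vector<int> > present(ns);
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < no; ++i)
      if (P(s, i) > 0.0) present[s].push_back(i);

  // M(i, s) = min over j present in sample s of D[ord(i), ord(j)]
  NumericMatrix M(no, ns);
  for (int s = 0; s < ns; ++s) {
    const std::vector<int>& ps = present[s];
    for (int i = 0; i < no; ++i) {
      double m = R_PosInf;
      const int oi = ord[i] - 1;
      for (size_t k = 0; k < ps.size(); ++k) {
        const double d = D(oi, ord[ps[k]] - 1);
        if (d < m) m = d;
      }
      M(i, s) = m;
    }
  }

  NumericMatrix out(ns, ns);
  for (int a = 0; a < ns; ++a) {
    for (int b = a + 1; b < ns; ++b) {
      double sa = 0.0, sb = 0.0;
      const std::vector<int>& pa = present[a];
      const std::vector<int>& pb = present[b];
      for (size_t k = 0; k < pa.size(); ++k) sa += P(a, pa[k]) * M(pa[k], b);
      for (size_t k = 0; k < pb.size(); ++k) sb += P(b, pb[k]) * M(pb[k], a);
      out(a, b) = out(b, a) = 0.5 * (sa + sb);
    }
  }
  return out;
}
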