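#include <Rcpp.h>
using namespace Rcpp;

// Minimum complementarity score per site category for each shuffled query.
//
// T:   P x L integer matrix; T(p, i) is the encoded transcript base paired
//      by sRNA position i+1 at candidate cleavage position p (1..5).
// cat: length-P integer vector of site categories (0..4).
// pm:  5 x 5 penalty matrix (sRNA base x target base).
// w:   length-L position weights.
// Q:   S x L integer matrix of shuffled encoded queries.
//
// Returns an S x 5 matrix: out(s, c) = min score of shuffle s over sites
// with category exactly c (R_PosInf when no such site).
// [[Rcpp::export(name = ".shuffle_min_scores_cpp")]]
NumericMatrix shuffle_min_scores(IntegerMatrix T, IntegerVector cat,
                                 NumericMatrix pm, NumericVector w,
                                 IntegerMatrix Q) {
  const int P = T.nrow(), L = T.ncol(), S = Q.nrow();
  NumericMatrix out(S, 5);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < P; ++p) {
      double sc = 0.0;
      for (int i = 0; i < L; ++i)
        sc += w[i] * pm(Q(s, i) - 1, T(p, i) - 1);
      const int c = cat[p];
      if (sc < out(s, c)) out(s, c) = sc;
    }
  }
  return out;
}
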