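#include <Rcpp.h>
using namespace Rcpp;

// Weighted degree kernel Gram matrices via match run-lengths.
//
// A maximal run of r consecutive position-wise matches between two equal
// length sequences contains (r - k + 1) matching k-mers for every k <= r,
// so k(s1, s2) = sum over maximal runs of w_d(r) with
// w_d(r) = sum_{k=1}^{min(r,d)} beta_k (r - k + 1).
// wtab holds w_d(r) for r = 1..L, one column per requested order d, so a
// single pass over the match vector evaluates the kernel for several
// orders at once.
//
// X, Y: integer code matrices (rows = sequences, columns = positions).
// sym: X and Y are the same set (compute upper triangle only).

// [[Rcpp::export]]
List wd_gram_cpp(IntegerMatrix X, IntegerMatrix Y, NumericMatrix wtab,
                 bool sym) {
  const int nX = X.nrow(), nY = Y.nrow(), L = X.ncol(), nd = wtab.ncol();
  if (Y.ncol() != L) stop("sequence sets have different lengths");
  List out(nd);
  std::vector<NumericMatrix> Ks;
  for (int t = 0; t < nd; ++t) Ks.push_back(NumericMatrix(nX, nY));
  std::vector<double> acc(nd);
  for (int i = 0; i < nX; ++i) {
    for (int j = sym ? i : 0; j < nY; ++j) {
      std::fill(acc.begin(), acc.end(), 0.0);
      int run = 0;
      for (int l = 0; l < L; ++l) {
        if (X(i, l) == Y(j, l)) {
          ++run;
        } else if (run > 0) {
          for (int t = 0; t < nd; ++t) acc[t] += wtab(run - 1, t);
          run = 0;
        }
      }
      if (run > 0)
        for (int t = 0; t < nd; ++t) acc[t] += wtab(run - 1, t);
      for (int t = 0; t < nd; ++t) {
        Ks[t](i, j) = acc[t];
        if (sym) Ks[t](j, i) = acc[t];
      }
    }
  }
  for (int t = 0; t < nd; ++t) out[t] = Ks[t];
  return out;
}
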