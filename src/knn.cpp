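#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbour score: fraction of positive labels among the k
// training points closest (Euclidean) to each query row. Ties in distance
// are resolved by training-row order (stable partial selection).
// [[Rcpp::export(name = ".knn_score_cpp")]]
NumericVector knn_score_cpp(NumericMatrix Xtr, IntegerVector ytr,
                            NumericMatrix Xte, int k) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow(), p = Xtr.ncol();
  if (k > ntr) k = ntr;
  NumericVector out(nte);
  std::vector<std::pair<double, int> > d(ntr);
  for (int i = 0; i < nte; ++i) {
    for (int j = 0; j < ntr; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = Xte(i, c) - Xtr(j, c);
        s += diff * diff;
      }
      d[j] = std::make_pair(s, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double pos = 0.0;
    for (int j = 0; j < k; ++j) pos += ytr[d[j].second];
    out[i] = pos / k;
  }
  return out;
}
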