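#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Expected posterior entropy (nats) for every candidate stimulus.
//
// P and XLsum are the engine's precomputed K x C tables: P(i, j) is the
// r = 1 response probability of grid cell i at candidate j, and XLsum is
// p log p + (1 - p) log(1 - p) elementwise. post is the current posterior
// over the K grid cells. Cells with posterior mass <= support_tol are
// skipped: their total contribution is bounded by K * support_tol * |log
// support_tol|, far below the stimulus-selection tie tolerance.
// [[Rcpp::export]]
NumericVector psi_expected_entropy_cpp(const NumericMatrix& P,
                                       const NumericMatrix& XLsum,
                                       const NumericVector& post,
                                       double support_tol) {
  const int K = P.nrow();
  const int C = P.ncol();
  std::vector<int> supp;
  supp.reserve(K);
  double xlp_sum = 0.0;
  for (int i = 0; i < K; ++i) {
    const double q = post[i];
    if (q > support_tol) {
      supp.push_back(i);
      xlp_sum += q * std::log(q);
    }
  }
  const int S = static_cast<int>(supp.size());
  NumericVector ee(C);
  for (int j = 0; j < C; ++j) {
    const double* pj = &P(0, j);
    const double* xj = &XLsum(0, j);
    double pr1 = 0.0;
    double xl = 0.0;
    for (int t = 0; t < S; ++t) {
      const int i = supp[t];
      const double q = post[i];
      pr1 += pj[i] * q;
      xl += xj[i] * q;
    }
    const double pr0 = 1.0 - pr1;
    double e = -xlp_sum - xl;
    if (pr1 > 0.0) e += pr1 * std::log(pr1);
    if (pr0 > 0.0) e += pr0 * std::log(pr0);
    ee[j] = e;
  }
  return ee;
}
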