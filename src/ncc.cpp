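#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalised cross-correlation of each echo row against a reference gate.
//
// echoes: P x (L + 2*maxlag) matrix; row p holds the gated echo of pulse p,
//         wider than the reference by maxlag samples on each side.
// ref:    reference gate of length L.
// Returns a P x (2*maxlag + 1) matrix; column (l + maxlag + 1) holds the
// normalised correlation of ref against echoes[p, l .. l+L-1] (0-based
// offset l = lag + maxlag). Zero-energy segments yield correlation 0.
// [[Rcpp::export(name = ".nccLags")]]
NumericMatrix nccLags(NumericMatrix echoes, NumericVector ref, int maxlag) {
  const int P = echoes.nrow();
  const int W = echoes.ncol();
  const int L = ref.size();
  const int nlag = 2 * maxlag + 1;
  if (W != L + 2 * maxlag)
    stop("echo width must equal reference length + 2*maxlag");

  double refE = 0.0;
  for (int i = 0; i < L; ++i) refE += ref[i] * ref[i];
  const double refN = std::sqrt(refE);

  NumericMatrix out(P, nlag);
  std::vector<double> row(W);
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < W; ++i) row[i] = echoes(p, i);
    // running energy via prefix sums
    std::vector<double> cs(W + 1, 0.0);
    for (int i = 0; i < W; ++i) cs[i + 1] = cs[i] + row[i] * row[i];
    for (int l = 0; l < nlag; ++l) {
      double num = 0.0;
      const double* seg = row.data() + l;
      for (int i = 0; i < L; ++i) num += seg[i] * ref[i];
      const double segE = cs[l + L] - cs[l];
      const double den = refN * std::sqrt(segE);
      out(p, l) = (den > 0.0) ? num / den : 0.0;
    }
  }
  return out;
}
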