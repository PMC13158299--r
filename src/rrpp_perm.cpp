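#include <Rcpp.h>
using namespace Rcpp;

// Quadratic-form permutation kernel for residual-randomization tests.
//
// For an idempotent contrast matrix D (n x n) and the Gram matrix
// G = E E' of reduced-model residuals, the sum of squares of D applied to
// row-permuted residuals is  sum_{a,b} D(a,b) * G(p(a), p(b)).  Evaluating
// this directly avoids re-fitting the linear model for every permutation.
//
// perms: n_perm x n matrix of 1-based permutation indices.
// [[Rcpp::export]]
NumericVector perm_quadform(NumericMatrix D, NumericMatrix G,
                            IntegerMatrix perms) {
  const int n = D.nrow();
  if (D.ncol() != n || G.nrow() != n || G.ncol() != n)
    stop("dimension mismatch between D and G");
  if (perms.ncol() != n)
    stop("permutation matrix must have n columns");
  const int np = perms.nrow();
  NumericVector out(np);
  std::vector<int> p(n);
  for (int j = 0; j < np; ++j) {
    for (int a = 0; a < n; ++a) {
      int idx = perms(j, a) - 1;
      if (idx < 0 || idx >= n) stop("permutation index out of range");
      p[a] = idx;
    }
    double s = 0.0;
    for (int a = 0; a < n; ++a) {
      const int pa = p[a];
      for (int b = 0; b < n; ++b)
        s += D(a, b) * G(pa, p[b]);
    }
    out[j] = s;
  }
  return out;
}
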