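#include <Rcpp.h>
using namespace Rcpp;

// Non-negative penalized least squares along a descending lambda grid,
// by cyclic coordinate descent with clipping at zero.
//
// Objective, matching the method's penalized form exactly:
//   ridge   (penalty=0): ||y - X a||_2^2 + (lambda/2) ||a||_2^2
//   lasso   (penalty=1): ||y - X a||_2^2 + lambda ||a||_1
//   enet    (penalty=2): ||y - X a||_2^2 +
//                        lambda * ((1-w)/2 ||a||_2^2 + w ||a||_1)
// subject to a >= 0. Coordinate updates use the Gram matrix (p is small);
// solutions are warm-started from the previous (larger) lambda.
//
// Returns a p x nlambda coefficient matrix.
// [[Rcpp::export]]
NumericMatrix nn_penalized_path_cpp(const NumericMatrix& X,
                                    const NumericVector& y,
                                    const NumericVector& lambdas,
                                    const int penalty,
                                    const double mixing,
                                    const double tol,
                                    const int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix out(p, nl);
  if (p == 0) return out;

  // Gram matrix G = X'X and moment vector b = X'y
  NumericMatrix G(p, p);
  NumericVector b(p);
  for (int j = 0; j < p; ++j) {
    double bj = 0.0;
    for (int i = 0; i < n; ++i) bj += X(i, j) * y[i];
    b[j] = bj;
    for (int k = j; k < p; ++k) {
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += X(i, j) * X(i, k);
      G(j, k) = g;
      G(k, j) = g;
    }
  }

  std::vector<double> a(p, 0.0), Ga(p, 0.0);  // Ga = G a, kept incrementally

  for (int li = 0; li < nl; ++li) {
    const double lambda = lambdas[li];
    double l2 = 0.0, l1 = 0.0;  // quadratic / soft-threshold parts
    if (penalty == 0) {
      l2 = lambda / 2.0;
    } else if (penalty == 1) {
      l1 = lambda / 2.0;  // from gradient of lambda*|a|: threshold lambda/2
    } else {
      l2 = lambda * (1.0 - mixing) / 2.0;
      l1 = lambda * mixing / 2.0;
    }
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_change = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        double anew;
        if (gjj + l2 <= 0.0) {
          anew = 0.0;
        } else {
          // partial residual correlation: X_j' (y - X a) + gjj * a_j
          const double rho = b[j] - Ga[j] + gjj * a[j];
          anew = (rho - l1) / (gjj + l2);
          if (anew < 0.0) anew = 0.0;
        }
        const double d = anew - a[j];
        if (d != 0.0) {
          a[j] = anew;
          for (int k = 0; k < p; ++k) Ga[k] += G(k, j) * d;
          const double ad = std::abs(d);
          if (ad > max_change) max_change = ad;
        }
      }
      if (max_change < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, li) = a[j];
  }
  return out;
}
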