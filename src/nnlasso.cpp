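#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the nonnegative lasso in Gram form:
//   min_{g >= 0}  0.5 * g' G g - b' g + lambda * sum(g)
// which is 0.5 * ||y - D' g||^2 + lambda * ||g||_1 up to a constant,
// with G = D D' and b = D y. Residual vector r = G g is maintained so a
// coordinate update costs O(n). Convergence is declared when the largest
// coordinate move in a full sweep falls below tol.
static void cd_sweep_solve(const double* G, int n, const double* b,
                           double lambda, int maxit, double tol,
                           double* gamma) {
  std::vector<double> r(n, 0.0); // r = G gamma
  for (int j = 0; j < n; ++j) gamma[j] = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double delta_max = 0.0;
    for (int j = 0; j < n; ++j) {
      double gjj = G[(size_t)j * n + j];
      if (gjj <= 0.0) continue; // zero row: coefficient stays at 0
      double grad_rest = r[j] - gjj * gamma[j];
      double gnew = (b[j] - grad_rest - lambda) / gjj;
      if (gnew < 0.0) gnew = 0.0;
      double d = gnew - gamma[j];
      if (d != 0.0) {
        const double* col = G + (size_t)j * n;
        for (int k = 0; k < n; ++k) r[k] += d * col[k];
        gamma[j] = gnew;
        double ad = d < 0 ? -d : d;
        if (ad > delta_max) delta_max = ad;
      }
    }
    if (delta_max < tol) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_nnlasso(NumericMatrix G, NumericVector b, double lambda,
                          int maxit, double tol) {
  int n = G.nrow();
  NumericVector gamma(n);
  cd_sweep_solve(REAL(G), n, REAL(b), lambda, maxit, tol, REAL(gamma));
  return gamma;
}

// Solve one nonnegative lasso per gene against the dictionary of all other
// genes. Gfull is the N x N Gram matrix of the propagated annotation rows;
// the subproblem for gene i uses Gfull with row/column i deleted and
// b = Gfull[-i, i]. Returns the N x N coefficient matrix C with
// C[i, j] = gamma_i(j) placed at the original gene indices (diagonal 0).
// [[Rcpp::export]]
NumericMatrix cpp_sparse_codes(NumericMatrix Gfull, double lambda,
                               int maxit, double tol) {
  int N = Gfull.nrow();
  NumericMatrix C(N, N);
  std::vector<double> G((size_t)(N - 1) * (N - 1));
  std::vector<double> b(N - 1), gamma(N - 1);
  const double* GF = REAL(Gfull);
  for (int i = 0; i < N; ++i) {
    // build the deleted Gram matrix and linear term
    int cj = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double* col = GF + (size_t)j * N;
      int ck = 0;
      for (int k = 0; k < N; ++k) {
        if (k == i) continue;
        G[(size_t)cj * (N - 1) + ck] = col[k];
        ++ck;
      }
      b[cj] = GF[(size_t)i * N + j]; // Gfull[j, i] == Gfull[i, j]
      ++cj;
    }
    cd_sweep_solve(G.data(), N - 1, b.data(), lambda, maxit, tol,
                   gamma.data());
    int cjj = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      C(i, j) = gamma[cjj++];
    }
  }
  return C;
}
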