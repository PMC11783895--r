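#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kabsch RMSD between two centered coordinate sets (3 x n each).
static double kabsch_rmsd(const arma::mat &A, const arma::mat &B) {
  arma::mat H = B * A.t();            // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return NA_REAL;
  double d = arma::det(V * U.t());
  double sum_s = s(0) + s(1) + (d < 0 ? -s(2) : s(2));
  double e2 = arma::accu(A % A) + arma::accu(B % B) - 2.0 * sum_s;
  if (e2 < 0) e2 = 0;
  return std::sqrt(e2 / A.n_cols);
}

// All-pairs minimal RMSD over rigid superposition. coords: (3*m) x n matrix,
// column j holding the m atom positions of conformer j stacked x1,y1,z1,x2,...
// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
NumericMatrix pairwise_rmsd_cpp(NumericMatrix coords, int natoms) {
  const int n = coords.ncol();
  std::vector<arma::mat> cs(n);
  for (int j = 0; j < n; ++j) {
    arma::mat M(3, natoms);
    for (int a = 0; a < natoms; ++a) {
      M(0, a) = coords(3 * a, j);
      M(1, a) = coords(3 * a + 1, j);
      M(2, a) = coords(3 * a + 2, j);
    }
    M.each_col() -= arma::mean(M, 1);
    cs[j] = M;
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r = kabsch_rmsd(cs[i], cs[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  return out;
}
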