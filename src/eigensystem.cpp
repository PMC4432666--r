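#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batch eigensystem of symmetric 3x3 diffusion tensors.
// tens: n x 6 matrix with columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
// Returns values (n x 3, descending) and vectors (n x 9, the eigenvector
// matrix V stacked column-wise: v1x v1y v1z v2x ... v3z), so column j of V
// pairs with eigenvalue j. Non-finite tensors yield NaN rows.
// [[Rcpp::export]]
List eig3_batch(const arma::mat& tens) {
  const arma::uword n = tens.n_rows;
  if (tens.n_cols != 6) stop("tensor matrix must have 6 columns");
  arma::mat vals(n, 3);
  arma::mat vecs(n, 9);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (arma::uword i = 0; i < n; ++i) {
    const double xx = tens(i, 0), yy = tens(i, 1), zz = tens(i, 2);
    const double xy = tens(i, 3), xz = tens(i, 4), yz = tens(i, 5);
    if (!std::isfinite(xx) || !std::isfinite(yy) || !std::isfinite(zz) ||
        !std::isfinite(xy) || !std::isfinite(xz) || !std::isfinite(yz)) {
      vals.row(i).fill(arma::datum::nan);
      vecs.row(i).fill(arma::datum::nan);
      continue;
    }
    D(0, 0) = xx; D(1, 1) = yy; D(2, 2) = zz;
    D(0, 1) = D(1, 0) = xy;
    D(0, 2) = D(2, 0) = xz;
    D(1, 2) = D(2, 1) = yz;
    arma::eig_sym(ev, V, D);  // ascending
    // reorder descending
    for (int j = 0; j < 3; ++j) {
      vals(i, j) = ev(2 - j);
      for (int k = 0; k < 3; ++k) vecs(i, 3 * j + k) = V(k, 2 - j);
    }
  }
  return List::create(Named("values") = vals, Named("vectors") = vecs);
}
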