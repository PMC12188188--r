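// Compiled kernels for the same-length 1-D convolution: the only part of the
// engine where R-level buffer copies dominate. Activations arrive as cubes
// (L positions, n sequences, cin channels); weights as one (k*cin, cout)
// matrix whose row blocks are the kernel taps. Both functions mirror the
// shift-and-GEMM decomposition: y[p] = sum_j W_j' x[p + j - pad].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Materialize the im2col buffer Xc (L*n rows, k*cin cols): column block j
// holds the input shifted by (j - pad) positions, zero-padded at the ends.
static void build_im2col(const arma::cube& a, const int k, arma::mat& Xc) {
  const uword L = a.n_rows, n = a.n_cols, cin = a.n_slices;
  const int pad = (k - 1) / 2;
  const mat a2(const_cast<double*>(a.memptr()), L, n * cin, false, true);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    mat B(Xc.colptr(uword(j) * cin), L, n * cin, false, true);
    if (off == 0) {
      B = a2;
    } else {
      B.zeros();
      if (off > 0) {
        B.rows(0, L - 1 - off) = a2.rows(off, L - 1);
      } else {
        B.rows(-off, L - 1) = a2.rows(0, L - 1 + off);
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_forward(const arma::cube& a, const arma::mat& W,
                           const arma::vec& b, const int k) {
  const uword L = a.n_rows, n = a.n_cols, cin = a.n_slices;
  mat Xc(L * n, uword(k) * cin);
  build_im2col(a, k, Xc);
  mat z = Xc * W;
  z.each_row() += b.t();
  return z;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::mat& dz, const arma::cube& a,
                             const arma::mat& W, const int k) {
  const uword L = a.n_rows, n = a.n_cols, cin = a.n_slices;
  const int pad = (k - 1) / 2;
  mat Xc(L * n, uword(k) * cin);
  build_im2col(a, k, Xc);
  mat dW = Xc.t() * dz;
  vec db = sum(dz, 0).t();
  mat tmp = dz * W.t(); // (L*n, k*cin)
  cube dx(L, n, cin, fill::zeros);
  mat dx2(dx.memptr(), L, n * cin, false, true);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const mat T(tmp.colptr(uword(j) * cin), L, n * cin, false, true);
    // output position p consumed x[p + off]; route the gradient back
    if (off == 0) {
      dx2 += T;
    } else if (off > 0) {
      dx2.rows(off, L - 1) += T.rows(0, L - 1 - off);
    } else {
      dx2.rows(0, L - 1 + off) += T.rows(-off, L - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Batch normalization over rows (one column per channel). Train mode uses
// batch statistics and returns them; eval mode normalizes with the running
// statistics. eps matches the engine's BN_EPS.
static const double BN_EPS_C = 1e-5;

// [[Rcpp::export]]
Rcpp::List cpp_bn_train(const arma::mat& x, const arma::vec& gamma,
                        const arma::vec& beta) {
  const uword m = x.n_rows, c = x.n_cols;
  rowvec mu = mean(x, 0);
  mat xc = x.each_row() - mu;
  rowvec v = mean(square(xc), 0);
  rowvec istd = 1.0 / sqrt(v + BN_EPS_C);
  mat xhat = xc.each_row() % istd;
  mat y = xhat.each_row() % gamma.t();
  y.each_row() += beta.t();
  double ub = m > 1 ? double(m) / double(m - 1) : 1.0;
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd.t(),
                            Rcpp::Named("mu") = mu.t(),
                            Rcpp::Named("var_unbiased") = (v * ub).t());
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_eval(const arma::mat& x, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& rmean,
                       const arma::vec& rvar) {
  rowvec istd = 1.0 / sqrt(rvar.t() + BN_EPS_C);
  mat xhat = x.each_row() - rmean.t();
  xhat.each_row() %= istd;
  mat y = xhat.each_row() % gamma.t();
  y.each_row() += beta.t();
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd.t());
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_backward(const arma::mat& dy, const arma::mat& xhat,
                           const arma::vec& istd, const arma::vec& gamma,
                           const bool train) {
  const uword m = dy.n_rows;
  rowvec dgamma = sum(dy % xhat, 0);
  rowvec dbeta = sum(dy, 0);
  mat dxhat = dy.each_row() % gamma.t();
  mat dx;
  if (train) {
    rowvec s1 = sum(dxhat, 0) / double(m);
    rowvec s2 = sum(dxhat % xhat, 0) / double(m);
    dx = dxhat.each_row() - s1;
    dx -= xhat.each_row() % s2;
    dx.each_row() %= istd.t();
  } else {
    dx = dxhat.each_row() % istd.t();
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma.t(),
                            Rcpp::Named("dbeta") = dbeta.t());
}
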