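// Hot loops of the CRNN: valid 1-D convolution (deep-learning
// cross-correlation convention), time-distributed dense, and the
// simple (Elman-style) recurrent cell with sigmoid activation,
// forward and backward. Cubes are laid out (time, feature, example)
// so that one slice is one example.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const rowvec& x, uword klen, mat& M) {
  const uword To = x.n_elem - klen + 1;
  for (uword j = 0; j < klen; ++j) {
    M.col(j) = x.subvec(j, j + To - 1).t();
  }
}

// X: (n, T) examples; K: (klen, F); b: (F). Returns pre-activation
// cube (To, F, n) with To = T - klen + 1.
// [[Rcpp::export]]
arma::cube conv1d_forward_cpp(const arma::mat& X, const arma::mat& K,
                              const arma::vec& b) {
  const uword n = X.n_rows, T = X.n_cols, klen = K.n_rows, F = K.n_cols;
  if (T < klen) Rcpp::stop("input shorter than kernel");
  const uword To = T - klen + 1;
  cube Y(To, F, n);
  mat M(To, klen);
  for (uword i = 0; i < n; ++i) {
    rowvec x = X.row(i);
    im2col(x, klen, M);
    mat Yi = M * K;
    Yi.each_row() += b.t();
    Y.slice(i) = Yi;
  }
  return Y;
}

// Gradient of the conv kernel and bias given dY (To, F, n).
// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::mat& X, const arma::cube& dY,
                               const int klen_) {
  const uword klen = (uword)klen_;
  const uword n = X.n_rows, T = X.n_cols;
  const uword To = T - klen + 1, F = dY.n_cols;
  if (dY.n_rows != To || dY.n_slices != n) Rcpp::stop("dY shape mismatch");
  mat dK(klen, F, fill::zeros);
  vec db(F, fill::zeros);
  mat M(To, klen);
  for (uword i = 0; i < n; ++i) {
    rowvec x = X.row(i);
    im2col(x, klen, M);
    dK += M.t() * dY.slice(i);
    db += sum(dY.slice(i), 0).t();
  }
  return Rcpp::List::create(Rcpp::Named("dK") = dK, Rcpp::Named("db") = db);
}

// Z: (T, in, n); W: (in, out); b: (out). Pre-activation (T, out, n).
// [[Rcpp::export]]
arma::cube td_dense_forward_cpp(const arma::cube& Z, const arma::mat& W,
                                const arma::vec& b) {
  cube Y(Z.n_rows, W.n_cols, Z.n_slices);
  for (uword i = 0; i < Z.n_slices; ++i) {
    mat Yi = Z.slice(i) * W;
    Yi.each_row() += b.t();
    Y.slice(i) = Yi;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List td_dense_backward_cpp(const arma::cube& Z, const arma::mat& W,
                                 const arma::cube& dY) {
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_cols, fill::zeros);
  cube dZ(Z.n_rows, Z.n_cols, Z.n_slices);
  for (uword i = 0; i < Z.n_slices; ++i) {
    dW += Z.slice(i).t() * dY.slice(i);
    db += sum(dY.slice(i), 0).t();
    dZ.slice(i) = dY.slice(i) * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dZ") = dZ);
}

// Simple recurrent cell, sigmoid activation, zero initial state:
//   h_t = sigmoid(z_t W + h_{t-1} U + b)
// Z: (T, in, n). Returns all hidden states H: (T, u, n). All examples
// advance together so each timestep is one (n x in)(in x u) GEMM.
// [[Rcpp::export]]
arma::cube rnn_forward_cpp(const arma::cube& Z, const arma::mat& W,
                           const arma::mat& U, const arma::vec& b) {
  const uword T = Z.n_rows, in = Z.n_cols, n = Z.n_slices, u = W.n_cols;
  cube H(T, u, n);
  mat h(n, u, fill::zeros);
  mat Zt(n, in);
  for (uword t = 0; t < T; ++t) {
    for (uword i = 0; i < n; ++i) Zt.row(i) = Z.slice(i).row(t);
    mat a = Zt * W + h * U;
    a.each_row() += b.t();
    h = 1.0 / (1.0 + exp(-a));
    for (uword i = 0; i < n; ++i) H.slice(i).row(t) = h.row(i);
  }
  return H;
}

// Backpropagation through time for the final-state read-out: only the
// last hidden state feeds the classifier, so the incoming gradient is
// dHT (n, u). Returns parameter gradients and dZ (T, in, n).
// [[Rcpp::export]]
Rcpp::List rnn_backward_cpp(const arma::cube& Z, const arma::cube& H,
                            const arma::mat& W, const arma::mat& U,
                            const arma::mat& dHT) {
  const uword T = Z.n_rows, in = Z.n_cols, n = Z.n_slices, u = W.n_cols;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dU(u, u, fill::zeros);
  vec db(u, fill::zeros);
  cube dZ(Z.n_rows, Z.n_cols, Z.n_slices);
  mat dh = dHT;              // (n, u)
  mat Zt(n, in), ht(n, u), hprev(n, u);
  for (uword t = T; t-- > 0;) {
    for (uword i = 0; i < n; ++i) {
      Zt.row(i) = Z.slice(i).row(t);
      ht.row(i) = H.slice(i).row(t);
      if (t > 0) hprev.row(i) = H.slice(i).row(t - 1);
    }
    mat ds = dh % ht % (1.0 - ht);
    dW += Zt.t() * ds;
    if (t > 0) dU += hprev.t() * ds;
    db += sum(ds, 0).t();
    mat dZt = ds * W.t();
    for (uword i = 0; i < n; ++i) dZ.slice(i).row(t) = dZt.row(i);
    dh = ds * U.t();
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = db, Rcpp::Named("dZ") = dZ);
}
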