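// 2D/1D same-padding convolutions (im2col + BLAS) for the fully convolutional
// residual contact network. Activations are cubes (L x L x C) / matrices
// (L x C); a conv layer is a weight matrix W of shape (C_in * K^2, C_out)
// plus bias. Patch index order inside a column: ch * K^2 + (dc+P) * K + (dr+P)
// with P = (K-1)/2. All kernels are K = 3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int K = 3;   // kernel width
static const int P = 1;   // zero padding

static mat im2col2d(const cube &X) {
  const uword L1 = X.n_rows, L2 = X.n_cols, C = X.n_slices;
  mat out(L1 * L2, C * K * K, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    const mat &sl = X.slice(ch);
    for (int dc = -P; dc <= P; ++dc) {
      for (int dr = -P; dr <= P; ++dr) {
        const uword col = ch * K * K + (dc + P) * K + (dr + P);
        // output pixel (r, c) reads sl(r + dr, c + dc)
        for (uword c = 0; c < L2; ++c) {
          const sword cs = (sword)c + dc;
          if (cs < 0 || cs >= (sword)L2) continue;
          for (uword r = 0; r < L1; ++r) {
            const sword rs = (sword)r + dr;
            if (rs < 0 || rs >= (sword)L1) continue;
            out(c * L1 + r, col) = sl(rs, cs);
          }
        }
      }
    }
  }
  return out;
}

static cube col2im2d(const mat &cols, uword L1, uword L2, uword C) {
  cube X(L1, L2, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    mat &sl = X.slice(ch);
    for (int dc = -P; dc <= P; ++dc) {
      for (int dr = -P; dr <= P; ++dr) {
        const uword col = ch * K * K + (dc + P) * K + (dr + P);
        for (uword c = 0; c < L2; ++c) {
          const sword cs = (sword)c + dc;
          if (cs < 0 || cs >= (sword)L2) continue;
          for (uword r = 0; r < L1; ++r) {
            const sword rs = (sword)r + dr;
            if (rs < 0 || rs >= (sword)L1) continue;
            sl(rs, cs) += cols(c * L1 + r, col);
          }
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube &X, const arma::mat &W,
                     const arma::vec &b) {
  const uword L1 = X.n_rows, L2 = X.n_cols;
  if (W.n_rows != X.n_slices * K * K)
    Rcpp::stop("conv2d_fw: weight rows (%d) do not match input channels x 9 (%d)",
               (int)W.n_rows, (int)(X.n_slices * K * K));
  if (W.n_cols != b.n_elem)
    Rcpp::stop("conv2d_fw: bias length does not match output channels");
  mat Y = im2col2d(X) * W;            // (L1*L2) x C_out
  Y.each_row() += b.t();
  return cube(Y.memptr(), L1, L2, W.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube &X, const arma::mat &W,
                     const arma::cube &dY) {
  const uword L1 = X.n_rows, L2 = X.n_cols, Cin = X.n_slices,
              Cout = dY.n_slices;
  if (dY.n_rows != L1 || dY.n_cols != L2)
    Rcpp::stop("conv2d_bw: gradient spatial dims do not match input");
  mat dYm(const_cast<double *>(dY.memptr()), L1 * L2, Cout, false, true);
  mat Xcol = im2col2d(X);
  mat dW = Xcol.t() * dYm;            // (Cin*9) x Cout
  vec db = sum(dYm, 0).t();
  cube dX = col2im2d(dYm * W.t(), L1, L2, Cin);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

static mat im2col1d(const mat &X) {
  const uword L = X.n_rows, C = X.n_cols;
  mat out(L, C * K, fill::zeros);
  for (uword ch = 0; ch < C; ++ch)
    for (int dr = -P; dr <= P; ++dr) {
      const uword col = ch * K + (dr + P);
      for (uword r = 0; r < L; ++r) {
        const sword rs = (sword)r + dr;
        if (rs < 0 || rs >= (sword)L) continue;
        out(r, col) = X(rs, ch);
      }
    }
  return out;
}

static mat col2im1d(const mat &cols, uword L, uword C) {
  mat X(L, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch)
    for (int dr = -P; dr <= P; ++dr) {
      const uword col = ch * K + (dr + P);
      for (uword r = 0; r < L; ++r) {
        const sword rs = (sword)r + dr;
        if (rs < 0 || rs >= (sword)L) continue;
        X(rs, ch) += cols(r, col);
      }
    }
  return X;
}

// [[Rcpp::export]]
arma::mat conv1d_fw(const arma::mat &X, const arma::mat &W,
                    const arma::vec &b) {
  if (W.n_rows != X.n_cols * K)
    Rcpp::stop("conv1d_fw: weight rows do not match input channels x 3");
  mat Y = im2col1d(X) * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw(const arma::mat &X, const arma::mat &W,
                     const arma::mat &dY) {
  mat Xcol = im2col1d(X);
  mat dW = Xcol.t() * dY;
  vec db = sum(dY, 0).t();
  mat dX = col2im1d(dY * W.t(), X.n_rows, X.n_cols);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
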