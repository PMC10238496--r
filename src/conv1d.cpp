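// 1-D convolution kernels for the contrastive encoder.
//
// Activations use a time-major layout: a C x (L*B) matrix whose column
// (t-1)*B + b holds channel values of sample b at time t.  With this
// layout every stride-1 convolution tap is one GEMM on a contiguous
// column view (no im2col copy); strided taps copy whole B-column time
// blocks, which are large contiguous memcpys.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// valid output-time range [t0, t1] for tap k (0-based)
static inline void tap_range(int k, int pl, int stride, int L, int Lout,
                             int& t0, int& t1) {
  int num = pl - k;
  t0 = num <= 0 ? 0 : (num + stride - 1) / stride;
  t1 = (L - 1 + pl - k) / stride;
  if (t1 > Lout - 1) t1 = Lout - 1;
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::mat& Wm,
                         int Cin, int K, int stride, int L, int B,
                         int pl, int Lout) {
  const int Cout = Wm.n_rows;
  mat Y(Cout, (size_t)Lout * B, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int t0, t1;
    tap_range(k, pl, stride, L, Lout, t0, t1);
    if (t0 > t1) continue;
    const int nt = t1 - t0 + 1;
    const mat Wk = Wm.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1);
    if (stride == 1) {
      const int u0 = t0 * stride - pl + k;
      Y.cols((size_t)t0 * B, (size_t)(t1 + 1) * B - 1) +=
        Wk * X.cols((size_t)u0 * B, (size_t)(u0 + nt) * B - 1);
    } else {
      mat tmp(Cin, (size_t)nt * B);
      for (int i = 0; i < nt; ++i) {
        const int u = (t0 + i) * stride - pl + k;
        std::memcpy(tmp.colptr((size_t)i * B), X.colptr((size_t)u * B),
                    (size_t)Cin * B * sizeof(double));
      }
      Y.cols((size_t)t0 * B, (size_t)(t1 + 1) * B - 1) += Wk * tmp;
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& X, const arma::mat& Wm,
                          const arma::mat& dY, int Cin, int K, int stride,
                          int L, int B, int pl, int Lout) {
  const int Cout = Wm.n_rows;
  mat dWm(Cout, (size_t)Cin * K, fill::zeros);
  mat dX(Cin, (size_t)L * B, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int t0, t1;
    tap_range(k, pl, stride, L, Lout, t0, t1);
    if (t0 > t1) continue;
    const int nt = t1 - t0 + 1;
    const mat Wk = Wm.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1);
    const mat dYv = dY.cols((size_t)t0 * B, (size_t)(t1 + 1) * B - 1);
    if (stride == 1) {
      const int u0 = t0 * stride - pl + k;
      dWm.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) +=
        dYv * X.cols((size_t)u0 * B, (size_t)(u0 + nt) * B - 1).t();
      dX.cols((size_t)u0 * B, (size_t)(u0 + nt) * B - 1) += Wk.t() * dYv;
    } else {
      mat tmp(Cin, (size_t)nt * B);
      for (int i = 0; i < nt; ++i) {
        const int u = (t0 + i) * stride - pl + k;
        std::memcpy(tmp.colptr((size_t)i * B), X.colptr((size_t)u * B),
                    (size_t)Cin * B * sizeof(double));
      }
      dWm.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) += dYv * tmp.t();
      const mat T = Wk.t() * dYv;   // Cin x nt*B
      for (int i = 0; i < nt; ++i) {
        const int u = (t0 + i) * stride - pl + k;
        dX.cols((size_t)u * B, (size_t)(u + 1) * B - 1) +=
          T.cols((size_t)i * B, (size_t)(i + 1) * B - 1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dWm,
                            Rcpp::Named("dX") = dX);
}

// Batch normalization over columns (per-channel moments), fused to
// minimize temporaries.  Returns the affine output plus the cache needed
// for the backward pass.

// [[Rcpp::export(name = ".bn_fwd_cpp")]]
Rcpp::List bn_fwd_cpp(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  const uword C = X.n_rows, N = X.n_cols;
  vec m = mean(X, 1);
  vec v(C, fill::zeros);
  for (uword j = 0; j < N; ++j) {
    const double* x = X.colptr(j);
    for (uword c = 0; c < C; ++c) {
      const double d = x[c] - m[c];
      v[c] += d * d;
    }
  }
  v /= (double)N;
  vec inv = 1.0 / sqrt(v + eps);
  mat xhat(C, N);
  mat Y(C, N);
  for (uword j = 0; j < N; ++j) {
    const double* x = X.colptr(j);
    double* xh = xhat.colptr(j);
    double* y = Y.colptr(j);
    for (uword c = 0; c < C; ++c) {
      xh[c] = (x[c] - m[c]) * inv[c];
      y[c] = gamma[c] * xh[c] + beta[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv,
                            Rcpp::Named("m") = m,
                            Rcpp::Named("v") = v);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
Rcpp::List bn_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                      const arma::vec& inv, const arma::vec& gamma) {
  const uword C = dY.n_rows, N = dY.n_cols;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (uword j = 0; j < N; ++j) {
    const double* dy = dY.colptr(j);
    const double* xh = xhat.colptr(j);
    for (uword c = 0; c < C; ++c) {
      dgamma[c] += dy[c] * xh[c];
      dbeta[c] += dy[c];
    }
  }
  vec m1 = dbeta % (gamma / (double)N);      // sum(dxhat) * g / N
  vec m2 = dgamma % (gamma / (double)N);     // sum(dxhat*xhat) * g / N
  mat dX(C, N);
  for (uword j = 0; j < N; ++j) {
    const double* dy = dY.colptr(j);
    const double* xh = xhat.colptr(j);
    double* dx = dX.colptr(j);
    for (uword c = 0; c < C; ++c)
      dx[c] = inv[c] * (dy[c] * gamma[c] - m1[c] - xh[c] * m2[c]);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
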