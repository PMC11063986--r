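// Low-level numerical kernels: 1D convolution (same padding) with its
// gradients, width-w max pooling at stride 1, and one explicit diffusion
// step on a 3D lattice.
//
// Activations are cubes in time-major layout (time x channels x instances),
// so each channel of each instance is a contiguous column and im2col reduces
// to contiguous block copies. Convolution weights are (C_in * k) x C_out
// matrices with row index c * k + j for input channel c, tap j; the whole
// batch is one GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unroll the batch into a (T*N) x (C_in*k) matrix (row n*T + t).
static arma::mat im2col_batch(const arma::cube& X, const int k,
                              const int pad_left) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  arma::mat col(T * N, C * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const int off = j - pad_left;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      double* dst = col.colptr(c * k + j);
      for (int n = 0; n < N; ++n) {
        const double* src = X.slice_colptr(n, c);
        std::copy(src + t0 + off, src + t1 + off, dst + n * T + t0);
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, const int k) {
  const int T = X.n_rows, N = X.n_slices, C_out = W.n_cols;
  arma::mat Ymat;
  if (k == 1) {
    arma::cube Y(T, C_out, N);
    for (int n = 0; n < N; ++n)
      Y.slice(n) = X.slice(n) * W;
    for (int c = 0; c < C_out; ++c)
      for (int n = 0; n < N; ++n) {
        double* p = Y.slice_colptr(n, c);
        for (int t = 0; t < T; ++t) p[t] += b[c];
      }
    return Y;
  }
  Ymat = im2col_batch(X, k, (k - 1) / 2) * W;  // (T*N) x C_out
  arma::cube Y(T, C_out, N);
  for (int c = 0; c < C_out; ++c) {
    const double* src = Ymat.colptr(c);
    for (int n = 0; n < N; ++n) {
      double* dst = Y.slice_colptr(n, c);
      for (int t = 0; t < T; ++t) dst[t] = src[n * T + t] + b[c];
    }
  }
  return Y;
}

// Gather a (T*N) x C cube into matrix form with row n*T + t.
static arma::mat cube_to_rows(const arma::cube& X) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  arma::mat M(T * N, C);
  for (int c = 0; c < C; ++c) {
    double* dst = M.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* src = X.slice_colptr(n, c);
      std::copy(src, src + T, dst + n * T);
    }
  }
  return M;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& X, const arma::mat& W,
                    const arma::cube& dY, const int k) {
  const int T = X.n_rows, C_in = X.n_cols, N = X.n_slices;
  arma::cube dX(T, C_in, N, arma::fill::zeros);
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(W.n_cols, arma::fill::zeros);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      dW += X.slice(n).t() * dY.slice(n);
      db += arma::sum(dY.slice(n), 0).t();
      dX.slice(n) = dY.slice(n) * W.t();
    }
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  const int pad_left = (k - 1) / 2;
  arma::mat col = im2col_batch(X, k, pad_left);
  arma::mat dYmat = cube_to_rows(dY);
  dW = col.t() * dYmat;
  db = arma::sum(dYmat, 0).t();
  arma::mat dcol = dYmat * W.t();  // (T*N) x (C_in*k)
  // col2im: scatter-add the unrolled gradient back onto the input
  for (int c = 0; c < C_in; ++c) {
    for (int j = 0; j < k; ++j) {
      const int off = j - pad_left;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      const double* src = dcol.colptr(c * k + j);
      for (int n = 0; n < N; ++n) {
        double* dst = dX.slice_colptr(n, c);
        const double* s = src + n * T + t0;
        double* d = dst + t0 + off;
        for (int t = 0; t < t1 - t0; ++t) d[t] += s[t];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool1d_fwd_cpp(const arma::cube& X, const int w) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int pad = (w - 1) / 2;
  arma::cube Y(T, C, N);
  arma::icube idx(T, C, N);  // argmax time index, first maximum on ties
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* x = X.slice_colptr(n, c);
      double* y = Y.slice_colptr(n, c);
      for (int t = 0; t < T; ++t) {
        const int lo = std::max(0, t - pad);
        const int hi = std::min(T - 1, t + w - 1 - pad);
        double best = x[lo];
        int besti = lo;
        for (int tt = lo + 1; tt <= hi; ++tt)
          if (x[tt] > best) { best = x[tt]; besti = tt; }
        y[t] = best;
        idx(t, c, n) = besti;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool1d_bwd_cpp(const arma::icube& idx, const arma::cube& dY) {
  const int T = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  arma::cube dX(T, C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dx = dX.slice_colptr(n, c);
      const double* dy = dY.slice_colptr(n, c);
      for (int t = 0; t < T; ++t) dx[idx(t, c, n)] += dy[t];
    }
  return dX;
}

// One explicit finite-difference step of du/dt = D lap(u) on a 3D lattice
// (unit spacing), 6-neighbour stencil, zero-flux (reflecting) boundaries.
// [[Rcpp::export]]
arma::cube diffuse_step_cpp(const arma::cube& U, const double D,
                            const double dt) {
  const int nx = U.n_rows, ny = U.n_cols, nz = U.n_slices;
  arma::cube V(nx, ny, nz);
  const double a = D * dt;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const double u = U(x, y, z);
        double lap = 0.0;
        if (x > 0)      lap += U(x - 1, y, z) - u;
        if (x < nx - 1) lap += U(x + 1, y, z) - u;
        if (y > 0)      lap += U(x, y - 1, z) - u;
        if (y < ny - 1) lap += U(x, y + 1, z) - u;
        if (z > 0)      lap += U(x, y, z - 1) - u;
        if (z < nz - 1) lap += U(x, y, z + 1) - u;
        V(x, y, z) = u + a * lap;
      }
    }
  }
  return V;
}
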