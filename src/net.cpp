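// Whole-network forward/backward/Adam for the inception-style 1D CNN.
// Mirrors the R reference implementation in R/net.R exactly (same parameter
// structure, same update rule); exists because minibatch training is the
// hot loop. Layout conventions match layers.cpp: activations are
// (time x channels x instances) cubes, conv weights (C_in*k) x C_out.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::icube;

#ifdef __GLIBC__
// The minibatch loop allocates and frees large im2col buffers every step;
// keep them on the heap (and keep the heap) instead of round-tripping pages
// through mmap/munmap, which otherwise dominates wall time with page faults.
static const bool malloc_tuned = [] {
  mallopt(M_MMAP_THRESHOLD, 128 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return true;
}();
#endif

// Per-slice im2col into a caller-provided (T x C*k) buffer: the buffer is
// small enough to stay cache-resident, so convolution never materializes a
// whole-batch unrolled matrix.
static void im2col_slice(const cube& X, const int n, const int k,
                         const int pad_left, mat& col) {
  const int T = X.n_rows, C = X.n_cols;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      const int off = j - pad_left;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      double* dst = col.colptr(c * k + j);
      if (t0 > 0) std::fill(dst, dst + t0, 0.0);
      if (t1 < T) std::fill(dst + t1, dst + T, 0.0);
      if (t1 > t0) {
        const double* src = X.slice_colptr(n, c);
        std::copy(src + t0 + off, src + t1 + off, dst + t0);
      }
    }
}

static cube conv_fwd(const cube& X, const mat& W, const vec& b, const int k) {
  const int T = X.n_rows, N = X.n_slices, C_out = W.n_cols;
  cube Y(T, C_out, N);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      Y.slice(n) = X.slice(n) * W;
      Y.slice(n).each_row() += b.t();
    }
    return Y;
  }
  mat col(T, X.n_cols * k);
  for (int n = 0; n < N; ++n) {
    im2col_slice(X, n, k, (k - 1) / 2, col);
    Y.slice(n) = col * W;
    Y.slice(n).each_row() += b.t();
  }
  return Y;
}

// Backward of conv_fwd; accumulates dW, db; returns dX.
static cube conv_bwd(const cube& X, const mat& W, const cube& dY, const int k,
                     mat& dW, vec& db) {
  const int T = X.n_rows, C_in = X.n_cols, N = X.n_slices;
  cube dX(T, C_in, N, arma::fill::zeros);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      dW += X.slice(n).t() * dY.slice(n);
      db += arma::sum(dY.slice(n), 0).t();
      dX.slice(n) = dY.slice(n) * W.t();
    }
    return dX;
  }
  const int pad_left = (k - 1) / 2;
  mat col(T, C_in * k);
  mat dcol(T, C_in * k);
  for (int n = 0; n < N; ++n) {
    im2col_slice(X, n, k, pad_left, col);
    dW += col.t() * dY.slice(n);
    db += arma::sum(dY.slice(n), 0).t();
    dcol = dY.slice(n) * W.t();
    // col2im: fold the unrolled gradient back onto the input slice
    for (int c = 0; c < C_in; ++c)
      for (int j = 0; j < k; ++j) {
        const int off = j - pad_left;
        const int t0 = std::max(0, -off);
        const int t1 = std::min(T, T - off);
        if (t1 <= t0) continue;
        const double* s = dcol.colptr(c * k + j) + t0;
        double* d = dX.slice_colptr(n, c) + t0 + off;
        for (int t = 0; t < t1 - t0; ++t) d[t] += s[t];
      }
  }
  return dX;
}

static void maxpool_fwd(const cube& X, const int w, cube& Y, icube& idx) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int pad = (w - 1) / 2;
  Y.set_size(T, C, N);
  idx.set_size(T, C, N);
  for (int n = 0; n < N; ++n)
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

struct BlockP {
  mat Wb; vec bb;
  std::vector<mat> Wc; std::vector<vec> bc;
  mat Wp; vec bp;
  bool res = false; mat Wr; vec br;
};

struct NetP {
  std::vector<BlockP> blocks;
  mat Wout; vec bout;
};

static NetP parse_params(const List& params) {
  NetP P;
  List bl = params["blocks"];
  for (int i = 0; i < bl.size(); ++i) {
    List b = bl[i];
    BlockP B;
    B.Wb = as<mat>(b["Wb"]); B.bb = as<vec>(b["bb"]);
    List conv = b["conv"];
    for (int j = 0; j < conv.size(); ++j) {
      List cj = conv[j];
      B.Wc.push_back(as<mat>(cj["W"]));
      B.bc.push_back(as<vec>(cj["b"]));
    }
    B.Wp = as<mat>(b["Wp"]); B.bp = as<vec>(b["bp"]);
    if (b.containsElementNamed("Wr")) {
      B.res = true;
      B.Wr = as<mat>(b["Wr"]); B.br = as<vec>(b["br"]);
    }
    P.blocks.push_back(std::move(B));
  }
  P.Wout = as<mat>(params["Wout"]);
  P.bout = as<vec>(params["bout"]);
  return P;
}

static List unparse_params(const NetP& P) {
  List bl(P.blocks.size());
  for (size_t i = 0; i < P.blocks.size(); ++i) {
    const BlockP& B = P.blocks[i];
    List conv(B.Wc.size());
    for (size_t j = 0; j < B.Wc.size(); ++j)
      conv[j] = List::create(_["W"] = B.Wc[j], _["b"] = B.bc[j]);
    List b = List::create(_["Wb"] = B.Wb, _["bb"] = B.bb, _["conv"] = conv,
                          _["Wp"] = B.Wp, _["bp"] = B.bp);
    if (B.res) { b.push_back(B.Wr, "Wr"); b.push_back(B.br, "br"); }
    bl[i] = b;
  }
  return List::create(_["blocks"] = bl, _["Wout"] = P.Wout,
                      _["bout"] = P.bout);
}

static NetP zero_net(const NetP& P) {
  NetP Z = P;
  for (auto& B : Z.blocks) {
    B.Wb.zeros(); B.bb.zeros();
    for (auto& W : B.Wc) W.zeros();
    for (auto& b : B.bc) b.zeros();
    B.Wp.zeros(); B.bp.zeros();
    if (B.res) { B.Wr.zeros(); B.br.zeros(); }
  }
  Z.Wout.zeros(); Z.bout.zeros();
  return Z;
}

struct Cache {
  cube B, P, S;
  icube pidx;
};

struct FwdOut {
  std::vector<cube> Z;
  std::vector<Cache> caches;
  mat g, logits;
};

static int res_src(const int i, const int residual_every) {
  // 0-based block i draws its shortcut from activation Z[i+1-residual_every]
  return i + 1 - residual_every;
}

static FwdOut net_fwd(const NetP& P, const cube& X,
                      const arma::ivec& kernels, const int filters,
                      const int residual_every, const bool keep) {
  const int depth = P.blocks.size();
  FwdOut F;
  F.Z.resize(depth + 1);
  F.Z[0] = X;
  if (keep) F.caches.resize(depth);
  const int f = filters;
  for (int i = 0; i < depth; ++i) {
    const BlockP& B = P.blocks[i];
    const cube& Zin = F.Z[i];
    cube Bott = conv_fwd(Zin, B.Wb, B.bb, 1);
    const int T = Zin.n_rows, N = Zin.n_slices;
    cube S(T, 4 * f, N);
    for (size_t j = 0; j < kernels.n_elem; ++j)
      S.cols(j * f, (j + 1) * f - 1) =
        conv_fwd(Bott, B.Wc[j], B.bc[j], kernels[j]);
    cube Pool; icube pidx;
    maxpool_fwd(Zin, 3, Pool, pidx);
    S.cols(3 * f, 4 * f - 1) = conv_fwd(Pool, B.Wp, B.bp, 1);
    if (B.res)
      S += conv_fwd(F.Z[res_src(i, residual_every)], B.Wr, B.br, 1);
    cube Zout = S;
    Zout.for_each([](double& v) { if (v < 0) v = 0; });
    F.Z[i + 1] = std::move(Zout);
    if (keep) {
      F.caches[i].B = std::move(Bott);
      F.caches[i].P = std::move(Pool);
      F.caches[i].pidx = std::move(pidx);
      F.caches[i].S = std::move(S);
    }
  }
  const cube& A = F.Z[depth];
  const int N = A.n_slices;
  F.g.set_size(A.n_cols, N);
  for (int n = 0; n < N; ++n)
    F.g.col(n) = arma::mean(A.slice(n), 0).t();
  F.logits = P.Wout * F.g;
  F.logits.each_col() += P.bout;
  return F;
}

static mat softmax_cols(mat L) {
  L.each_row() -= arma::max(L, 0);
  mat E = arma::exp(L);
  E.each_row() /= arma::sum(E, 0);
  return E;
}

// Loss and full gradient for one batch; G accumulates in place (caller
// zeroes it beforehand).
static double net_lossgrad(const NetP& P, const cube& X, const mat& Y,
                           const arma::ivec& kernels, const int filters,
                           const int residual_every, NetP& G) {
  FwdOut F = net_fwd(P, X, kernels, filters, residual_every, true);
  const int depth = P.blocks.size();
  const int N = F.logits.n_cols;
  const int T = X.n_rows;
  mat Pr = softmax_cols(F.logits);
  double loss = 0.0;
  for (int n = 0; n < N; ++n)
    loss -= std::log(std::max(arma::dot(Y.col(n), Pr.col(n)), 1e-12));
  loss /= N;
  mat dlogits = (Pr - Y) / N;
  G.Wout += dlogits * F.g.t();
  G.bout += arma::sum(dlogits, 1);
  mat dg = P.Wout.t() * dlogits;          // M x N
  const int f = filters;
  std::vector<cube> dZ(depth + 1);
  dZ[depth].set_size(T, dg.n_rows, N);
  for (int n = 0; n < N; ++n)
    dZ[depth].slice(n) = arma::repmat(dg.col(n).t() / T, T, 1);
  for (int i = depth - 1; i >= 0; --i) {
    const BlockP& B = P.blocks[i];
    BlockP& Gb = G.blocks[i];
    Cache& C = F.caches[i];
    cube dS = dZ[i + 1];
    // ReLU gate on the pre-activation
    const double* s = C.S.memptr();
    double* d = dS.memptr();
    for (size_t q = 0; q < dS.n_elem; ++q) if (s[q] <= 0) d[q] = 0;
    if (B.res) {
      const int src = i + 1 - residual_every;
      cube dR = conv_bwd(F.Z[src], B.Wr, dS, 1, Gb.Wr, Gb.br);
      if (dZ[src].n_elem == 0) dZ[src] = dR; else dZ[src] += dR;
    }
    cube dB;
    for (size_t j = 0; j < kernels.n_elem; ++j) {
      cube dCj = dS.cols(j * f, (j + 1) * f - 1);
      cube dBj = conv_bwd(C.B, B.Wc[j], dCj, kernels[j],
                          Gb.Wc[j], Gb.bc[j]);
      if (dB.n_elem == 0) dB = std::move(dBj); else dB += dBj;
    }
    cube dQ = dS.cols(3 * f, 4 * f - 1);
    cube dP = conv_bwd(C.P, B.Wp, dQ, 1, Gb.Wp, Gb.bp);
    // route pooled gradient through the argmax
    cube dZin(X.n_rows, F.Z[i].n_cols, N, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
      for (size_t c = 0; c < dP.n_cols; ++c) {
        double* dx = dZin.slice_colptr(n, c);
        const double* dy = dP.slice_colptr(n, c);
        for (int t = 0; t < T; ++t) dx[C.pidx(t, c, n)] += dy[t];
      }
    dZin += conv_bwd(F.Z[i], B.Wb, dB, 1, Gb.Wb, Gb.bb);
    if (dZ[i].n_elem == 0) dZ[i] = std::move(dZin); else dZ[i] += dZin;
  }
  return loss;
}

// [[Rcpp::export]]
List net_fwd_cpp(const List& params, const arma::cube& X,
                 const arma::ivec& kernel_lengths, const int filters,
                 const int residual_every, const bool want_A) {
  NetP P = parse_params(params);
  FwdOut F = net_fwd(P, X, kernel_lengths, filters, residual_every, false);
  if (want_A)
    return List::create(_["logits"] = F.logits, _["A"] = F.Z.back());
  return List::create(_["logits"] = F.logits);
}

// [[Rcpp::export]]
List net_lossgrad_cpp(const List& params, const arma::cube& X,
                      const arma::mat& Y, const arma::ivec& kernel_lengths,
                      const int filters, const int residual_every) {
  NetP P = parse_params(params);
  NetP G = zero_net(P);
  double loss = net_lossgrad(P, X, Y, kernel_lengths, filters,
                             residual_every, G);
  return List::create(_["loss"] = loss, _["grads"] = unparse_params(G));
}

// Adam over the whole parameter struct, bias-corrected, one shared step
// counter; identical to the R reference update.
struct Adam {
  NetP m, v;
  long t = 0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void upd1(mat& p, const mat& g, mat& m_, mat& v_, const double lr) {
    m_ = b1 * m_ + (1 - b1) * g;
    v_ = b2 * v_ + (1 - b2) * (g % g);
    p -= lr * (m_ / (1 - std::pow(b1, t))) /
         (arma::sqrt(v_ / (1 - std::pow(b2, t))) + eps);
  }
  void upd1(vec& p, const vec& g, vec& m_, vec& v_, const double lr) {
    m_ = b1 * m_ + (1 - b1) * g;
    v_ = b2 * v_ + (1 - b2) * (g % g);
    p -= lr * (m_ / (1 - std::pow(b1, t))) /
         (arma::sqrt(v_ / (1 - std::pow(b2, t))) + eps);
  }
  void step(NetP& P, const NetP& G, const double lr) {
    ++t;
    for (size_t i = 0; i < P.blocks.size(); ++i) {
      BlockP& p = P.blocks[i]; const BlockP& g = G.blocks[i];
      BlockP& mm = m.blocks[i]; BlockP& vv = v.blocks[i];
      upd1(p.Wb, g.Wb, mm.Wb, vv.Wb, lr);
      upd1(p.bb, g.bb, mm.bb, vv.bb, lr);
      for (size_t j = 0; j < p.Wc.size(); ++j) {
        upd1(p.Wc[j], g.Wc[j], mm.Wc[j], vv.Wc[j], lr);
        upd1(p.bc[j], g.bc[j], mm.bc[j], vv.bc[j], lr);
      }
      upd1(p.Wp, g.Wp, mm.Wp, vv.Wp, lr);
      upd1(p.bp, g.bp, mm.bp, vv.bp, lr);
      if (p.res) {
        upd1(p.Wr, g.Wr, mm.Wr, vv.Wr, lr);
        upd1(p.br, g.br, mm.br, vv.br, lr);
      }
    }
    upd1(P.Wout, G.Wout, m.Wout, v.Wout, lr);
    upd1(P.bout, G.bout, m.bout, v.bout, lr);
  }
};

// Fisher-Yates permutation driven by R's RNG (so training is reproducible
// under set.seed on the R side).
static arma::uvec r_permutation(const int n) {
  arma::uvec p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// [[Rcpp::export]]
List net_train_cpp(const List& params, const arma::cube& X,
                   const arma::mat& Y, const arma::ivec& kernel_lengths,
                   const int filters, const int residual_every,
                   const int epochs, const int batch_size, const double lr0,
                   const int lr_patience, const double lr_factor,
                   const double lr_min) {
  NetP P = parse_params(params);
  Adam opt;
  opt.m = zero_net(P);
  opt.v = zero_net(P);
  const int n = X.n_slices;
  const int T = X.n_rows, C = X.n_cols;
  arma::vec history(epochs);
  double lr = lr0, best = arma::datum::inf;
  int stall = 0;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    arma::uvec perm = r_permutation(n);
    double tot = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      cube Xb(T, C, stop - start);
      mat Yb(Y.n_rows, stop - start);
      for (int q = start; q < stop; ++q) {
        Xb.slice(q - start) = X.slice(perm[q]);
        Yb.col(q - start) = Y.col(perm[q]);
      }
      NetP G = zero_net(P);
      tot += net_lossgrad(P, Xb, Yb, kernel_lengths, filters,
                          residual_every, G);
      opt.step(P, G, lr);
      ++nb;
    }
    history[epoch] = tot / nb;
    if (history[epoch] < best - 1e-4) { best = history[epoch]; stall = 0; }
    else ++stall;
    if (stall >= lr_patience && lr > lr_min) {
      lr = std::max(lr_min, lr * lr_factor);
      stall = 0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = unparse_params(P),
                      _["history"] = history);
}
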