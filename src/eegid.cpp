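// Core numerical kernels: IIR filtering and the 1D-CNN classifier.
// Single precision throughout the network; convolutions are expressed as
// kernel-tap-shifted SGEMM calls (BLAS) and the batch-norm/ReLU stages as
// fused single passes, which keeps cross-validated training of the
// channel-reduction study tractable on one CPU.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>

using namespace Rcpp;
using namespace arma;

// Single-precision GEMM through armadillo's BLAS translation layer.
static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  blas_int m_ = m, n_ = n, k_ = k, lda_ = lda, ldb_ = ldb, ldc_ = ldc;
  arma::blas::gemm<float>(&ta, &tb, &m_, &n_, &k_, &alpha, A, &lda_, B,
                          &ldb_, &beta, C, &ldc_);
}

// ---------------------------------------------------------------------
// IIR filter, direct form II transposed, with explicit initial state.
// ---------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i < n; ++i) { bb[i] /= a0; aa[i] /= a0; }
  std::vector<double> z(std::max(n - 1, 1), 0.0);
  for (int i = 0; i < zi.size() && i < n - 1; ++i) z[i] = zi[i];
  int N = x.size();
  NumericVector y(N);
  for (int t = 0; t < N; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int j = 0; j + 2 < n; ++j)
      z[j] = bb[j + 1] * xt + z[j + 1] - aa[j + 1] * yt;
    if (n > 1) z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// ---------------------------------------------------------------------
// 1D-CNN: [conv(k, stride 1, same) -> batchnorm -> ReLU
//          -> maxpool(2, stride 2)] x blocks
//         -> global average pooling -> fully connected -> softmax
// ---------------------------------------------------------------------

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

struct Block {
  fmat W;                 // K x (Cin * kernel), tap j in cols [j*Cin, ...)
  fvec b, gamma, beta, rmean, rvar;
};

struct Net {
  std::vector<Block> blocks;
  fmat Wfc;               // n_classes x K_last
  fvec bfc;
  int n_channels, n_classes, kernel;
};

static Net net_from_list(const List& wts) {
  Net net;
  List meta = wts["meta"];
  net.n_channels = as<int>(meta["n_channels"]);
  net.n_classes = as<int>(meta["n_classes"]);
  net.kernel = as<int>(meta["kernel"]);
  List blocks = wts["blocks"];
  for (int i = 0; i < blocks.size(); ++i) {
    List bl = blocks[i];
    Block b;
    b.W = conv_to<fmat>::from(as<mat>(bl["W"]));
    b.b = conv_to<fvec>::from(as<vec>(bl["b"]));
    b.gamma = conv_to<fvec>::from(as<vec>(bl["gamma"]));
    b.beta = conv_to<fvec>::from(as<vec>(bl["beta"]));
    b.rmean = conv_to<fvec>::from(as<vec>(bl["rmean"]));
    b.rvar = conv_to<fvec>::from(as<vec>(bl["rvar"]));
    net.blocks.push_back(b);
  }
  List fc = wts["fc"];
  net.Wfc = conv_to<fmat>::from(as<mat>(fc["W"]));
  net.bfc = conv_to<fvec>::from(as<vec>(fc["b"]));
  return net;
}

static List net_to_list(const Net& net) {
  List blocks(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    const Block& b = net.blocks[i];
    blocks[i] = List::create(
      _["W"] = conv_to<mat>::from(b.W), _["b"] = conv_to<vec>::from(b.b),
      _["gamma"] = conv_to<vec>::from(b.gamma),
      _["beta"] = conv_to<vec>::from(b.beta),
      _["rmean"] = conv_to<vec>::from(b.rmean),
      _["rvar"] = conv_to<vec>::from(b.rvar));
  }
  return List::create(
    _["blocks"] = blocks,
    _["fc"] = List::create(_["W"] = conv_to<mat>::from(net.Wfc),
                           _["b"] = conv_to<vec>::from(net.bfc)),
    _["meta"] = List::create(_["n_channels"] = net.n_channels,
                             _["n_classes"] = net.n_classes,
                             _["kernel"] = net.kernel));
}

// [[Rcpp::export]]
List cnn_init_cpp(int n_channels, int n_classes, IntegerVector filters,
                  int kernel, int seed) {
  Net net;
  net.n_channels = n_channels;
  net.n_classes = n_classes;
  net.kernel = kernel;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  int cin = n_channels;
  for (int i = 0; i < filters.size(); ++i) {
    int k = filters[i];
    Block b;
    float sd = std::sqrt(2.0f / (cin * kernel));  // He initialization
    b.W.set_size(k, cin * kernel);
    for (uword j = 0; j < b.W.n_elem; ++j) b.W(j) = sd * gauss(rng);
    b.b.zeros(k);
    b.gamma.ones(k);
    b.beta.zeros(k);
    b.rmean.zeros(k);
    b.rvar.ones(k);
    net.blocks.push_back(b);
    cin = k;
  }
  float sd = std::sqrt(2.0f / cin);
  net.Wfc.set_size(n_classes, cin);
  for (uword j = 0; j < net.Wfc.n_elem; ++j) net.Wfc(j) = sd * gauss(rng);
  net.bfc.zeros(n_classes);
  return net_to_list(net);
}

// Convolution forward: Z (K, B*L) += per-tap W_j * X shifted by j - pad,
// sample blocks of length L kept independent ("same" zero padding).
static void conv_forward(const fmat& W, const fvec& bias, const fmat& X,
                         int B, int L, int k, fmat& Z) {
  int C = X.n_rows, K = W.n_rows, pad = (k - 1) / 2;
  Z.set_size(K, X.n_cols);
  for (uword c = 0; c < Z.n_cols; ++c)
    std::memcpy(Z.colptr(c), bias.memptr(), K * sizeof(float));
  for (int s = 0; s < B; ++s) {
    const float* Xs = X.colptr((size_t)s * L);
    float* Zs = Z.colptr((size_t)s * L);
    for (int j = 0; j < k; ++j) {
      int off = j - pad;
      int t0 = std::max(0, -off), t1 = std::min(L - 1, L - 1 - off);
      int n = t1 - t0 + 1;
      if (n <= 0) continue;
      sgemm('N', 'N', K, n, C, 1.0f, W.colptr((size_t)j * C), K,
            Xs + (size_t)(t0 + off) * C, C, 1.0f, Zs + (size_t)t0 * K, K);
    }
  }
}

// dX = sum_j W_j^T * dZ shifted; dW_j += dZ * X^T shifted; db += rowsum(dZ)
static void conv_backward(const fmat& W, const fmat& X, const fmat& dZ,
                          int B, int L, int k, fmat& dW, fvec& db,
                          fmat* dX) {
  int C = X.n_rows, K = W.n_rows, pad = (k - 1) / 2;
  dW.zeros(K, C * k);
  db.zeros(K);
  for (uword c = 0; c < dZ.n_cols; ++c) {
    const float* p = dZ.colptr(c);
    for (int r = 0; r < K; ++r) db[r] += p[r];
  }
  if (dX) dX->zeros(C, X.n_cols);
  for (int s = 0; s < B; ++s) {
    const float* Xs = X.colptr((size_t)s * L);
    const float* dZs = dZ.colptr((size_t)s * L);
    for (int j = 0; j < k; ++j) {
      int off = j - pad;
      int t0 = std::max(0, -off), t1 = std::min(L - 1, L - 1 - off);
      int n = t1 - t0 + 1;
      if (n <= 0) continue;
      sgemm('N', 'T', K, C, n, 1.0f, dZs + (size_t)t0 * K, K,
            Xs + (size_t)(t0 + off) * C, C, 1.0f, dW.colptr((size_t)j * C),
            K);
      if (dX)
        sgemm('T', 'N', C, n, K, 1.0f, W.colptr((size_t)j * C), K,
              dZs + (size_t)t0 * K, K, 1.0f,
              dX->colptr((size_t)s * L) + (size_t)(t0 + off) * C, C);
    }
  }
}

struct BlockCache {
  fmat Z;                      // pre-batchnorm activations
  fmat act;                    // post-ReLU activations
  fmat pool;                   // pooled output (input to next stage)
  Mat<unsigned char> argmax;   // pooling winner offset (0/1)
  fvec mu, invstd;
  int L_in, L_out;
};

// One block forward. X: (Cin, B*L). Fills cache; returns pooled (K, B*L/2).
static void block_forward(Block& bl, const fmat& X, int B, int L, int kernel,
                          bool train, bool need_cache, BlockCache& cache) {
  int K = bl.W.n_rows;
  conv_forward(bl.W, bl.b, X, B, L, kernel, cache.Z);
  fmat& Z = cache.Z;
  size_t M = Z.n_cols;
  fvec mu(K), var(K);
  if (train) {
    std::vector<double> sum(K, 0.0), sq(K, 0.0);
    for (size_t c = 0; c < M; ++c) {
      const float* p = Z.colptr(c);
      for (int r = 0; r < K; ++r) { sum[r] += p[r]; sq[r] += (double)p[r] * p[r]; }
    }
    for (int r = 0; r < K; ++r) {
      mu[r] = (float)(sum[r] / M);
      var[r] = (float)std::max(sq[r] / M - (double)mu[r] * mu[r], 0.0);
    }
    bl.rmean = (1.0f - BN_MOMENTUM) * bl.rmean + BN_MOMENTUM * mu;
    bl.rvar = (1.0f - BN_MOMENTUM) * bl.rvar + BN_MOMENTUM * var;
  } else {
    mu = bl.rmean;
    var = bl.rvar;
  }
  fvec invstd = 1.0f / sqrt(var + BN_EPS);
  // fused normalize + scale/shift + ReLU
  fvec scale = bl.gamma % invstd;
  fvec shift = bl.beta - mu % scale;
  cache.act.set_size(K, M);
  for (size_t c = 0; c < M; ++c) {
    const float* z = Z.colptr(c);
    float* a = cache.act.colptr(c);
    const float* sc = scale.memptr();
    const float* sh = shift.memptr();
    for (int r = 0; r < K; ++r) {
      float v = z[r] * sc[r] + sh[r];
      a[r] = v > 0.0f ? v : 0.0f;
    }
  }
  // max pooling 2 / stride 2 (trailing odd column dropped)
  int Lp = L / 2;
  cache.pool.set_size(K, (size_t)B * Lp);
  if (need_cache) cache.argmax.set_size(K, (size_t)B * Lp);
  for (int s = 0; s < B; ++s) {
    for (int p = 0; p < Lp; ++p) {
      const float* c0 = cache.act.colptr((size_t)s * L + 2 * p);
      const float* c1 = c0 + K;
      float* o = cache.pool.colptr((size_t)s * Lp + p);
      if (need_cache) {
        unsigned char* m = cache.argmax.colptr((size_t)s * Lp + p);
        for (int r = 0; r < K; ++r) {
          if (c0[r] >= c1[r]) { o[r] = c0[r]; m[r] = 0; }
          else { o[r] = c1[r]; m[r] = 1; }
        }
      } else {
        for (int r = 0; r < K; ++r)
          o[r] = c0[r] >= c1[r] ? c0[r] : c1[r];
      }
    }
  }
  cache.mu = mu;
  cache.invstd = invstd;
  cache.L_in = L;
  cache.L_out = Lp;
  if (!need_cache) { cache.Z.reset(); }
}

// Forward through all blocks plus global average pooling -> (K_last, B).
static fmat forward_blocks(Net& net, const fmat& X, int B, int L0, bool train,
                           std::vector<BlockCache>* caches) {
  std::vector<BlockCache> local;
  std::vector<BlockCache>& cc = caches ? *caches : local;
  cc.resize(net.blocks.size());
  const fmat* cur = &X;
  int L = L0;
  for (size_t bi = 0; bi < net.blocks.size(); ++bi) {
    block_forward(net.blocks[bi], *cur, B, L, net.kernel, train,
                  caches != nullptr, cc[bi]);
    if (!caches && bi > 0) cc[bi - 1].pool.reset();
    cur = &cc[bi].pool;
    L = cc[bi].L_out;
  }
  int K = cur->n_rows;
  fmat G(K, B);
  for (int s = 0; s < B; ++s)
    G.col(s) = mean(cur->cols((size_t)s * L, (size_t)(s + 1) * L - 1), 1);
  return G;
}

static fmat softmax_cols(fmat logits) {
  logits.each_row() -= max(logits, 0);
  logits = exp(logits);
  frowvec s = sum(logits, 0);
  logits.each_row() /= s;
  return logits;
}

struct Adam {
  std::vector<fmat*> params;
  std::vector<fmat> m, v;
  float lr, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void add(fmat* p) {
    params.push_back(p);
    m.push_back(fmat(p->n_rows, p->n_cols, fill::zeros));
    v.push_back(fmat(p->n_rows, p->n_cols, fill::zeros));
  }
  void step(const std::vector<fmat>& grads) {
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * grads[i];
      v[i] = b2 * v[i] + (1.0f - b2) * square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// Assemble (C, B*L) batch matrix from selected slices of the data cube.
static fmat gather_batch(const fcube& X, const std::vector<int>& idx,
                         size_t from, size_t to) {
  int C = X.n_rows, L = X.n_cols;
  int B = to - from;
  fmat out(C, (size_t)B * L);
  for (int i = 0; i < B; ++i)
    std::memcpy(out.colptr((size_t)i * L), X.slice(idx[from + i]).memptr(),
                (size_t)C * L * sizeof(float));
  return out;
}

// Mean cross-entropy loss and accuracy in inference mode.
static void evaluate(Net& net, const fcube& X, const IntegerVector& y,
                     int batch, double* loss_out, double* acc_out) {
  int n = X.n_slices, L = X.n_cols;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double loss = 0.0;
  int correct = 0;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    fmat Xb = gather_batch(X, idx, s, e);
    fmat G = forward_blocks(net, Xb, e - s, L, false, nullptr);
    fmat logits = net.Wfc * G;
    logits.each_col() += net.bfc;
    fmat P = softmax_cols(logits);
    for (int i = 0; i < e - s; ++i) {
      int yi = y[s + i];
      loss += -std::log(std::max(P(yi, i), 1e-12f));
      if ((int)P.col(i).index_max() == yi) ++correct;
    }
  }
  *loss_out = loss / n;
  *acc_out = (double)correct / n;
}

// One mini-batch: forward in training mode, backward, gradients for every
// parameter in optimizer order (per block W, b, gamma, beta; then FC W, b).
static void train_batch(Net& net, const fmat& Xb, int B, int L,
                        const std::vector<int>& yb,
                        std::vector<fmat>& grads, double* loss_sum,
                        int* correct) {
  int nb = net.blocks.size();
  std::vector<BlockCache> caches;
  fmat G = forward_blocks(net, Xb, B, L, true, &caches);
  fmat logits = net.Wfc * G;
  logits.each_col() += net.bfc;
  fmat P = softmax_cols(logits);

  fmat dlogits = P;
  for (int i = 0; i < B; ++i) {
    int yi = yb[i];
    *loss_sum += -std::log(std::max(P(yi, i), 1e-12f));
    if ((int)P.col(i).index_max() == yi) ++(*correct);
    dlogits(yi, i) -= 1.0f;
  }
  dlogits /= (float)B;

  size_t gi = 4 * (size_t)nb;
  grads[gi] = dlogits * G.t();             // dWfc
  grads[gi + 1] = sum(dlogits, 1);         // dbfc
  fmat dG = net.Wfc.t() * dlogits;

  // GAP backward: spread evenly over the final feature-map length
  int Lg = caches.back().L_out;
  fmat dpool(dG.n_rows, (size_t)B * Lg);
  for (int i = 0; i < B; ++i) {
    fvec g = dG.col(i) / (float)Lg;
    for (int p = 0; p < Lg; ++p) dpool.col((size_t)i * Lg + p) = g;
  }

  for (int bi = nb - 1; bi >= 0; --bi) {
    Block& bl = net.blocks[bi];
    BlockCache& c = caches[bi];
    int Li = c.L_in, Lp = c.L_out;
    int K = bl.W.n_rows;
    size_t M = (size_t)B * Li;
    // pool backward + ReLU mask in one scatter pass
    fmat dact(K, M, fill::zeros);
    for (int si = 0; si < B; ++si) {
      for (int p = 0; p < Lp; ++p) {
        const float* dc = dpool.colptr((size_t)si * Lp + p);
        const unsigned char* mm = c.argmax.colptr((size_t)si * Lp + p);
        for (int r = 0; r < K; ++r) {
          size_t col = (size_t)si * Li + 2 * p + mm[r];
          if (c.act(r, col) > 0.0f) dact(r, col) = dc[r];
        }
      }
    }
    // batchnorm backward (xhat recomputed from cached Z)
    float Mf = (float)M;
    fvec dgamma(K, fill::zeros), dbeta(K, fill::zeros);
    for (size_t col = 0; col < M; ++col) {
      const float* d = dact.colptr(col);
      const float* z = c.Z.colptr(col);
      for (int r = 0; r < K; ++r) {
        float xh = (z[r] - c.mu[r]) * c.invstd[r];
        dgamma[r] += d[r] * xh;
        dbeta[r] += d[r];
      }
    }
    fvec k1 = bl.gamma % c.invstd;            // dZ overall scale
    fvec k2 = dbeta / Mf;
    fvec k3 = dgamma / Mf;
    for (size_t col = 0; col < M; ++col) {
      float* d = dact.colptr(col);
      const float* z = c.Z.colptr(col);
      for (int r = 0; r < K; ++r) {
        float xh = (z[r] - c.mu[r]) * c.invstd[r];
        d[r] = k1[r] * (d[r] - k2[r] - xh * k3[r]);
      }
    }
    // conv backward
    const fmat& Xin = bi == 0 ? Xb : caches[bi - 1].pool;
    fmat dW;
    fvec db;
    fmat dX;
    conv_backward(bl.W, Xin, dact, B, Li, net.kernel, dW, db,
                  bi > 0 ? &dX : nullptr);
    grads[4 * (size_t)bi] = std::move(dW);
    grads[4 * (size_t)bi + 1] = db;
    grads[4 * (size_t)bi + 2] = dgamma;
    grads[4 * (size_t)bi + 3] = dbeta;
    if (bi > 0) dpool = std::move(dX);
    c.Z.reset();
    c.act.reset();
  }
}

// [[Rcpp::export]]
List cnn_train_cpp(List wts, arma::cube Xtr, IntegerVector ytr,
                   arma::cube Xval, IntegerVector yval, int epochs,
                   int batch, double lr, int seed, bool verbose) {
  Net net = net_from_list(wts);
  fcube X = conv_to<fcube>::from(Xtr);
  fcube Xv = conv_to<fcube>::from(Xval);
  int n = X.n_slices, L = X.n_cols;
  int nb = net.blocks.size();

  Adam opt;
  opt.lr = (float)lr;
  for (int i = 0; i < nb; ++i) {
    Block& b = net.blocks[i];
    opt.add(&b.W);
    opt.add((fmat*)&b.b);      // fvec shares the fmat layout
    opt.add((fmat*)&b.gamma);
    opt.add((fmat*)&b.beta);
  }
  opt.add(&net.Wfc);
  opt.add((fmat*)&net.bfc);

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  NumericVector h_tr_loss(epochs), h_tr_acc(epochs), h_val_loss(epochs),
      h_val_acc(epochs);
  double best_loss = datum::inf;
  int best_epoch = 0;
  Net best = net;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      int B = e - s;
      fmat Xb = gather_batch(X, idx, s, e);
      std::vector<int> yb(B);
      for (int i = 0; i < B; ++i) yb[i] = ytr[idx[s + i]];
      std::vector<fmat> grads(opt.params.size());
      train_batch(net, Xb, B, L, yb, grads, &ep_loss, &ep_correct);
      opt.step(grads);
    }
    h_tr_loss[ep] = ep_loss / n;
    h_tr_acc[ep] = (double)ep_correct / n;
    double vl, va;
    evaluate(net, Xv, yval, 256, &vl, &va);
    h_val_loss[ep] = vl;
    h_val_acc[ep] = va;
    if (vl < best_loss) {     // strict: first epoch wins ties
      best_loss = vl;
      best_epoch = ep + 1;    // 1-based
      best = net;
    }
    if (verbose)
      Rprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
              ep + 1, h_tr_loss[ep], h_tr_acc[ep], vl, va);
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["weights"] = net_to_list(best),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["train_loss"] = h_tr_loss,
      _["train_acc"] = h_tr_acc, _["val_loss"] = h_val_loss,
      _["val_acc"] = h_val_acc),
    _["best_epoch"] = best_epoch);
}

// Single forward+backward pass in training mode over one batch; exposes
// the loss and every analytic gradient so tests can check them against
// finite differences.
// [[Rcpp::export]]
List cnn_fwdbwd_cpp(List wts, arma::cube Xin, IntegerVector y) {
  Net net = net_from_list(wts);
  fcube X = conv_to<fcube>::from(Xin);
  int n = X.n_slices, L = X.n_cols;
  std::vector<int> idx(n), yb(n);
  for (int i = 0; i < n; ++i) { idx[i] = i; yb[i] = y[i]; }
  fmat Xb = gather_batch(X, idx, 0, n);
  int nb = net.blocks.size();
  std::vector<fmat> grads(4 * nb + 2);
  double loss = 0.0;
  int correct = 0;
  train_batch(net, Xb, n, L, yb, grads, &loss, &correct);
  List out(grads.size());
  for (size_t i = 0; i < grads.size(); ++i)
    out[i] = conv_to<mat>::from(grads[i]);
  return List::create(_["loss"] = loss / n, _["grads"] = out);
}

// Mean training-mode cross-entropy loss over one batch (no updates);
// finite-difference counterpart of cnn_fwdbwd_cpp.
// [[Rcpp::export]]
double cnn_loss_cpp(List wts, arma::cube Xin, IntegerVector y) {
  Net net = net_from_list(wts);
  fcube X = conv_to<fcube>::from(Xin);
  int n = X.n_slices, L = X.n_cols;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  fmat Xb = gather_batch(X, idx, 0, n);
  std::vector<BlockCache> caches;
  fmat G = forward_blocks(net, Xb, n, L, true, &caches);
  fmat logits = net.Wfc * G;
  logits.each_col() += net.bfc;
  fmat P = softmax_cols(logits);
  double loss = 0.0;
  for (int i = 0; i < n; ++i)
    loss += -std::log(std::max(P(y[i], i), 1e-12f));
  return loss / n;
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List wts, arma::cube Xin, int batch) {
  Net net = net_from_list(wts);
  fcube X = conv_to<fcube>::from(Xin);
  int n = X.n_slices, L = X.n_cols;
  mat probs(n, net.n_classes);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    fmat Xb = gather_batch(X, idx, s, e);
    fmat G = forward_blocks(net, Xb, e - s, L, false, nullptr);
    fmat logits = net.Wfc * G;
    logits.each_col() += net.bfc;
    fmat P = softmax_cols(logits);
    for (int i = 0; i < e - s; ++i)
      probs.row(s + i) = conv_to<rowvec>::from(P.col(i).t());
  }
  return probs;
}
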