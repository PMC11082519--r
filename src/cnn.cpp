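// 1-D convolutional classifier over SNP images, single precision.
//
// Architecture: three 1-D convolutions along the locus axis (samples are
// input channels), kernel 3, no bias, each followed by batch
// normalization and ReLU; one max-pooling step (window 2) after the conv
// stack; two dense layers (ReLU, inverted dropout) and a softmax output.
// Trained by minibatch SGD with momentum on categorical cross-entropy,
// with model checkpointing on validation accuracy and early stopping.
//
// Images arrive as raw bytes (0 = major, 1 = minor, 2 = missing); missing
// enters the network as the numeric code -1. All randomness (init,
// shuffling, dropout) comes from R's RNG so results are reproducible
// under set.seed(). Single-threaded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uword;

namespace {

const float BN_EPS = 1e-5f;

struct Config {
  int F1, F2, F3, K, pool, D1, D2, classes;
  int batch, patience, max_epochs;
  float lr, momentum, dropout, bn_momentum;
  int L, C;             // image: L loci x C sample-channels
  int P1, P2, P3, P4, flat;
};

Config read_config(List cfg) {
  Config c;
  IntegerVector f = cfg["conv_filters"];
  c.F1 = f[0]; c.F2 = f[1]; c.F3 = f[2];
  c.K = as<int>(cfg["kernel"]);
  c.pool = as<int>(cfg["pool"]);
  IntegerVector d = cfg["dense_units"];
  c.D1 = d[0]; c.D2 = d[1];
  c.classes = as<int>(cfg["classes"]);
  c.batch = as<int>(cfg["batch_size"]);
  c.patience = as<int>(cfg["patience_epochs"]);
  c.max_epochs = as<int>(cfg["max_epochs"]);
  c.lr = (float)as<double>(cfg["learning_rate"]);
  c.momentum = (float)as<double>(cfg["momentum"]);
  c.dropout = (float)as<double>(cfg["dropout"]);
  c.bn_momentum = (float)as<double>(cfg["bn_momentum"]);
  c.L = as<int>(cfg["n_loci"]);
  c.C = as<int>(cfg["n_samples"]);
  c.P1 = c.L - c.K + 1;
  c.P2 = c.P1 - c.K + 1;
  c.P3 = c.P2 - c.K + 1;
  c.P4 = c.P3 / c.pool;
  if (c.P4 < 1) stop("image has too few loci for this architecture");
  c.flat = c.F3 * c.P4;
  return c;
}

struct Params {
  fmat W1, W2, W3, Wd1, Wd2, Wo;
  fvec g1, b1, g2, b2, g3, b3;
  fvec rm1, rv1, rm2, rv2, rm3, rv3; // running BN stats
  fvec bd1, bd2, bo;
};

List params_to_r(const Params& p) {
  auto M = [](const fmat& x) { return wrap(arma::conv_to<arma::mat>::from(x)); };
  auto V = [](const fvec& x) { return wrap(arma::conv_to<arma::vec>::from(x)); };
  return List::create(
    _["W1"] = M(p.W1), _["W2"] = M(p.W2), _["W3"] = M(p.W3),
    _["Wd1"] = M(p.Wd1), _["Wd2"] = M(p.Wd2), _["Wo"] = M(p.Wo),
    _["g1"] = V(p.g1), _["b1"] = V(p.b1), _["g2"] = V(p.g2),
    _["b2"] = V(p.b2), _["g3"] = V(p.g3), _["b3"] = V(p.b3),
    _["rm1"] = V(p.rm1), _["rv1"] = V(p.rv1), _["rm2"] = V(p.rm2),
    _["rv2"] = V(p.rv2), _["rm3"] = V(p.rm3), _["rv3"] = V(p.rv3),
    _["bd1"] = V(p.bd1), _["bd2"] = V(p.bd2), _["bo"] = V(p.bo));
}

Params params_from_r(List l) {
  Params p;
  auto M = [&](const char* n) {
    return arma::conv_to<fmat>::from(as<arma::mat>(l[n]));
  };
  auto V = [&](const char* n) {
    return arma::conv_to<fvec>::from(as<arma::vec>(l[n]));
  };
  p.W1 = M("W1"); p.W2 = M("W2"); p.W3 = M("W3");
  p.Wd1 = M("Wd1"); p.Wd2 = M("Wd2"); p.Wo = M("Wo");
  p.g1 = V("g1"); p.b1 = V("b1"); p.g2 = V("g2"); p.b2 = V("b2");
  p.g3 = V("g3"); p.b3 = V("b3");
  p.rm1 = V("rm1"); p.rv1 = V("rv1"); p.rm2 = V("rm2"); p.rv2 = V("rv2");
  p.rm3 = V("rm3"); p.rv3 = V("rv3");
  p.bd1 = V("bd1"); p.bd2 = V("bd2"); p.bo = V("bo");
  return p;
}

fmat he_init(int rows, int cols, int fan_in) {
  fmat w(rows, cols);
  float sd = std::sqrt(2.0f / (float)fan_in);
  for (uword i = 0; i < w.n_elem; ++i) w(i) = (float)norm_rand() * sd;
  return w;
}

// gather raw images (bytes, one column per image) into a float matrix of
// im2col patches for the first convolution; 2 decodes to -1 (missing)
void im2col_raw(const RawMatrix& X, const IntegerVector& idx,
                const Config& c, fmat& cols) {
  int B = idx.size();
  cols.set_size(c.K * c.C, (uword)B * c.P1);
  static const float lut[3] = {0.0f, 1.0f, -1.0f};
  for (int b = 0; b < B; ++b) {
    const Rbyte* img = &X(0, idx[b]);
    for (int p = 0; p < c.P1; ++p) {
      float* dst = cols.colptr((uword)b * c.P1 + p);
      const Rbyte* src = img + (size_t)p * c.C; // channel-major layout
      for (int k = 0; k < c.K * c.C; ++k) dst[k] = lut[src[k]];
    }
  }
}

// im2col over an activation map A (F x B*P_in), per-sample blocks
void im2col_act(const fmat& A, int B, int P_in, int K, fmat& cols) {
  int F = A.n_rows, P_out = P_in - K + 1;
  cols.set_size((uword)K * F, (uword)B * P_out);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P_out; ++p) {
      float* dst = cols.colptr((uword)b * P_out + p);
      const float* src = A.colptr((uword)b * P_in + p);
      std::memcpy(dst, src, sizeof(float) * K * F); // columns contiguous
    }
}

// scatter-add of dcols back onto the activation gradient
void col2im_act(const fmat& dcols, int B, int P_in, int K, fmat& dA) {
  int P_out = P_in - K + 1, F = dA.n_rows;
  dA.zeros();
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P_out; ++p) {
      const float* src = dcols.colptr((uword)b * P_out + p);
      float* dst = dA.colptr((uword)b * P_in + p);
      for (int k = 0; k < K * F; ++k) dst[k] += src[k];
    }
}

struct BNCache {
  fvec mu, var, istd;
  fmat zhat;
};

// training-mode batch normalization + affine, caching what backward needs
void bn_forward_train(const fmat& Z, const fvec& g, const fvec& b,
                      fvec& rm, fvec& rv, float mom, BNCache& cache,
                      fmat& out) {
  uword F = Z.n_rows, M = Z.n_cols;
  arma::vec s1(F, arma::fill::zeros), s2(F, arma::fill::zeros);
  for (uword j = 0; j < M; ++j) {
    const float* z = Z.colptr(j);
    for (uword i = 0; i < F; ++i) { s1[i] += z[i]; s2[i] += (double)z[i] * z[i]; }
  }
  cache.mu.set_size(F); cache.var.set_size(F); cache.istd.set_size(F);
  for (uword i = 0; i < F; ++i) {
    double m = s1[i] / M;
    double v = std::max(0.0, s2[i] / M - m * m); // biased, minibatch
    cache.mu[i] = (float)m;
    cache.var[i] = (float)v;
    cache.istd[i] = 1.0f / std::sqrt((float)v + BN_EPS);
  }
  cache.zhat.set_size(F, M);
  out.set_size(F, M);
  for (uword j = 0; j < M; ++j) {
    const float* z = Z.colptr(j);
    float* zh = cache.zhat.colptr(j);
    float* o = out.colptr(j);
    for (uword i = 0; i < F; ++i) {
      float h = (z[i] - cache.mu[i]) * cache.istd[i];
      zh[i] = h;
      o[i] = g[i] * h + b[i];
    }
  }
  rm = mom * rm + (1.0f - mom) * cache.mu;
  rv = mom * rv + (1.0f - mom) * cache.var * ((float)M / std::max(1.0f, (float)M - 1.0f));
}

void bn_forward_infer(fmat& Z, const fvec& g, const fvec& b,
                      const fvec& rm, const fvec& rv) {
  fvec scale = g / arma::sqrt(rv + BN_EPS);
  fvec shift = b - rm % scale;
  Z.each_col() %= scale;
  Z.each_col() += shift;
}

// gradient through batch normalization; overwrites dout with dZ
void bn_backward(fmat& dout, const BNCache& cache, const fvec& g,
                 fvec& dg, fvec& db) {
  uword F = dout.n_rows, M = dout.n_cols;
  arma::vec sg(F, arma::fill::zeros), sb(F, arma::fill::zeros);
  for (uword j = 0; j < M; ++j) {
    const float* d = dout.colptr(j);
    const float* zh = cache.zhat.colptr(j);
    for (uword i = 0; i < F; ++i) { sg[i] += (double)d[i] * zh[i]; sb[i] += d[i]; }
  }
  dg = arma::conv_to<fvec>::from(sg);
  db = arma::conv_to<fvec>::from(sb);
  fvec coef = g % cache.istd / (float)M;
  // dZ = coef * (M*dout - db - zhat*dg)
  for (uword j = 0; j < M; ++j) {
    float* d = dout.colptr(j);
    const float* zh = cache.zhat.colptr(j);
    for (uword i = 0; i < F; ++i)
      d[i] = coef[i] * ((float)M * d[i] - db[i] - zh[i] * dg[i]);
  }
}

void relu_(fmat& x) {
  float* p = x.memptr();
  for (uword i = 0, n = x.n_elem; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero the gradient wherever the activation was clipped by ReLU
void relu_mask(fmat& d, const fmat& act) {
  float* dp = d.memptr();
  const float* ap = act.memptr();
  for (uword i = 0, n = d.n_elem; i < n; ++i) if (ap[i] == 0.0f) dp[i] = 0.0f;
}

void maxpool(const fmat& A, int B, int P_in, int pool, fmat& out,
             arma::umat& argmax) {
  int F = A.n_rows, P_out = P_in / pool;
  out.set_size(F, (uword)B * P_out);
  argmax.set_size(F, (uword)B * P_out);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P_out; ++p) {
      uword oc = (uword)b * P_out + p;
      uword ic = (uword)b * P_in + p * pool;
      for (int f = 0; f < F; ++f) {
        float best = A(f, ic);
        uword bi = ic;
        for (int q = 1; q < pool; ++q)
          if (A(f, ic + q) > best) { best = A(f, ic + q); bi = ic + q; }
        out(f, oc) = best;
        argmax(f, oc) = bi;
      }
    }
}

// per-sample flatten: contiguous (F3 x P4) block becomes one column
void flatten(const fmat& pooled, int B, int per_sample, fmat& out) {
  out.set_size(per_sample, B);
  for (int b = 0; b < B; ++b)
    std::memcpy(out.colptr(b), pooled.colptr((uword)b * (per_sample / pooled.n_rows)),
                sizeof(float) * per_sample);
}

fmat softmax_cols(fmat O) {
  frowvec mx = arma::max(O, 0);
  O.each_row() -= mx;
  O = arma::exp(O);
  frowvec s = arma::sum(O, 0);
  O.each_row() /= s;
  return O;
}

struct FwdCache {
  fmat cols0, cols1, cols2;
  fmat Z1, A1, Z2, A2, Z3, A3;
  BNCache bn1, bn2, bn3;
  fmat pooled, flat, H1, H2, O, probs;
  fmat mask1, mask2;
  arma::umat argmax;
};

// full training-mode forward pass over a minibatch given by idx
void forward_train(Params& p, const Config& c, const RawMatrix& X,
                   const IntegerVector& idx, float bn_mom, FwdCache& f) {
  int B = idx.size();
  im2col_raw(X, idx, c, f.cols0);
  f.Z1 = p.W1 * f.cols0;
  bn_forward_train(f.Z1, p.g1, p.b1, p.rm1, p.rv1, bn_mom, f.bn1, f.A1);
  f.Z1.reset();
  relu_(f.A1);
  im2col_act(f.A1, B, c.P1, c.K, f.cols1);
  f.Z2 = p.W2 * f.cols1;
  bn_forward_train(f.Z2, p.g2, p.b2, p.rm2, p.rv2, bn_mom, f.bn2, f.A2);
  f.Z2.reset();
  relu_(f.A2);
  im2col_act(f.A2, B, c.P2, c.K, f.cols2);
  f.Z3 = p.W3 * f.cols2;
  bn_forward_train(f.Z3, p.g3, p.b3, p.rm3, p.rv3, bn_mom, f.bn3, f.A3);
  f.Z3.reset();
  relu_(f.A3);
  maxpool(f.A3, B, c.P3, c.pool, f.pooled, f.argmax);
  flatten(f.pooled, B, c.flat, f.flat);

  f.H1 = p.Wd1 * f.flat;
  f.H1.each_col() += p.bd1;
  relu_(f.H1);
  f.mask1.set_size(f.H1.n_rows, f.H1.n_cols);
  float keep = 1.0f - c.dropout, inv = 1.0f / keep;
  for (uword i = 0; i < f.mask1.n_elem; ++i)
    f.mask1(i) = (unif_rand() < keep) ? inv : 0.0f;
  f.H1 %= f.mask1;

  f.H2 = p.Wd2 * f.H1;
  f.H2.each_col() += p.bd2;
  relu_(f.H2);
  f.mask2.set_size(f.H2.n_rows, f.H2.n_cols);
  for (uword i = 0; i < f.mask2.n_elem; ++i)
    f.mask2(i) = (unif_rand() < keep) ? inv : 0.0f;
  f.H2 %= f.mask2;

  f.O = p.Wo * f.H2;
  f.O.each_col() += p.bo;
  f.probs = softmax_cols(f.O);
}

// inference logits for a set of images, chunked to bound memory
fmat infer_logits(const Params& p, const Config& c, const RawMatrix& X,
                  const IntegerVector& idx, int chunk = 256) {
  int n = idx.size();
  fmat logits(c.classes, n);
  fmat cols0, Z1, cols1, Z2, cols2, Z3, pooled, flat, H1, H2, O;
  arma::umat argmax;
  for (int at = 0; at < n; at += chunk) {
    int B = std::min(chunk, n - at);
    IntegerVector sub(B);
    for (int i = 0; i < B; ++i) sub[i] = idx[at + i];
    im2col_raw(X, sub, c, cols0);
    Z1 = p.W1 * cols0;
    bn_forward_infer(Z1, p.g1, p.b1, p.rm1, p.rv1);
    relu_(Z1);
    im2col_act(Z1, B, c.P1, c.K, cols1);
    Z2 = p.W2 * cols1;
    bn_forward_infer(Z2, p.g2, p.b2, p.rm2, p.rv2);
    relu_(Z2);
    im2col_act(Z2, B, c.P2, c.K, cols2);
    Z3 = p.W3 * cols2;
    bn_forward_infer(Z3, p.g3, p.b3, p.rm3, p.rv3);
    relu_(Z3);
    maxpool(Z3, B, c.P3, c.pool, pooled, argmax);
    flatten(pooled, B, c.flat, flat);
    H1 = p.Wd1 * flat;
    H1.each_col() += p.bd1;
    relu_(H1);
    H2 = p.Wd2 * H1;
    H2.each_col() += p.bd2;
    relu_(H2);
    O = p.Wo * H2;
    O.each_col() += p.bo;
    logits.cols(at, at + B - 1) = O;
  }
  return logits;
}

struct Velocity {
  fmat W1, W2, W3, Wd1, Wd2, Wo;
  fvec g1, b1, g2, b2, g3, b3, bd1, bd2, bo;
  void init(const Params& p) {
    W1.zeros(arma::size(p.W1)); W2.zeros(arma::size(p.W2));
    W3.zeros(arma::size(p.W3)); Wd1.zeros(arma::size(p.Wd1));
    Wd2.zeros(arma::size(p.Wd2)); Wo.zeros(arma::size(p.Wo));
    g1.zeros(arma::size(p.g1)); b1.zeros(arma::size(p.b1));
    g2.zeros(arma::size(p.g2)); b2.zeros(arma::size(p.b2));
    g3.zeros(arma::size(p.g3)); b3.zeros(arma::size(p.b3));
    bd1.zeros(arma::size(p.bd1)); bd2.zeros(arma::size(p.bd2));
    bo.zeros(arma::size(p.bo));
  }
};

inline void sgd(fmat& w, fmat& v, const fmat& g, float lr, float mom) {
  v = mom * v - lr * g;
  w += v;
}
inline void sgd(fvec& w, fvec& v, const fvec& g, float lr, float mom) {
  v = mom * v - lr * g;
  w += v;
}

} // namespace

// [[Rcpp::export]]
List cnn_init_cpp(List cfg) {
  Config c = read_config(cfg);
  Params p;
  p.W1 = he_init(c.F1, c.K * c.C, c.K * c.C);
  p.W2 = he_init(c.F2, c.K * c.F1, c.K * c.F1);
  p.W3 = he_init(c.F3, c.K * c.F2, c.K * c.F2);
  p.Wd1 = he_init(c.D1, c.flat, c.flat);
  p.Wd2 = he_init(c.D2, c.D1, c.D1);
  p.Wo = he_init(c.classes, c.D2, c.D2);
  p.g1.ones(c.F1); p.b1.zeros(c.F1);
  p.g2.ones(c.F2); p.b2.zeros(c.F2);
  p.g3.ones(c.F3); p.b3.zeros(c.F3);
  p.rm1.zeros(c.F1); p.rv1.ones(c.F1);
  p.rm2.zeros(c.F2); p.rv2.ones(c.F2);
  p.rm3.zeros(c.F3); p.rv3.ones(c.F3);
  p.bd1.zeros(c.D1); p.bd2.zeros(c.D2); p.bo.zeros(c.classes);
  return params_to_r(p);
}

// [[Rcpp::export]]
List cnn_train_cpp(List params_r, List cfg, RawMatrix Xtr, IntegerVector ytr,
                   RawMatrix Xval, IntegerVector yval, bool verbose) {
  Config c = read_config(cfg);
  Params p = params_from_r(params_r);
  Velocity v;
  v.init(p);
  int ntr = Xtr.ncol(), nval = Xval.ncol();
  if (ntr < 1 || nval < 1)
    stop("training and validation sets must be nonempty");

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;
  IntegerVector val_idx(nval);
  for (int i = 0; i < nval; ++i) val_idx[i] = i;

  FwdCache f;
  std::vector<double> h_epoch, h_train_loss, h_val_loss, h_val_acc;
  double best_acc = -1.0;
  int best_epoch = -1, since_best = 0;
  List best_params = params_to_r(p);

  for (int epoch = 1; epoch <= c.max_epochs; ++epoch) {
    // shuffle with R's RNG
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    long seen = 0;
    for (int at = 0; at < ntr; at += c.batch) {
      int B = std::min(c.batch, ntr - at);
      IntegerVector idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order[at + i];
      forward_train(p, c, Xtr, idx, c.bn_momentum, f);

      // cross-entropy and softmax gradient
      fmat dO = f.probs;
      for (int i = 0; i < B; ++i) {
        int y = ytr[idx[i]];
        epoch_loss += -std::log(std::max(1e-12f, f.probs(y, i)));
        dO(y, i) -= 1.0f;
      }
      seen += B;
      dO /= (float)B;

      fvec dbo = arma::sum(dO, 1);
      fmat dWo = dO * f.H2.t();
      fmat dH2 = p.Wo.t() * dO;        // tiny: lazy transpose is fine
      dH2 %= f.mask2;
      relu_mask(dH2, f.H2);
      fvec dbd2 = arma::sum(dH2, 1);
      fmat dWd2 = dH2 * f.H1.t();
      fmat Wd2t = p.Wd2.t();           // no-trans GEMM path is faster
      fmat dH1 = Wd2t * dH2;
      dH1 %= f.mask1;
      relu_mask(dH1, f.H1);
      fvec dbd1 = arma::sum(dH1, 1);
      fmat dWd1 = dH1 * f.flat.t();
      fmat Wd1t = p.Wd1.t();
      fmat dflat = Wd1t * dH1;

      // unflatten + unpool into dA3
      fmat dA3(c.F3, (uword)B * c.P3, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        const float* src = dflat.colptr(b);
        for (int pp = 0; pp < c.P4; ++pp) {
          uword oc = (uword)b * c.P4 + pp;
          for (int ff = 0; ff < c.F3; ++ff) {
            uword tgt = f.argmax(ff, oc);
            dA3(ff, tgt) += src[pp * c.F3 + ff];
          }
        }
      }
      relu_mask(dA3, f.A3);
      f.A3.reset();
      fvec dg3, db3;
      bn_backward(dA3, f.bn3, p.g3, dg3, db3); // dA3 is now dZ3
      f.bn3.zhat.reset();
      fmat dW3 = dA3 * f.cols2.t();
      f.cols2.reset();
      fmat W3t = p.W3.t();
      fmat dcols2 = W3t * dA3;
      dA3.reset();
      fmat dA2(c.F2, (uword)B * c.P2);
      col2im_act(dcols2, B, c.P2, c.K, dA2);
      dcols2.reset();
      relu_mask(dA2, f.A2);
      f.A2.reset();
      fvec dg2, db2;
      bn_backward(dA2, f.bn2, p.g2, dg2, db2);
      f.bn2.zhat.reset();
      fmat dW2 = dA2 * f.cols1.t();
      f.cols1.reset();
      fmat W2t = p.W2.t();
      fmat dcols1 = W2t * dA2;
      dA2.reset();
      fmat dA1(c.F1, (uword)B * c.P1);
      col2im_act(dcols1, B, c.P1, c.K, dA1);
      dcols1.reset();
      relu_mask(dA1, f.A1);
      f.A1.reset();
      fvec dg1, db1;
      bn_backward(dA1, f.bn1, p.g1, dg1, db1);
      f.bn1.zhat.reset();
      fmat dW1 = dA1 * f.cols0.t();
      f.cols0.reset();
      dA1.reset();

      sgd(p.W1, v.W1, dW1, c.lr, c.momentum);
      sgd(p.W2, v.W2, dW2, c.lr, c.momentum);
      sgd(p.W3, v.W3, dW3, c.lr, c.momentum);
      sgd(p.g1, v.g1, dg1, c.lr, c.momentum);
      sgd(p.b1, v.b1, db1, c.lr, c.momentum);
      sgd(p.g2, v.g2, dg2, c.lr, c.momentum);
      sgd(p.b2, v.b2, db2, c.lr, c.momentum);
      sgd(p.g3, v.g3, dg3, c.lr, c.momentum);
      sgd(p.b3, v.b3, db3, c.lr, c.momentum);
      sgd(p.Wd1, v.Wd1, dWd1, c.lr, c.momentum);
      sgd(p.bd1, v.bd1, dbd1, c.lr, c.momentum);
      sgd(p.Wd2, v.Wd2, dWd2, c.lr, c.momentum);
      sgd(p.bd2, v.bd2, dbd2, c.lr, c.momentum);
      sgd(p.Wo, v.Wo, dWo, c.lr, c.momentum);
      sgd(p.bo, v.bo, dbo, c.lr, c.momentum);
    }

    fmat lg = infer_logits(p, c, Xval, val_idx);
    fmat pr = softmax_cols(lg);
    double vloss = 0.0;
    int correct = 0;
    for (int i = 0; i < nval; ++i) {
      int y = yval[i];
      vloss += -std::log(std::max(1e-12f, pr(y, i)));
      if ((int)arma::index_max(pr.col(i)) == y) ++correct;
    }
    vloss /= nval;
    double vacc = (double)correct / nval;
    h_epoch.push_back(epoch);
    h_train_loss.push_back(epoch_loss / std::max(1L, seen));
    h_val_loss.push_back(vloss);
    h_val_acc.push_back(vacc);
    if (verbose)
      Rprintf("epoch %3d train loss %.4f | val loss %.4f acc %.4f\n",
              epoch, epoch_loss / std::max(1L, seen), vloss, vacc);
    if (vacc > best_acc) {
      best_acc = vacc;
      best_epoch = epoch;
      since_best = 0;
      best_params = params_to_r(p);
    } else if (++since_best >= c.patience) break;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = best_params,
    _["best_epoch"] = best_epoch,
    _["best_val_acc"] = best_acc,
    _["history"] = DataFrame::create(
      _["epoch"] = h_epoch, _["train_loss"] = h_train_loss,
      _["val_loss"] = h_val_loss, _["val_accuracy"] = h_val_acc));
}

// [[Rcpp::export]]
NumericMatrix cnn_logits_cpp(List params_r, List cfg, RawMatrix X) {
  Config c = read_config(cfg);
  Params p = params_from_r(params_r);
  IntegerVector idx(X.ncol());
  for (int i = 0; i < X.ncol(); ++i) idx[i] = i;
  fmat lg = infer_logits(p, c, X, idx);
  NumericMatrix out(lg.n_rows, lg.n_cols);
  for (uword j = 0; j < lg.n_cols; ++j)
    for (uword i = 0; i < lg.n_rows; ++i) out(i, j) = lg(i, j);
  return out;
}
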