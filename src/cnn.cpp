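// Small CNN for cycle-image classification.
//
// Architecture (fixed stack, sizes from the config): three conv(3x3, valid,
// ReLU) + maxpool(2x2) blocks, a dense ReLU layer, and a softmax output,
// trained with Adam on the categorical cross-entropy.  Single precision
// throughout; convolutions are im2col + GEMM, processed one image at a time
// so the working set stays cache-resident.  All randomness (weight
// initialization, batch shuffling) comes from one std::mt19937 seed, so a
// fixed seed reproduces confusion matrices exactly on CPU.

#include <RcppArmadillo.h>
#include <cstring>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;

// Feature maps are fmat (channels x positions), position p = x * H + y.
// im2col produces (C*k*k x Ho*Wo) with patch row r = (kx*k + ky)*C + c, so
// each (kx, ky) block is a contiguous C-vector and copies are memcpys.
static void im2col(const fmat& in, int C, int H, int W, int k, fmat& out) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  const int K = C * k * k;
  out.set_size(K, (size_t)Ho * Wo);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      float* dst = out.colptr((size_t)ox * Ho + oy);
      for (int kx = 0; kx < k; ++kx) {
        const float* src = in.colptr((size_t)(ox + kx) * H + oy);
        // k consecutive ky values are contiguous C-vectors in the input
        std::memcpy(dst + (size_t)kx * k * C, src,
                    sizeof(float) * (size_t)k * C);
      }
    }
  }
}

static void col2im_add(const fmat& cols, int C, int H, int W, int k,
                       fmat& out) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  out.zeros(C, (size_t)H * W);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const float* src = cols.colptr((size_t)ox * Ho + oy);
      for (int kx = 0; kx < k; ++kx) {
        float* dst = out.colptr((size_t)(ox + kx) * H + oy);
        const float* s = src + (size_t)kx * k * C;
        const int n = k * C;
        for (int i = 0; i < n; ++i) dst[i] += s[i];
      }
    }
  }
}

// 2x2 max pooling, stride 2; amax stores the input position index.
static void maxpool(const fmat& in, int C, int H, int W, fmat& out,
                    arma::Mat<int>& amax) {
  const int Ho = H / 2, Wo = W / 2;
  out.set_size(C, (size_t)Ho * Wo);
  amax.set_size(C, (size_t)Ho * Wo);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const int p = ox * Ho + oy;
      const int q00 = (2 * ox) * H + 2 * oy;
      const int cand[4] = {q00, q00 + 1, q00 + H, q00 + H + 1};
      float* op = out.colptr(p);
      int* ap = amax.colptr(p);
      const float* c0 = in.colptr(cand[0]);
      const float* c1 = in.colptr(cand[1]);
      const float* c2 = in.colptr(cand[2]);
      const float* c3 = in.colptr(cand[3]);
      for (int c = 0; c < C; ++c) {
        float best = c0[c];
        int bi = cand[0];
        if (c1[c] > best) { best = c1[c]; bi = cand[1]; }
        if (c2[c] > best) { best = c2[c]; bi = cand[2]; }
        if (c3[c] > best) { best = c3[c]; bi = cand[3]; }
        op[c] = best;
        ap[c] = bi;
      }
    }
  }
}

static void maxpool_back(const fmat& dout, const arma::Mat<int>& amax,
                         int C, int H, int W, fmat& din) {
  din.zeros(C, (size_t)H * W);
  const size_t n = dout.n_cols;
  for (size_t p = 0; p < n; ++p) {
    const float* dp = dout.colptr(p);
    const int* ap = amax.colptr(p);
    for (int c = 0; c < C; ++c) din(c, ap[c]) += dp[c];
  }
}

static inline void relu_vec(float* p, size_t n) {
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero gradient entries where the forward activation was clipped
static inline void relu_mask(float* g, const float* a, size_t n) {
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0.0f) g[i] = 0.0f;
}

struct Adam {
  fmat m, v;
  void init(const fmat& w) { m.zeros(arma::size(w)); v.zeros(arma::size(w)); }
  void step(fmat& w, const fmat& g, float lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

static fmat glorot(int rows, int cols, int fan_in, int fan_out,
                   std::mt19937& gen) {
  const float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
  std::uniform_real_distribution<float> unif(-lim, lim);
  fmat w(rows, cols);
  for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = unif(gen);
  return w;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cnn_train_eval_cpp(Rcpp::NumericMatrix X,
                                       Rcpp::IntegerVector y,
                                       Rcpp::IntegerVector train_idx,
                                       Rcpp::IntegerVector test_idx,
                                       int n_classes, int H, int W, int C,
                                       int filters, int dense_units,
                                       double lr, int epochs, int batch,
                                       int seed) {
  const int D = X.nrow(), n = X.ncol();
  if (D != C * H * W) Rcpp::stop("image dimension mismatch");
  fmat Xf(D, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < D; ++i) Xf(i, j) = (float)X(i, j);

  const int k = 3, F = filters;
  const int Hc1 = H - 2, Wc1 = W - 2;
  const int Hp1 = Hc1 / 2, Wp1 = Wc1 / 2;
  const int Hc2 = Hp1 - 2, Wc2 = Wp1 - 2;
  const int Hp2 = Hc2 / 2, Wp2 = Wc2 / 2;
  const int Hc3 = Hp2 - 2, Wc3 = Wp2 - 2;
  const int Hp3 = Hc3 / 2, Wp3 = Wc3 / 2;
  const int flat = F * Hp3 * Wp3;

  std::mt19937 gen((unsigned)seed);
  fmat W1 = glorot(F, C * 9, C * 9, F * 9, gen);
  fmat W2 = glorot(F, F * 9, F * 9, F * 9, gen);
  fmat W3 = glorot(F, F * 9, F * 9, F * 9, gen);
  fmat Wd1 = glorot(dense_units, flat, flat, dense_units, gen);
  fmat Wd2 = glorot(n_classes, dense_units, dense_units, n_classes, gen);
  fmat b1(F, 1, arma::fill::zeros), b2(F, 1, arma::fill::zeros),
      b3(F, 1, arma::fill::zeros), bd1(dense_units, 1, arma::fill::zeros),
      bd2(n_classes, 1, arma::fill::zeros);

  Adam aW1, aW2, aW3, aWd1, aWd2, ab1, ab2, ab3, abd1, abd2;
  aW1.init(W1); aW2.init(W2); aW3.init(W3); aWd1.init(Wd1); aWd2.init(Wd2);
  ab1.init(b1); ab2.init(b2); ab3.init(b3); abd1.init(bd1); abd2.init(bd2);

  fmat col1, col2, col3, A1, A1p, A2, A2p, A3, A3p;
  arma::Mat<int> i1, i2, i3;
  fmat gW1, gW2, gW3, gWd1, gWd2;
  fvec gb1, gb2, gb3, gbd1, gbd2;
  fmat dA1, dA1p, dA2, dA2p, dA3, dcol;

  auto forward = [&](int img) {
    const fmat A0(const_cast<float*>(Xf.colptr(img)), C,
                  (size_t)H * W, false, true);
    im2col(A0, C, H, W, k, col1);
    A1 = W1 * col1;
    A1.each_col() += b1.col(0);
    relu_vec(A1.memptr(), A1.n_elem);
    maxpool(A1, F, Hc1, Wc1, A1p, i1);
    im2col(A1p, F, Hp1, Wp1, k, col2);
    A2 = W2 * col2;
    A2.each_col() += b2.col(0);
    relu_vec(A2.memptr(), A2.n_elem);
    maxpool(A2, F, Hc2, Wc2, A2p, i2);
    im2col(A2p, F, Hp2, Wp2, k, col3);
    A3 = W3 * col3;
    A3.each_col() += b3.col(0);
    relu_vec(A3.memptr(), A3.n_elem);
    maxpool(A3, F, Hc3, Wc3, A3p, i3);
    const fvec fl(const_cast<float*>(A3p.memptr()), flat, false, true);
    fvec h = Wd1 * fl + bd1.col(0);
    relu_vec(h.memptr(), h.n_elem);
    fvec logits = Wd2 * h + bd2.col(0);
    logits -= logits.max();
    fvec p = arma::exp(logits);
    p /= arma::accu(p);
    return std::make_pair(p, h);
  };

  std::vector<int> order(train_idx.begin(), train_idx.end());
  const int n_train = (int)order.size();
  int t_step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    for (int b0 = 0; b0 < n_train; b0 += batch) {
      const int bsz = std::min(batch, n_train - b0);
      gW1.zeros(arma::size(W1)); gW2.zeros(arma::size(W2));
      gW3.zeros(arma::size(W3)); gWd1.zeros(arma::size(Wd1));
      gWd2.zeros(arma::size(Wd2));
      gb1.zeros(F); gb2.zeros(F); gb3.zeros(F);
      gbd1.zeros(dense_units); gbd2.zeros(n_classes);
      for (int bi = 0; bi < bsz; ++bi) {
        const int img = order[b0 + bi];
        auto ph = forward(img);
        fvec dl = ph.first;
        dl(y[img]) -= 1.0f;
        const fvec fl(const_cast<float*>(A3p.memptr()), flat, false, true);
        gWd2 += dl * ph.second.t();
        gbd2 += dl;
        fvec dh = Wd2.t() * dl;
        relu_mask(dh.memptr(), ph.second.memptr(), dh.n_elem);
        gWd1 += dh * fl.t();
        gbd1 += dh;
        fvec dfl = Wd1.t() * dh;
        const fmat dA3pv(dfl.memptr(), F, (size_t)Hp3 * Wp3, false, true);
        maxpool_back(dA3pv, i3, F, Hc3, Wc3, dA3);
        relu_mask(dA3.memptr(), A3.memptr(), dA3.n_elem);
        gW3 += dA3 * col3.t();
        gb3 += arma::sum(dA3, 1);
        dcol = W3.t() * dA3;
        col2im_add(dcol, F, Hp2, Wp2, k, dA2p);
        maxpool_back(dA2p, i2, F, Hc2, Wc2, dA2);
        relu_mask(dA2.memptr(), A2.memptr(), dA2.n_elem);
        gW2 += dA2 * col2.t();
        gb2 += arma::sum(dA2, 1);
        dcol = W2.t() * dA2;
        col2im_add(dcol, F, Hp1, Wp1, k, dA1p);
        maxpool_back(dA1p, i1, F, Hc1, Wc1, dA1);
        relu_mask(dA1.memptr(), A1.memptr(), dA1.n_elem);
        gW1 += dA1 * col1.t();
        gb1 += arma::sum(dA1, 1);
      }
      const float inv = 1.0f / (float)bsz;
      ++t_step;
      const float flr = (float)lr;
      aW1.step(W1, gW1 * inv, flr, t_step);
      aW2.step(W2, gW2 * inv, flr, t_step);
      aW3.step(W3, gW3 * inv, flr, t_step);
      aWd1.step(Wd1, gWd1 * inv, flr, t_step);
      aWd2.step(Wd2, gWd2 * inv, flr, t_step);
      fmat gb;
      gb = fmat(gb1) * inv; ab1.step(b1, gb, flr, t_step);
      gb = fmat(gb2) * inv; ab2.step(b2, gb, flr, t_step);
      gb = fmat(gb3) * inv; ab3.step(b3, gb, flr, t_step);
      gb = fmat(gbd1) * inv; abd1.step(bd1, gb, flr, t_step);
      gb = fmat(gbd2) * inv; abd2.step(bd2, gb, flr, t_step);
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::IntegerMatrix cm(n_classes, n_classes);
  for (int i = 0; i < test_idx.size(); ++i) {
    const int img = test_idx[i];
    auto ph = forward(img);
    cm(y[img], (int)ph.first.index_max()) += 1;
  }
  return cm;
}
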