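// Dense U-Net: native CPU implementation (forward, backprop, Adam).
//
// Feature maps are stored as arma::mat A(H*W, C): one column per channel,
// pixels column-major within a channel (p = i + j*H). im2col / col2im are
// contiguous-segment copies, dense blocks grow inside a preallocated buffer
// (layer inputs are leading-column alias views, so concatenations cost
// nothing), and convolutions are single GEMMs. The architecture is an
// encoder-decoder with dense blocks: inside a block, layer l convolves (3x3,
// ReLU) the concatenation of the block input and all previous layer outputs
// (growth rate G per layer); a 1x1 transition compresses the concatenation.
// Decoder levels concatenate the matching encoder feature map (skip
// connection) after 2x nearest-neighbour upsampling.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

typedef Mat<unsigned char> bmat;

// ---------- conv primitive ----------

struct Conv {
  int cin = 0, cout = 0, k = 1;  // k in {1, 3}
  mat W;   // (cin*k*k) x cout
  rowvec b;
  mat gW; rowvec gb;             // batch-accumulated gradients
  mat mW, vW; rowvec mb, vb;     // Adam state

  void init(int cin_, int cout_, int k_) {
    cin = cin_; cout = cout_; k = k_;
    const int fan_in = cin * k * k;
    W.set_size(fan_in, cout);
    // He-normal init via R's RNG so set.seed() governs reproducibility
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
    b.zeros(cout);
    gW.zeros(fan_in, cout); gb.zeros(cout);
    mW.zeros(fan_in, cout); vW.zeros(fan_in, cout);
    mb.zeros(cout); vb.zeros(cout);
  }

  void zero_grad() { gW.zeros(); gb.zeros(); }

  void adam_step(double lr, double beta1, double beta2, double eps,
                 long t, double inv_batch) {
    const mat g = gW * inv_batch;
    const rowvec gv = gb * inv_batch;
    mW = beta1 * mW + (1.0 - beta1) * g;
    vW = beta2 * vW + (1.0 - beta2) * square(g);
    mb = beta1 * mb + (1.0 - beta1) * gv;
    vb = beta2 * vb + (1.0 - beta2) * square(gv);
    const double bc1 = 1.0 - std::pow(beta1, (double)t);
    const double bc2 = 1.0 - std::pow(beta2, (double)t);
    W -= lr * (mW / bc1) / (sqrt(vW / bc2) + eps);
    b -= lr * (mb / bc1) / (sqrt(vb / bc2) + eps);
  }
};

// per-conv forward cache (one sample at a time). For 3x3 convs `cols` owns
// the im2col matrix; 1x1 transitions alias their block buffer via cols_ext.
// `dcols` and `dinput` are backward scratch, persistent across steps so the
// big buffers are allocated once per training run, not once per step.
struct ConvCache {
  mat cols;
  const mat* cols_ext = nullptr;
  bmat mask;                       // post-ReLU positivity (empty if linear)
  mat dcols, dinput;
  const mat& inputs() const { return cols_ext ? *cols_ext : cols; }
};

void relu_inplace(mat& Z, bmat& mask) {
  mask.set_size(Z.n_rows, Z.n_cols);
  double* z = Z.memptr();
  unsigned char* m = mask.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (z[i] > 0.0) m[i] = 1;
    else { z[i] = 0.0; m[i] = 0; }
  }
}

void mask_inplace(mat& dY, const bmat& mask) {
  if (mask.is_empty()) return;
  double* d = dY.memptr();
  const unsigned char* m = mask.memptr();
  const uword n = dY.n_elem;
  for (uword i = 0; i < n; ++i)
    if (!m[i]) d[i] = 0.0;
}

// im2col for 3x3 same-conv with zero padding, using the first C_use columns
// of A, filled into `cols` (HW, C_use*9; reallocation skipped when the shape
// is unchanged). Interior is segment memcpy; only the one-pixel borders are
// zero-filled.
void im2col3(const mat& A, int H, int W, int C_use, mat& cols) {
  const size_t HW = (size_t)H * W;
  cols.set_size(HW, (uword)C_use * 9);
  for (int c = 0; c < C_use; ++c) {
    const double* src = A.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        double* dst = cols.colptr((uword)c * 9 + (di + 1) + 3 * (dj + 1));
        const int i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 2 : H - 1;
        const int j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 2 : W - 1;
        const int len = i1 - i0 + 1;
        if (j0 > 0) std::memset(dst, 0, sizeof(double) * H);
        if (j1 < W - 1)
          std::memset(dst + (size_t)(W - 1) * H, 0, sizeof(double) * H);
        for (int j = j0; j <= j1; ++j) {
          double* d = dst + (size_t)j * H;
          const double* s = src + (size_t)(j + dj) * H + (i0 + di);
          if (i0 > 0) d[0] = 0.0;
          std::memcpy(d + i0, s, sizeof(double) * len);
          if (i1 < H - 1) d[H - 1] = 0.0;
        }
      }
    }
  }
}

// transpose of im2col3: scatter-add dcols (HW, C*9) onto dA (HW, C; filled,
// reallocation skipped when the shape is unchanged)
void col2im3(const mat& dcols, int C, int H, int W, mat& dA) {
  dA.set_size((uword)H * W, C);
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    double* dst = dA.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const double* src = dcols.colptr((uword)c * 9 + (di + 1) +
                                         3 * (dj + 1));
        const int i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 2 : H - 1;
        const int j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 2 : W - 1;
        const int len = i1 - i0 + 1;
        for (int j = j0; j <= j1; ++j) {
          const double* s = src + (size_t)j * H + i0;
          double* d = dst + (size_t)(j + dj) * H + (i0 + di);
          for (int t = 0; t < len; ++t) d[t] += s[t];
        }
      }
    }
  }
}

// 3x3 conv + ReLU over the first C_use buffer columns, GEMM'ed directly into
// `out` (an alias of the next G buffer columns)
void conv3_forward_into(Conv& cv, ConvCache& cc, const mat& B, int C_use,
                        int H, int W, double* out) {
  cc.cols_ext = nullptr;
  im2col3(B, H, W, C_use, cc.cols);
  mat Z(out, (uword)H * W, cv.cout, false, true);
  Z = cc.cols * cv.W;
  Z.each_row() += cv.b;
  relu_inplace(Z, cc.mask);
}

// 1x1 transition over the full block buffer; caches an alias, not a copy
mat trans_forward(Conv& cv, ConvCache& cc, const mat& B, bool relu_act) {
  cc.cols_ext = &B;
  mat Z = B * cv.W;
  Z.each_row() += cv.b;
  if (relu_act) relu_inplace(Z, cc.mask); else cc.mask.reset();
  return Z;
}

// generic forward for stem/head (owns a copy of its input in the cache)
mat conv_forward(Conv& cv, ConvCache& cc, const mat& A, int H, int W,
                 bool relu_act) {
  cc.cols_ext = nullptr;
  if (cv.k == 3) im2col3(A, H, W, A.n_cols, cc.cols);
  else cc.cols = A;
  mat Z = cc.cols * cv.W;
  Z.each_row() += cv.b;
  if (relu_act) relu_inplace(Z, cc.mask); else cc.mask.reset();
  return Z;
}

// dY is mutated (ReLU mask applied); returns the input gradient (a reference
// to per-conv scratch, valid until this conv's next backward call)
const mat& conv_backward(Conv& cv, ConvCache& cc, mat& dY, int C_in, int H,
                         int W) {
  mask_inplace(dY, cc.mask);
  const mat& cols = cc.inputs();
  cv.gW += cols.t() * dY;
  cv.gb += sum(dY, 0);
  cc.dcols = dY * cv.W.t();
  if (cv.k == 3) {
    col2im3(cc.dcols, C_in, H, W, cc.dinput);
    return cc.dinput;
  }
  return cc.dcols;
}

// ---------- pooling / upsampling ----------

mat maxpool2(const mat& A, int H, int W, umat& argmax) {
  const int C = A.n_cols, Ho = H / 2, Wo = W / 2;
  mat Y((uword)Ho * Wo, C);
  argmax.set_size((uword)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = Y.colptr(c);
    uword* arg = argmax.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int po = i + j * Ho;
        const int q00 = 2 * i + 2 * j * H;
        const int qs[4] = {q00, q00 + 1, q00 + H, q00 + H + 1};
        double best = src[qs[0]]; int bq = qs[0];
        for (int m = 1; m < 4; ++m)
          if (src[qs[m]] > best) { best = src[qs[m]]; bq = qs[m]; }
        dst[po] = best; arg[po] = (uword)bq;
      }
    }
  }
  return Y;
}

mat maxpool2_backward(const mat& dY, const umat& argmax, int C, int H, int W) {
  mat dA((uword)H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = dY.colptr(c);
    const uword* arg = argmax.colptr(c);
    double* dst = dA.colptr(c);
    for (uword p = 0; p < dY.n_rows; ++p) dst[arg[p]] += src[p];
  }
  return dA;
}

// nearest-neighbour 2x upsample; H, W are the input (small) dims
mat upsample2(const mat& A, int H, int W) {
  const int C = A.n_cols, Ho = H * 2, Wo = W * 2;
  mat Y((uword)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = Y.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      const double* s = src + (size_t)(j / 2) * H;
      double* d = dst + (size_t)j * Ho;
      for (int i = 0; i < Ho; ++i) d[i] = s[i / 2];
    }
  }
  return Y;
}

mat upsample2_backward(const mat& dY, int H, int W) {
  const int C = dY.n_cols, Ho = H * 2;
  mat dA((uword)H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = dY.colptr(c);
    double* dst = dA.colptr(c);
    for (int j = 0; j < 2 * W; ++j) {
      const double* s = src + (size_t)j * Ho;
      double* d = dst + (size_t)(j / 2) * H;
      for (int i = 0; i < Ho; ++i) d[i / 2] += s[i];
    }
  }
  return dA;
}

// ---------- the network ----------

struct DenseUNet {
  int depth, F, L, G, ncls, input_size;
  bool skips;
  std::vector<Conv> convs;
  long adam_t = 0;

  std::vector<int> enc_in;     // block input channels per encoder level
  std::vector<int> enc_trans;  // transition output channels per level
  std::vector<int> dec_out;    // decoder transition output channels
  int bott_out = 0;

  std::vector<ConvCache> caches;
  std::vector<mat> block_buf;  // one growing buffer per dense block
  std::vector<umat> pool_arg;
  std::vector<int> skip_block; // encoder block index feeding each skip
  mat prob;                    // last softmax output (HW, ncls)
  int cur_H = 0, cur_W = 0;

  int width_cap() const { return 4 * F; }

  DenseUNet(int depth_, int F_, int L_, int G_, int ncls_, int input_size_,
            bool skips_)
      : depth(depth_), F(F_), L(L_), G(G_), ncls(ncls_),
        input_size(input_size_), skips(skips_) {
    enc_in.resize(depth + 1); enc_trans.resize(depth + 1);
    dec_out.resize(depth + 1);
    int c = F;
    for (int i = 1; i <= depth; ++i) {
      enc_in[i] = c;
      enc_trans[i] = std::min(F << (i - 1), width_cap());
      c = enc_trans[i];
    }
    bott_out = enc_trans[depth];
    for (int i = depth; i >= 1; --i)
      dec_out[i] = (i == 1) ? F : enc_trans[i - 1];

    // construction order: stem | enc blocks | bottleneck | dec blocks | head
    convs.emplace_back(); convs.back().init(1, F, 3);
    for (int i = 1; i <= depth; ++i) add_block(enc_in[i], enc_trans[i]);
    add_block(enc_trans[depth], bott_out);
    for (int i = depth; i >= 1; --i) {
      int cin = bott_or_prev(i) + (skips ? enc_in[i] + L * G : 0);
      add_block(cin, dec_out[i]);
    }
    convs.emplace_back(); convs.back().init(F, ncls, 1);  // linear head
    caches.resize(convs.size());
    block_buf.resize(2 * depth + 1);
    pool_arg.resize(depth + 1);
    skip_block.resize(depth + 1);
    for (int i = 1; i <= depth; ++i) skip_block[i] = i - 1;  // enc blocks
  }

  int bott_or_prev(int i) const {
    return (i == depth) ? bott_out : dec_out[i + 1];
  }

  void add_block(int cin, int tout) {
    for (int l = 0; l < L; ++l) {
      convs.emplace_back();
      convs.back().init(cin + l * G, G, 3);
    }
    convs.emplace_back();
    convs.back().init(cin + L * G, tout, 1);
  }

  // dense block + transition; A (and optionally skip) are copied once into
  // the block buffer, layers read leading-column views and write in place.
  mat block_forward(size_t& ci, size_t bi, const mat& A, const mat* skip,
                    int H, int W) {
    const size_t HW = (size_t)H * W;
    const int cin = A.n_cols + (skip ? (int)skip->n_cols : 0);
    mat& B = block_buf[bi];
    B.set_size(HW, cin + L * G);
    std::memcpy(B.memptr(), A.memptr(), sizeof(double) * A.n_elem);
    if (skip)
      std::memcpy(B.colptr(A.n_cols), skip->memptr(),
                  sizeof(double) * skip->n_elem);
    for (int l = 0; l < L; ++l) {
      conv3_forward_into(convs[ci], caches[ci], B, cin + l * G, H, W,
                         B.colptr(cin + l * G));
      ++ci;
    }
    mat out = trans_forward(convs[ci], caches[ci], B, true);
    ++ci;
    return out;
  }

  // backward through transition + block; dskip (optional) is extra gradient
  // flowing directly into the block's concatenated output (the skip path).
  mat block_backward(size_t ci, int cin, mat& dOut, const mat& dskip,
                     int H, int W) {
    const size_t trans = ci + L;
    // reference to the transition's backward scratch: mutating it is fine
    mat& dcat = const_cast<mat&>(
        conv_backward(convs[trans], caches[trans], dOut, cin + L * G, H, W));
    if (!dskip.is_empty()) dcat += dskip;
    std::vector<mat> dx(L + 1);
    dx[0] = dcat.cols(0, cin - 1);
    for (int m = 1; m <= L; ++m)
      dx[m] = dcat.cols(cin + (m - 1) * G, cin + m * G - 1);
    for (int l = L; l >= 1; --l) {
      const size_t cj = ci + (l - 1);
      const int in_ch = cin + (l - 1) * G;
      const mat& din = conv_backward(convs[cj], caches[cj], dx[l], in_ch,
                                     H, W);
      dx[0] += din.cols(0, cin - 1);
      for (int m = 1; m < l; ++m)
        dx[m] += din.cols(cin + (m - 1) * G, cin + m * G - 1);
    }
    return dx[0];
  }

  // full forward; X is (HW, 1) normalized. H0, W0 divisible by 2^depth.
  void forward(const mat& X, int H0, int W0) {
    cur_H = H0; cur_W = W0;
    int H = H0, W = W0;
    size_t ci = 0, bi = 0;
    mat A = conv_forward(convs[0], caches[0], X, H, W, true);
    ci = 1;
    for (int i = 1; i <= depth; ++i) {
      A = block_forward(ci, bi++, A, nullptr, H, W);
      A = maxpool2(A, H, W, pool_arg[i]);
      H /= 2; W /= 2;
    }
    A = block_forward(ci, bi++, A, nullptr, H, W);  // bottleneck
    for (int i = depth; i >= 1; --i) {
      A = upsample2(A, H, W);
      H *= 2; W *= 2;
      // the skip taps the encoder block's concatenated output, which is
      // exactly that block's buffer contents (still live)
      const mat* skip = skips ? &block_buf[skip_block[i]] : nullptr;
      A = block_forward(ci, bi++, A, skip, H, W);
    }
    const size_t head = convs.size() - 1;
    mat logits = conv_forward(convs[head], caches[head], A, H, W, false);
    logits.each_col() -= max(logits, 1);
    prob = exp(logits);
    prob.each_col() /= sum(prob, 1);
  }

  // backward from 0-based labels y (length HW); accumulates gradients and
  // returns the cross-entropy loss of the cached forward pass
  double backward(const uvec& y) {
    const int HW = cur_H * cur_W;
    double loss = 0.0;
    mat dlog = prob;
    for (int p = 0; p < HW; ++p) {
      loss -= std::log(std::max(prob(p, y(p)), 1e-12));
      dlog(p, y(p)) -= 1.0;
    }
    loss /= HW;
    dlog /= (double)HW;

    int H = cur_H, W = cur_W;
    const size_t head = convs.size() - 1;
    mat dA = conv_backward(convs[head], caches[head], dlog, F, H, W);

    const size_t per_block = L + 1;
    const size_t dec_first = 1 + per_block * (size_t)(depth + 1);
    const mat none;
    std::vector<mat> dskip(depth + 1);
    for (int i = 1; i <= depth; ++i) {  // decoder, shallow to deep
      const size_t ci = dec_first + per_block * (size_t)(depth - i);
      const int cin = bott_or_prev(i) + (skips ? enc_in[i] + L * G : 0);
      mat din = block_backward(ci, cin, dA, none, H, W);
      const int up_ch = bott_or_prev(i);
      if (skips) {
        dskip[i] = din.cols(up_ch, cin - 1);
        din = din.cols(0, up_ch - 1);
      }
      H /= 2; W /= 2;
      dA = upsample2_backward(din, H, W);
    }
    const size_t bott_ci = 1 + per_block * (size_t)depth;
    dA = block_backward(bott_ci, enc_trans[depth], dA, none, H, W);
    for (int i = depth; i >= 1; --i) {  // encoder, deep to shallow
      dA = maxpool2_backward(dA, pool_arg[i], enc_trans[i], H * 2, W * 2);
      H *= 2; W *= 2;
      const size_t ci = 1 + per_block * (size_t)(i - 1);
      dA = block_backward(ci, enc_in[i], dA, skips ? dskip[i] : none, H, W);
    }
    conv_backward(convs[0], caches[0], dA, 1, H, W);
    return loss;
  }

  long n_params() const {
    long n = 0;
    for (const auto& c : convs) n += (long)c.W.n_elem + (long)c.b.n_elem;
    return n;
  }
};

}  // namespace

// ---------- R interface ----------

// [[Rcpp::export]]
SEXP unet_create(int depth, int base_filters, int block_layers, int growth,
                 int n_classes, int input_size, bool skip_connections) {
  Rcpp::XPtr<DenseUNet> p(
      new DenseUNet(depth, base_filters, block_layers, growth, n_classes,
                    input_size, skip_connections),
      true);
  return p;
}

// [[Rcpp::export]]
double unet_n_params(SEXP xp) {
  Rcpp::XPtr<DenseUNet> p(xp);
  return (double)p->n_params();
}

// returns (HW, ncls) probabilities, pixels column-major
// [[Rcpp::export]]
arma::mat unet_forward(SEXP xp, const arma::mat& image) {
  Rcpp::XPtr<DenseUNet> p(xp);
  const int H = image.n_rows, W = image.n_cols;
  const int div = 1 << p->depth;
  if (H % div != 0 || W % div != 0)
    Rcpp::stop("image dims must be divisible by 2^depth = %d", div);
  mat X = reshape(vectorise(image), (uword)H * W, 1);
  p->forward(X, H, W);
  return p->prob;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_train(SEXP xp, const Rcpp::List& images,
                               const Rcpp::List& labels, int epochs,
                               int batch_size, double lr) {
  Rcpp::XPtr<DenseUNet> p(xp);
  const int n = images.size();
  const int div = 1 << p->depth;
  std::vector<mat> X(n);
  std::vector<uvec> Y(n);
  std::vector<std::pair<int, int>> dims(n);
  for (int s = 0; s < n; ++s) {
    mat img = Rcpp::as<mat>(images[s]);
    const int H = img.n_rows, W = img.n_cols;
    if (H % div != 0 || W % div != 0)
      Rcpp::stop("sample %d: dims must be divisible by 2^depth = %d",
                 s + 1, div);
    dims[s] = {H, W};
    X[s] = reshape(vectorise(img), (uword)H * W, 1);
    Rcpp::IntegerMatrix lm = labels[s];
    if (lm.nrow() != H || lm.ncol() != W)
      Rcpp::stop("sample %d: mask/image shape mismatch", s + 1);
    uvec y((uword)H * W);
    for (int q = 0; q < H * W; ++q) {
      const int v = lm[q];
      if (v < 0 || v >= p->ncls) Rcpp::stop("label out of range");
      y(q) = (uword)v;
    }
    Y[s] = std::move(y);
  }

  Rcpp::NumericVector epoch_loss(epochs);
  std::vector<int> order(n);
  for (int s = 0; s < n; ++s) order[s] = s;

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with R's RNG (reproducible under set.seed)
    for (int s = n - 1; s > 0; --s) {
      int j = (int)std::floor(unif_rand() * (s + 1));
      if (j > s) j = s;
      std::swap(order[s], order[j]);
    }
    double tot = 0.0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch_size, n - done);
      for (auto& c : p->convs) c.zero_grad();
      for (int m = 0; m < bs; ++m) {
        const int s = order[done + m];
        p->forward(X[s], dims[s].first, dims[s].second);
        tot += p->backward(Y[s]);
      }
      p->adam_t += 1;
      for (auto& c : p->convs)
        c.adam_step(lr, 0.9, 0.999, 1e-8, p->adam_t, 1.0 / bs);
      done += bs;
      Rcpp::checkUserInterrupt();
    }
    epoch_loss[e] = tot / n;
  }
  return epoch_loss;
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights(SEXP xp) {
  Rcpp::XPtr<DenseUNet> p(xp);
  Rcpp::List out(p->convs.size());
  for (size_t i = 0; i < p->convs.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = p->convs[i].W,
        Rcpp::Named("b") = rowvec(p->convs[i].b),
        Rcpp::Named("k") = p->convs[i].k);
  }
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP xp, const Rcpp::List& weights) {
  Rcpp::XPtr<DenseUNet> p(xp);
  if ((size_t)weights.size() != p->convs.size())
    Rcpp::stop("weight list length does not match architecture");
  for (size_t i = 0; i < p->convs.size(); ++i) {
    Rcpp::List wi = weights[i];
    mat W = Rcpp::as<mat>(wi["W"]);
    rowvec b = Rcpp::as<rowvec>(wi["b"]);
    if (W.n_rows != p->convs[i].W.n_rows || W.n_cols != p->convs[i].W.n_cols)
      Rcpp::stop("weight %d has wrong shape", (int)i + 1);
    p->convs[i].W = W;
    p->convs[i].b = b;
  }
}
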