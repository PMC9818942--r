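// Compact CNN for six-channel 224x224 sub-band stacks.
//
// Architecture (fixed): conv 6x6x64/s2 - relu - maxpool 2x2/s1 -
// conv 5x5x46/s2 - relu - maxpool - conv 4x4x32/s2 - relu - maxpool -
// conv 3x3x16/s1 - relu - maxpool - avgpool 2x2/s1 (or strict global
// average) - fc 16 - relu - fc 2 - combined softmax+sigmoid activation.
// "Same"-style zero padding is sized so the printed intermediate extents
// (112, 56, 28, 28) hold exactly. Single precision throughout; gradients
// are exact backprop. The training loop (Adam) lives in R.
//
// Activation tensors use plane-contiguous layout (H*H x C, spatial index
// p = h + H*w fastest) so pooling and im2col walk memory sequentially.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct ConvSpec {
  int cin, cout, k, stride, hin, hout, pad0;
};

// Layer geometry for input 224x224x6 (pad0 = leading pad; trailing pad
// is whatever the output extent implies).
const ConvSpec CONV[4] = {
  {6,   64, 6, 2, 224, 112, 2},
  {64,  46, 5, 2, 112, 56,  1},
  {46,  32, 4, 2, 56,  28,  1},
  {32,  16, 3, 1, 28,  28,  1},
};
const int FC1_OUT = 16, N_CLASS = 2;
const int POOL_H = 28, POOL_C = 16;

int conv_wsize(const ConvSpec& c) { return c.cout * (c.cin * c.k * c.k) + c.cout; }
int fc1_in(bool flatten) { return flatten ? POOL_H * POOL_H * POOL_C : POOL_C; }

int n_params(bool flatten) {
  int n = 0;
  for (int i = 0; i < 4; ++i) n += conv_wsize(CONV[i]);
  n += FC1_OUT * fc1_in(flatten) + FC1_OUT;
  n += N_CLASS * FC1_OUT + N_CLASS;
  return n;
}

// x: plane-contiguous input (hin^2 x cin). K: (cin*k*k x hout^2),
// column p = oh + hout*ow, row = c*k*k + kj*k + ki (ki = row offset,
// fastest, matching contiguous input rows).
void im2col(const arma::fmat& x, const ConvSpec& cs, arma::fmat& K) {
  const int k = cs.k, s = cs.stride, H = cs.hin, HO = cs.hout;
  const int rows = cs.cin * k * k;
  for (int ow = 0; ow < HO; ++ow) {
    for (int oh = 0; oh < HO; ++oh) {
      float* col = K.colptr(oh + HO * ow);
      const int ih0 = oh * s - cs.pad0, iw0 = ow * s - cs.pad0;
      int r = 0;
      for (int c = 0; c < cs.cin; ++c) {
        const float* plane = x.colptr(c);
        for (int kj = 0; kj < k; ++kj) {
          const int iw = iw0 + kj;
          if (iw < 0 || iw >= H) {
            for (int ki = 0; ki < k; ++ki) col[r++] = 0.0f;
          } else {
            const float* src = plane + (size_t)iw * H + ih0;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = ih0 + ki;
              col[r++] = (ih >= 0 && ih < H) ? src[ki] : 0.0f;
            }
          }
        }
      }
      (void)rows;
    }
  }
}

void col2im(const arma::fmat& dK, const ConvSpec& cs, arma::fmat& dx) {
  const int k = cs.k, s = cs.stride, H = cs.hin, HO = cs.hout;
  dx.zeros(H * H, cs.cin);
  for (int ow = 0; ow < HO; ++ow) {
    for (int oh = 0; oh < HO; ++oh) {
      const float* col = dK.colptr(oh + HO * ow);
      const int ih0 = oh * s - cs.pad0, iw0 = ow * s - cs.pad0;
      int r = 0;
      for (int c = 0; c < cs.cin; ++c) {
        float* plane = dx.colptr(c);
        for (int kj = 0; kj < k; ++kj) {
          const int iw = iw0 + kj;
          if (iw < 0 || iw >= H) { r += k; continue; }
          float* dst = plane + (size_t)iw * H + ih0;
          for (int ki = 0; ki < k; ++ki) {
            const int ih = ih0 + ki;
            if (ih >= 0 && ih < H) dst[ki] += col[r];
            ++r;
          }
        }
      }
    }
  }
}

// 2x2 stride-1 "same" max pool on plane layout (padded cells excluded).
void maxpool_fwd(const arma::fmat& in, int H, arma::fmat& out,
                 arma::Mat<int>& arg) {
  const int C = in.n_cols, HH = H * H;
  out.set_size(HH, C); arg.set_size(HH, C);
  for (int c = 0; c < C; ++c) {
    const float* p = in.colptr(c);
    float* o = out.colptr(c);
    int* a = arg.colptr(c);
    for (int w = 0; w < H; ++w) {
      const bool wok = (w + 1 < H);
      const int base = H * w;
      for (int h = 0; h < H; ++h) {
        const int q = base + h;
        float best = p[q]; int bi = q;
        if (h + 1 < H && p[q + 1] > best) { best = p[q + 1]; bi = q + 1; }
        if (wok) {
          if (p[q + H] > best) { best = p[q + H]; bi = q + H; }
          if (h + 1 < H && p[q + H + 1] > best) { best = p[q + H + 1]; bi = q + H + 1; }
        }
        o[q] = best; a[q] = bi;
      }
    }
  }
}

void maxpool_bwd(const arma::fmat& dout, const arma::Mat<int>& arg,
                 arma::fmat& din) {
  din.zeros(dout.n_rows, dout.n_cols);
  const int C = dout.n_cols, HH = dout.n_rows;
  for (int c = 0; c < C; ++c) {
    const float* g = dout.colptr(c);
    const int* a = arg.colptr(c);
    float* d = din.colptr(c);
    for (int q = 0; q < HH; ++q) d[a[q]] += g[q];
  }
}

// 2x2 stride-1 "same" average pool over the valid cells (plane layout).
void avgpool_fwd(const arma::fmat& in, int H, arma::fmat& out) {
  const int C = in.n_cols;
  out.set_size(H * H, C);
  for (int c = 0; c < C; ++c) {
    const float* p = in.colptr(c);
    float* o = out.colptr(c);
    for (int w = 0; w < H; ++w) {
      const bool wok = (w + 1 < H);
      for (int h = 0; h < H; ++h) {
        const int q = h + H * w;
        float s = p[q]; int n = 1;
        if (h + 1 < H) { s += p[q + 1]; ++n; }
        if (wok) {
          s += p[q + H]; ++n;
          if (h + 1 < H) { s += p[q + H + 1]; ++n; }
        }
        o[q] = s / n;
      }
    }
  }
}

void avgpool_bwd(const arma::fmat& dout, int H, arma::fmat& din) {
  const int C = dout.n_cols;
  din.zeros(H * H, C);
  for (int c = 0; c < C; ++c) {
    const float* g = dout.colptr(c);
    float* d = din.colptr(c);
    for (int w = 0; w < H; ++w) {
      const bool wok = (w + 1 < H);
      for (int h = 0; h < H; ++h) {
        const int q = h + H * w;
        int n = 1;
        if (h + 1 < H) ++n;
        if (wok) { ++n; if (h + 1 < H) ++n; }
        const float gg = g[q] / n;
        d[q] += gg;
        if (h + 1 < H) d[q + 1] += gg;
        if (wok) {
          d[q + H] += gg;
          if (h + 1 < H) d[q + H + 1] += gg;
        }
      }
    }
  }
}

struct Weights {
  arma::fmat Wc[4]; arma::fvec bc[4];
  arma::fmat W1; arma::fvec b1;
  arma::fmat W2; arma::fvec b2;
};

void unpack(const NumericVector& w, bool flatten, Weights& W) {
  size_t off = 0;
  auto take_mat = [&](arma::fmat& M, int rows, int cols) {
    M.set_size(rows, cols);
    float* p = M.memptr();
    for (size_t j = 0; j < (size_t)rows * cols; ++j) p[j] = (float)w[off + j];
    off += (size_t)rows * cols;
  };
  auto take_vec = [&](arma::fvec& v, int n) {
    v.set_size(n);
    for (int j = 0; j < n; ++j) v(j) = (float)w[off + j];
    off += n;
  };
  for (int i = 0; i < 4; ++i) {
    const ConvSpec& c = CONV[i];
    take_mat(W.Wc[i], c.cout, c.cin * c.k * c.k);
    take_vec(W.bc[i], c.cout);
  }
  take_mat(W.W1, FC1_OUT, fc1_in(flatten));
  take_vec(W.b1, FC1_OUT);
  take_mat(W.W2, N_CLASS, FC1_OUT);
  take_vec(W.b2, N_CLASS);
}

struct Cache {
  arma::fmat K[4];       // im2col matrices
  arma::fmat a[4];       // post-relu conv outputs (cout x hout^2)
  arma::fmat pool[4];    // post-maxpool outputs, plane layout (hout^2 x cout)
  arma::Mat<int> arg[4];
  arma::fvec head;       // pooled/flattened input to fc1
  arma::fvec h1, h1r;    // fc1 pre/post relu
  arma::fvec z;          // logits
  arma::fmat at, davg, dp, dpool_t, da, dat, dK, dx;  // scratch
};

void forward_one(const arma::fmat& x0, const Weights& W, bool flatten,
                 Cache& C) {
  const arma::fmat* cur = &x0;
  for (int i = 0; i < 4; ++i) {
    const ConvSpec& cs = CONV[i];
    C.K[i].set_size(cs.cin * cs.k * cs.k, cs.hout * cs.hout);
    im2col(*cur, cs, C.K[i]);
    C.a[i] = W.Wc[i] * C.K[i];
    C.a[i].each_col() += W.bc[i];
    C.a[i].for_each([](float& v) { if (v < 0) v = 0; });
    C.at = C.a[i].t();  // plane layout
    maxpool_fwd(C.at, cs.hout, C.pool[i], C.arg[i]);
    cur = &C.pool[i];
  }
  if (flatten) {
    arma::fmat avg;
    avgpool_fwd(C.pool[3], POOL_H, avg);
    C.head = arma::vectorise(avg);  // index = p + H^2 * c
  } else {
    C.head = arma::mean(C.pool[3], 0).t();
  }
  C.h1 = W.W1 * C.head + W.b1;
  C.h1r = C.h1;
  C.h1r.for_each([](float& v) { if (v < 0) v = 0; });
  C.z = W.W2 * C.h1r + W.b2;
}

// Combined activation loss: p~ = softmax(z) + sigmoid(z), renormalized;
// L = -log p~[y] + log S with S = sum(p~). The gradient is assembled in
// the analytically cancelled form so it stays bounded (like standard
// softmax cross-entropy) even when p~[y] underflows:
//   dL/dz_j = sig_j(1-sig_j)/S
//             - rho_s (1[j==y] - s_j) - 1[j==y] (1-sig_y) rho_sig,
// where rho_s = s_y/p~_y and rho_sig = sig_y/p~_y (computed via logs).
double loss_grad(const arma::fvec& z, int y, arma::fvec& dz) {
  arma::vec zd = arma::conv_to<arma::vec>::from(z);
  double m = zd.max();
  arma::vec e = arma::exp(zd - m);
  double esum = arma::accu(e);
  arma::vec s = e / esum;
  arma::vec sig = 1.0 / (1.0 + arma::exp(-zd));
  double S = arma::accu(s) + arma::accu(sig);  // always >= 1
  // log s_y and log sig_y, stable at deep saturation
  double ls = zd(y) - m - std::log(esum);
  double lsig = zd(y) >= 0 ? -std::log1p(std::exp(-zd(y)))
                           : zd(y) - std::log1p(std::exp(zd(y)));
  double lpt = std::max(ls, lsig) + std::log1p(std::exp(-std::fabs(ls - lsig)));
  double loss = std::log(S) - lpt;
  double rho_s = 1.0 / (1.0 + std::exp(lsig - ls));    // s_y / pt_y
  double rho_sig = 1.0 - rho_s;                        // sig_y / pt_y
  arma::vec dzd(N_CLASS);
  for (int j = 0; j < N_CLASS; ++j) {
    double g = sig(j) * (1.0 - sig(j)) / S;
    g -= rho_s * ((j == y ? 1.0 : 0.0) - s(j));
    if (j == y) g -= (1.0 - sig(y)) * rho_sig;
    dzd(j) = g;
  }
  dz = arma::conv_to<arma::fvec>::from(dzd);
  return loss;
}

struct Grads {
  arma::fmat dWc[4]; arma::fvec dbc[4];
  arma::fmat dW1; arma::fvec db1;
  arma::fmat dW2; arma::fvec db2;
  void init(const Weights& W) {
    for (int i = 0; i < 4; ++i) {
      dWc[i].zeros(W.Wc[i].n_rows, W.Wc[i].n_cols);
      dbc[i].zeros(W.bc[i].n_elem);
    }
    dW1.zeros(W.W1.n_rows, W.W1.n_cols); db1.zeros(W.b1.n_elem);
    dW2.zeros(W.W2.n_rows, W.W2.n_cols); db2.zeros(W.b2.n_elem);
  }
};

void backward_one(const Weights& W, bool flatten, Cache& C,
                  const arma::fvec& dz, Grads& G) {
  G.dW2 += dz * C.h1r.t();
  G.db2 += dz;
  arma::fvec dh1 = W.W2.t() * dz;
  for (int i = 0; i < FC1_OUT; ++i) if (C.h1(i) <= 0) dh1(i) = 0;
  G.dW1 += dh1 * C.head.t();
  G.db1 += dh1;
  arma::fvec dhead = W.W1.t() * dh1;

  arma::fmat dpool3;  // (H^2 x C) plane layout
  if (flatten) {
    C.davg.set_size(POOL_H * POOL_H, POOL_C);
    std::copy(dhead.begin(), dhead.end(), C.davg.memptr());
    avgpool_bwd(C.davg, POOL_H, dpool3);
  } else {
    const int HH = POOL_H * POOL_H;
    dpool3.set_size(HH, POOL_C);
    for (int c = 0; c < POOL_C; ++c)
      dpool3.col(c).fill(dhead(c) / HH);
  }

  arma::fmat dcur = dpool3;
  for (int i = 3; i >= 0; --i) {
    const ConvSpec& cs = CONV[i];
    maxpool_bwd(dcur, C.arg[i], C.dpool_t);          // plane layout
    C.da = C.dpool_t.t();                            // (cout x hout^2)
    const float* amask = C.a[i].memptr();
    float* dap = C.da.memptr();
    for (size_t j = 0; j < C.da.n_elem; ++j)
      if (amask[j] <= 0) dap[j] = 0;
    G.dWc[i] += C.da * C.K[i].t();
    G.dbc[i] += arma::sum(C.da, 1);
    if (i > 0) {
      C.dK = W.Wc[i].t() * C.da;
      col2im(C.dK, cs, C.dx);
      dcur = C.dx;
    }
  }
}

void pack_grads(const Grads& G, NumericVector& out) {
  size_t off = 0;
  auto put = [&](const float* p, size_t n) {
    for (size_t j = 0; j < n; ++j) out[off + j] = p[j];
    off += n;
  };
  for (int i = 0; i < 4; ++i) {
    put(G.dWc[i].memptr(), G.dWc[i].n_elem);
    put(G.dbc[i].memptr(), G.dbc[i].n_elem);
  }
  put(G.dW1.memptr(), G.dW1.n_elem);
  put(G.db1.memptr(), G.db1.n_elem);
  put(G.dW2.memptr(), G.dW2.n_elem);
  put(G.db2.memptr(), G.db2.n_elem);
}

arma::fmat sample_planes(const arma::fmat& X, int i) {
  // column i holds 224*224*6 values, plane-contiguous
  return arma::fmat(const_cast<float*>(X.colptr(i)), 224 * 224, 6, false);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_n_params")]]
int cnn_n_params(bool flatten) { return n_params(flatten); }

// [[Rcpp::export(name = ".cnn_data_alloc")]]
SEXP cnn_data_alloc(int n_samples, int n_features) {
  arma::fmat* X = new arma::fmat(n_features, n_samples, arma::fill::zeros);
  XPtr<arma::fmat> p(X, true);
  return p;
}

// [[Rcpp::export(name = ".cnn_data_set")]]
void cnn_data_set(SEXP ptr, int i, NumericVector x) {
  XPtr<arma::fmat> X(ptr);
  if (i < 1 || i > (int)X->n_cols) stop("sample index out of range");
  if ((int)x.size() != (int)X->n_rows) stop("feature length mismatch");
  float* col = X->colptr(i - 1);
  for (int j = 0; j < (int)x.size(); ++j) col[j] = (float)x[j];
}

// [[Rcpp::export(name = ".cnn_data_dim")]]
IntegerVector cnn_data_dim(SEXP ptr) {
  XPtr<arma::fmat> X(ptr);
  return IntegerVector::create(X->n_rows, X->n_cols);
}

// [[Rcpp::export(name = ".cnn_grad")]]
List cnn_grad(SEXP ptr, IntegerVector idx, IntegerVector labels,
              NumericVector w, bool flatten) {
  XPtr<arma::fmat> X(ptr);
  if ((int)w.size() != n_params(flatten)) stop("weight vector length mismatch");
  Weights W; unpack(w, flatten, W);
  Grads G; G.init(W);
  Cache C;
  double loss = 0;
  NumericMatrix logits(idx.size(), N_CLASS);
  for (int b = 0; b < idx.size(); ++b) {
    int i = idx[b] - 1;
    if (i < 0 || i >= (int)X->n_cols) stop("sample index out of range");
    arma::fmat x0 = sample_planes(*X, i);
    forward_one(x0, W, flatten, C);
    arma::fvec dz;
    loss += loss_grad(C.z, labels[b], dz);
    logits(b, 0) = C.z(0); logits(b, 1) = C.z(1);
    backward_one(W, flatten, C, dz, G);
  }
  const int B = idx.size();
  loss /= B;
  for (int i = 0; i < 4; ++i) { G.dWc[i] /= B; G.dbc[i] /= B; }
  G.dW1 /= B; G.db1 /= B; G.dW2 /= B; G.db2 /= B;
  NumericVector grad(n_params(flatten));
  pack_grads(G, grad);
  return List::create(_["loss"] = loss, _["grad"] = grad,
                      _["logits"] = logits);
}

// [[Rcpp::export(name = ".cnn_forward")]]
List cnn_forward(SEXP ptr, IntegerVector idx, NumericVector w, bool flatten) {
  XPtr<arma::fmat> X(ptr);
  if ((int)w.size() != n_params(flatten)) stop("weight vector length mismatch");
  Weights W; unpack(w, flatten, W);
  Cache C;
  NumericMatrix logits(idx.size(), N_CLASS);
  NumericMatrix feats(idx.size(), FC1_OUT);
  for (int b = 0; b < idx.size(); ++b) {
    int i = idx[b] - 1;
    if (i < 0 || i >= (int)X->n_cols) stop("sample index out of range");
    arma::fmat x0 = sample_planes(*X, i);
    forward_one(x0, W, flatten, C);
    logits(b, 0) = C.z(0); logits(b, 1) = C.z(1);
    for (int j = 0; j < FC1_OUT; ++j)
      feats(b, j) = flatten ? C.h1r(j) : C.head(j);
  }
  return List::create(_["logits"] = logits, _["features"] = feats);
}
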