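// U-net regression backend: encoder blocks of two 3x3 same-padded ReLU
// convolutions followed by 2x2 max pooling, a mirrored decoder with 2x2
// nearest upsampling and skip concatenation, a final 1x1 projection, and
// the network input added to the projection output (residual output).
// Training is mean-squared error with Adam; forward/backward are im2col +
// single-precision GEMM on one CPU core.
//
// Layout: activations are (batch * H * W) x channels, spatial index
// p = x + H*y within an image (column-major in x, matching R matrices).
// Pixels-in-rows makes every GEMM tall-and-skinny (fast with OpenBLAS),
// im2col a set of shifted column copies, and skip concatenation a plain
// column block copy. Large buffers persist across batches.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Conv {
  int cin = 0, cout = 0, k = 3;
  fmat W; fvec b;        // W is (cin*k*k) x cout
  fmat mW, vW; fvec mb, vb;
  fmat gW; fvec gb;
  void init(int cin_, int cout_, int k_, std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_;
    W.set_size(cin * k * k, cout);
    std::normal_distribution<float> he(0.f, std::sqrt(2.f / (cin * k * k)));
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = he(rng);
    b.zeros(cout);
    mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    mb.zeros(cout); vb.zeros(cout);
  }
  void adam(double lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    float c1 = 1.0f - std::pow(b1, (float)t), c2 = 1.0f - std::pow(b2, (float)t);
    mW = b1 * mW + (1 - b1) * gW; vW = b2 * vW + (1 - b2) * arma::square(gW);
    mb = b1 * mb + (1 - b1) * gb; vb = b2 * vb + (1 - b2) * arma::square(gb);
    W -= (float)lr * (mW / c1) / (arma::sqrt(vW / c2) + eps);
    b -= (float)lr * (mb / c1) / (arma::sqrt(vb / c2) + eps);
  }
};

// ---------------------------------------------------------------------------
// spatial primitives
// ---------------------------------------------------------------------------

// col[:, o*cin + c] = A[:, c] shifted by offset o = (dx, dy); zero padded.
// The shifted copy is one memcpy per image per channel, with the x-border
// rows (where x + dx leaves [0, H)) zeroed afterwards.
static void im2col3(const fmat& A, int B, int H, int W, fmat& col) {
  const int cin = A.n_cols, P = H * W;
  col.set_size((arma::uword)B * P, (arma::uword)cin * 9);
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      const int o = (dy + 1) * 3 + (dx + 1);
      const int s = dx + H * dy;                 // flat spatial shift
      const int lo = std::max(0, -s), hi = P - std::max(0, s);  // dest rows
      for (int c = 0; c < cin; ++c) {
        float* dst = col.colptr((arma::uword)o * cin + c);
        const float* src = A.colptr(c);
        for (int b = 0; b < B; ++b) {
          float* d = dst + (arma::uword)b * P;
          const float* sp = src + (arma::uword)b * P;
          if (lo > 0) std::fill(d, d + lo, 0.f);
          if (hi < P) std::fill(d + hi, d + P, 0.f);
          std::copy(sp + lo + s, sp + hi + s, d + lo);
        }
        // zero the x-border rows the flat shift wrapped across
        if (dx != 0) {
          const int xbad = (dx > 0) ? H - 1 : 0;
          for (int b = 0; b < B; ++b)
            for (int y = 0; y < W; ++y) {
              arma::uword r = (arma::uword)b * P + xbad + (arma::uword)H * y;
              dst[r] = 0.f;
            }
        }
      }
    }
}

// dA[:, c] += sum over offsets of dcol[:, o*cin + c] shifted back
static void col2im3(const fmat& dcol, int B, int H, int W, fmat& dA) {
  const int cin = dA.n_cols, P = H * W;
  dA.zeros();
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      const int o = (dy + 1) * 3 + (dx + 1);
      const int s = dx + H * dy;
      const int lo = std::max(0, -s), hi = P - std::max(0, s);
      for (int c = 0; c < cin; ++c) {
        const float* src = dcol.colptr((arma::uword)o * cin + c);
        float* dst = dA.colptr(c);
        for (int b = 0; b < B; ++b) {
          const float* sp = src + (arma::uword)b * P;
          float* d = dst + (arma::uword)b * P;
          if (dx == 0) {
            for (int r = lo; r < hi; ++r) d[r + s] += sp[r];
          } else {
            const int xbad = (dx > 0) ? H - 1 : 0;
            for (int r = lo; r < hi; ++r) {
              int x = (r - (r / H) * H);
              if (x == xbad) continue;
              d[r + s] += sp[r];
            }
          }
        }
      }
    }
}

// out = relu(col * W + b); bias add and activation fused per column
static void conv_apply(Conv& cv, const fmat& col, fmat& out, bool relu) {
  out = col * cv.W;
  for (int c = 0; c < cv.cout; ++c) {
    float* oc = out.colptr(c);
    const float bc = cv.b[c];
    const arma::uword n = out.n_rows;
    if (relu)
      for (arma::uword i = 0; i < n; ++i) {
        float v = oc[i] + bc; oc[i] = v < 0.f ? 0.f : v;
      }
    else
      for (arma::uword i = 0; i < n; ++i) oc[i] += bc;
  }
}

static void relu_mask(fmat& g, const fmat& act) {
  float* gp = g.memptr(); const float* ap = act.memptr();
  for (arma::uword i = 0; i < g.n_elem; ++i)
    if (ap[i] <= 0.f) gp[i] = 0.f;
}

static void maxpool(const fmat& A, int B, int H, int W, fmat& out,
                    arma::umat& idx) {
  const int C = A.n_cols, Ho = H / 2, Wo = W / 2, P = H * W, Po = Ho * Wo;
  out.set_size((arma::uword)B * Po, C);
  idx.set_size((arma::uword)B * Po, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* op = out.colptr(c);
    arma::uword* ip = idx.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int y = 0; y < Wo; ++y)
        for (int x = 0; x < Ho; ++x) {
          arma::uword po = (arma::uword)b * Po + x + (arma::uword)Ho * y;
          arma::uword s0 = (arma::uword)b * P + 2 * x + (arma::uword)H * (2 * y);
          float best = a[s0]; arma::uword bi = s0;
          if (a[s0 + 1] > best) { best = a[s0 + 1]; bi = s0 + 1; }
          if (a[s0 + H] > best) { best = a[s0 + H]; bi = s0 + H; }
          if (a[s0 + H + 1] > best) { best = a[s0 + H + 1]; bi = s0 + H + 1; }
          op[po] = best; ip[po] = bi;
        }
  }
}

static void maxpool_back(const fmat& dY, const arma::umat& idx,
                         arma::uword nrow_in, fmat& dA) {
  dA.zeros(nrow_in, dY.n_cols);
  for (int c = 0; c < (int)dY.n_cols; ++c) {
    const float* dp = dY.colptr(c);
    const arma::uword* ip = idx.colptr(c);
    float* d = dA.colptr(c);
    for (arma::uword p = 0; p < dY.n_rows; ++p) d[ip[p]] += dp[p];
  }
}

// nearest 2x2 upsample of A (coarse H x W) written into `ncols` columns of
// `dst` starting at column `c0`
static void upsample2_into(const fmat& A, int B, int H, int W, fmat& dst,
                           int c0) {
  const int C = A.n_cols, Ho = H * 2, Wo = W * 2, P = H * W, Po = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* d = dst.colptr(c0 + c);
    for (int b = 0; b < B; ++b)
      for (int y = 0; y < Wo; ++y) {
        const float* ar = a + (arma::uword)b * P + (arma::uword)H * (y / 2);
        float* dr = d + (arma::uword)b * Po + (arma::uword)Ho * y;
        for (int x = 0; x < Ho; ++x) dr[x] = ar[x / 2];
      }
  }
}

static void upsample2_back(const fmat& dY, int B, int H, int W, int c0,
                           fmat& dA) {
  // H, W are the coarse (output) dims of dA; dY columns start at c0
  const int C = dA.n_cols, Ho = H * 2, Wo = W * 2, P = H * W, Po = Ho * Wo;
  dA.zeros((arma::uword)B * P, C);
  for (int c = 0; c < C; ++c) {
    const float* s = dY.colptr(c0 + c);
    float* d = dA.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int y = 0; y < Wo; ++y) {
        const float* sr = s + (arma::uword)b * Po + (arma::uword)Ho * y;
        float* dr = d + (arma::uword)b * P + (arma::uword)H * (y / 2);
        for (int x = 0; x < Ho; ++x) dr[x / 2] += sr[x];
      }
  }
}

// ---------------------------------------------------------------------------
// network
// ---------------------------------------------------------------------------

struct Level {
  fmat col1, col2;   // im2col caches
  fmat a1, a2;       // post-ReLU activations
  fmat pooled;       // encoder only
  arma::umat pidx;
  fmat cat;          // decoder concat input [upsampled | skip]
};

struct Net {
  int depth, base, H, W;
  std::vector<Conv> enc, dec;
  Conv fin;
  std::vector<Level> elv, dlv;
  fmat fin_out;

  int ch(int level) const { return base << (level - 1); }

  void init(int depth_, int base_, int H_, int W_, unsigned seed) {
    depth = depth_; base = base_; H = H_; W = W_;
    std::mt19937 rng(seed);
    enc.resize(2 * depth); dec.resize(2 * depth);
    elv.resize(depth); dlv.resize(depth);
    int cin = 1;
    for (int l = 1; l <= depth; ++l) {
      enc[2 * (l - 1)].init(cin, ch(l), 3, rng);
      enc[2 * (l - 1) + 1].init(ch(l), ch(l), 3, rng);
      cin = ch(l);
    }
    for (int l = depth; l >= 1; --l) {
      // the upsampled stream entering level l carries ch(l+1) channels
      // (ch(depth) from the bottleneck at the deepest level), concatenated
      // with the ch(l)-channel encoder skip
      int up_c = (l == depth) ? ch(depth) : ch(l + 1);
      int i = 2 * (depth - l);
      dec[i].init(up_c + ch(l), ch(l), 3, rng);
      dec[i + 1].init(ch(l), ch(l), 3, rng);
    }
    fin.init(base, 1, 1, rng);
    fin.W.zeros();  // start as the exact identity map (residual output)
  }

  std::vector<Conv*> all() {
    std::vector<Conv*> v;
    for (auto& c : enc) v.push_back(&c);
    for (auto& c : dec) v.push_back(&c);
    v.push_back(&fin);
    return v;
  }

  void forward(const fmat& x, int B, fmat& out) {
    int h = H, w = W;
    const fmat* a = &x;
    for (int l = 1; l <= depth; ++l) {
      Level& L = elv[l - 1];
      im2col3(*a, B, h, w, L.col1);
      conv_apply(enc[2 * (l - 1)], L.col1, L.a1, true);
      im2col3(L.a1, B, h, w, L.col2);
      conv_apply(enc[2 * (l - 1) + 1], L.col2, L.a2, true);
      maxpool(L.a2, B, h, w, L.pooled, L.pidx);
      a = &L.pooled;
      h /= 2; w /= 2;
    }
    for (int l = depth; l >= 1; --l) {
      Level& D = dlv[depth - l];
      const fmat& skip = elv[l - 1].a2;
      const int up_c = a->n_cols;
      D.cat.set_size(skip.n_rows, up_c + skip.n_cols);
      upsample2_into(*a, B, h, w, D.cat, 0);
      h *= 2; w *= 2;
      for (int c = 0; c < (int)skip.n_cols; ++c)
        std::copy(skip.colptr(c), skip.colptr(c) + skip.n_rows,
                  D.cat.colptr(up_c + c));
      int i = 2 * (depth - l);
      im2col3(D.cat, B, h, w, D.col1);
      conv_apply(dec[i], D.col1, D.a1, true);
      im2col3(D.a1, B, h, w, D.col2);
      conv_apply(dec[i + 1], D.col2, D.a2, true);
      a = &D.a2;
    }
    conv_apply(fin, *a, fin_out, false);  // 1x1: col == activation
    out = fin_out + x;
  }

  void backward(const fmat& dOut, int B) {
    // final 1x1: its "col" is the level-1 decoder output
    fmat& top_a2 = dlv[depth - 1].a2;
    fin.gW = top_a2.t() * dOut;
    fin.gb = arma::sum(dOut, 0).t();
    fmat da = dOut * fin.W.t();
    int h = H, w = W;
    std::vector<fmat> dskip(depth + 1);
    for (int l = 1; l <= depth; ++l) {
      Level& D = dlv[depth - l];
      int i = 2 * (depth - l);
      relu_mask(da, D.a2);
      Conv& c2 = dec[i + 1];
      c2.gW = D.col2.t() * da;
      c2.gb = arma::sum(da, 0).t();
      fmat dcol = da * c2.W.t();
      fmat da1(da.n_rows, c2.cin);
      col2im3(dcol, B, h, w, da1);
      relu_mask(da1, D.a1);
      Conv& c1 = dec[i];
      c1.gW = D.col1.t() * da1;
      c1.gb = arma::sum(da1, 0).t();
      fmat dcat_col = da1 * c1.W.t();
      fmat dcat(da1.n_rows, c1.cin);
      col2im3(dcat_col, B, h, w, dcat);
      const int up_c = c1.cin - ch(l);
      dskip[l] = dcat.cols(up_c, dcat.n_cols - 1);
      fmat dup((arma::uword)B * (h / 2) * (w / 2), up_c);
      upsample2_back(dcat, B, h / 2, w / 2, 0, dup);
      da = std::move(dup);
      h /= 2; w /= 2;
    }
    for (int l = depth; l >= 1; --l) {
      Level& L = elv[l - 1];
      int hh = H >> (l - 1), ww = W >> (l - 1);
      fmat da2;
      maxpool_back(da, L.pidx, (arma::uword)B * hh * ww, da2);
      da2 += dskip[l];
      relu_mask(da2, L.a2);
      Conv& c2 = enc[2 * (l - 1) + 1];
      c2.gW = L.col2.t() * da2;
      c2.gb = arma::sum(da2, 0).t();
      fmat dcol = da2 * c2.W.t();
      fmat da1(da2.n_rows, c2.cin);
      col2im3(dcol, B, hh, ww, da1);
      relu_mask(da1, L.a1);
      Conv& c1 = enc[2 * (l - 1)];
      c1.gW = L.col1.t() * da1;
      c1.gb = arma::sum(da1, 0).t();
      if (l > 1) {
        fmat dcol1 = da1 * c1.W.t();
        da.set_size(da1.n_rows, c1.cin);
        col2im3(dcol1, B, hh, ww, da);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// weight (de)serialisation — R sees W as (cout) x (cin*k*k) like the
// conventional layout, transposed on the way in/out
// ---------------------------------------------------------------------------

static List weights_out(Net& net) {
  List out;
  for (Conv* c : net.all()) {
    NumericMatrix W(c->W.n_cols, c->W.n_rows);
    for (arma::uword j = 0; j < c->W.n_rows; ++j)
      for (arma::uword i = 0; i < c->W.n_cols; ++i)
        W(i, j) = c->W(j, i);
    NumericVector b(c->b.n_elem);
    for (arma::uword j = 0; j < c->b.n_elem; ++j) b[j] = c->b[j];
    out.push_back(W); out.push_back(b);
  }
  return out;
}

static void weights_in(Net& net, List w) {
  int i = 0;
  for (Conv* c : net.all()) {
    NumericMatrix W = w[2 * i]; NumericVector b = w[2 * i + 1];
    if ((int)W.nrow() != (int)c->W.n_cols || (int)W.ncol() != (int)c->W.n_rows)
      stop("weight shape mismatch at conv %d", i);
    for (int r = 0; r < W.nrow(); ++r)
      for (int cc = 0; cc < W.ncol(); ++cc)
        c->W(cc, r) = (float)W(r, cc);
    for (int j = 0; j < b.length(); ++j) c->b[j] = (float)b[j];
    ++i;
  }
}

static void fill_batch(const arma::cube& X, const std::vector<arma::uword>& ord,
                       arma::uword s, int B, fmat& x) {
  arma::uword P = X.n_rows * X.n_cols;
  x.set_size((arma::uword)B * P, 1);
  for (int b = 0; b < B; ++b) {
    const double* src = X.slice(ord[s + b]).memptr();
    float* dst = x.memptr() + (arma::uword)b * P;
    for (arma::uword j = 0; j < P; ++j) dst[j] = (float)src[j];
  }
}

static double eval_loss(Net& net, const arma::cube& X, const arma::cube& Y,
                        int batch) {
  arma::uword N = X.n_slices, P = X.n_rows * X.n_cols;
  if (N == 0) return NA_REAL;
  std::vector<arma::uword> ord(N);
  for (arma::uword i = 0; i < N; ++i) ord[i] = i;
  double se = 0.0;
  fmat x, y, out;
  for (arma::uword s = 0; s < N; s += batch) {
    int B = (int)std::min((arma::uword)batch, N - s);
    fill_batch(X, ord, s, B, x);
    fill_batch(Y, ord, s, B, y);
    net.forward(x, B, out);
    const float* o = out.memptr(); const float* t = y.memptr();
    for (arma::uword i = 0; i < out.n_elem; ++i) {
      double d = (double)o[i] - (double)t[i];
      se += d * d;
    }
  }
  return se / ((double)N * P);
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_init(int depth, int base, int H, int W, int seed) {
  Net net; net.init(depth, base, H, W, (unsigned)seed);
  return weights_out(net);
}

// [[Rcpp::export]]
List cpp_unet_train(const arma::cube& train_x, const arma::cube& train_y,
                    const arma::cube& val_x, const arma::cube& val_y,
                    int depth, int base, int epochs, int batch,
                    const NumericVector& lr_per_epoch,
                    int seed, Nullable<List> init_weights = R_NilValue) {
  int H = train_x.n_rows, W = train_x.n_cols;
  Net net; net.init(depth, base, H, W, (unsigned)seed);
  if (init_weights.isNotNull()) weights_in(net, List(init_weights));
  arma::uword N = train_x.n_slices, P = (arma::uword)H * W;
  std::vector<arma::uword> order(N);
  for (arma::uword i = 0; i < N; ++i) order[i] = i;
  std::mt19937 shuf((unsigned)seed + 1000003u);
  NumericVector tr_loss(epochs), va_loss(epochs);
  int t = 0;
  fmat x, y, out;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), shuf);
    double se = 0.0; arma::uword seen = 0;
    for (arma::uword s = 0; s < N; s += batch) {
      int B = (int)std::min((arma::uword)batch, N - s);
      fill_batch(train_x, order, s, B, x);
      fill_batch(train_y, order, s, B, y);
      net.forward(x, B, out);
      out -= y;
      double batch_se = 0.0;
      for (arma::uword i = 0; i < out.n_elem; ++i)
        batch_se += (double)out[i] * (double)out[i];
      se += batch_se; seen += (arma::uword)B * P;
      out *= 2.0f / (float)((arma::uword)B * P);
      net.backward(out, B);
      ++t;
      for (Conv* c : net.all()) c->adam(lr_per_epoch[ep], t);
      if (!std::isfinite(batch_se))
        stop("training diverged at epoch %d (loss is not finite)", ep + 1);
    }
    tr_loss[ep] = se / (double)seen;
    va_loss[ep] = eval_loss(net, val_x, val_y, batch);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_out(net),
                      _["train_loss"] = tr_loss, _["val_loss"] = va_loss);
}

// [[Rcpp::export]]
List cpp_unet_grad(List weights, const arma::mat& x, const arma::mat& y,
                   int depth, int base) {
  // loss and analytic gradients for one image; used by the
  // finite-difference gradient check in the tests
  int H = x.n_rows, W = x.n_cols;
  Net net; net.init(depth, base, H, W, 1u);
  weights_in(net, weights);
  fmat xm((arma::uword)H * W, 1), ym((arma::uword)H * W, 1);
  for (int j = 0; j < H * W; ++j) { xm[j] = (float)x[j]; ym[j] = (float)y[j]; }
  fmat out;
  net.forward(xm, 1, out);
  out -= ym;
  double se = 0.0;
  for (arma::uword i = 0; i < out.n_elem; ++i)
    se += (double)out[i] * (double)out[i];
  out *= 2.0f / (float)out.n_elem;
  net.backward(out, 1);
  List grads;
  for (Conv* c : net.all()) {
    NumericMatrix gW(c->gW.n_cols, c->gW.n_rows);
    for (arma::uword j = 0; j < c->gW.n_rows; ++j)
      for (arma::uword i = 0; i < c->gW.n_cols; ++i)
        gW(i, j) = c->gW(j, i);
    NumericVector gb(c->gb.n_elem);
    for (arma::uword j = 0; j < c->gb.n_elem; ++j) gb[j] = c->gb[j];
    grads.push_back(gW); grads.push_back(gb);
  }
  return List::create(_["loss"] = se / out.n_elem, _["grads"] = grads);
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(List weights, const arma::mat& x,
                               int depth, int base) {
  int H = x.n_rows, W = x.n_cols;
  Net net; net.init(depth, base, H, W, 1u);
  weights_in(net, weights);
  fmat xm((arma::uword)H * W, 1);
  const double* src = x.memptr();
  for (int j = 0; j < H * W; ++j) xm[j] = (float)src[j];
  fmat out;
  net.forward(xm, 1, out);
  NumericMatrix res(H, W);
  for (int j = 0; j < H * W; ++j) res[j] = out[j];
  return res;
}
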