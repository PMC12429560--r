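// Residual U-Net core: im2col/GEMM convolutions on single-precision
// Armadillo matrices. Feature maps are stored as (H*W) x C matrices in
// column-major pixel order (p = r + c*H), matching R's matrix layout.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::Named;
using Rcpp::stop;

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 "same" convolution with zero padding.
// Column order of the patch matrix: [channel][dc][dr].

static fmat im2col3(const fmat& X, int H, int W) {
  const int C = X.n_cols, np = H * W;
  fmat out(np, 9 * C);
  int col = 0;
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        float* dst = out.colptr(col++);
        std::memset(dst, 0, np * sizeof(float));
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        if (r1 <= r0) continue;
        for (int c = c0; c < c1; ++c) {
          const float* s = src + (size_t)(c + dc) * H + dr;
          float* d = dst + (size_t)c * H;
          std::memcpy(d + r0, s + r0, (size_t)(r1 - r0) * sizeof(float));
        }
      }
    }
  }
  return out;
}

static fmat col2im3(const fmat& cols, int H, int W, int C) {
  fmat out(H * W, C, fill::zeros);
  int col = 0;
  for (int ch = 0; ch < C; ++ch) {
    float* dst = out.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const float* src = cols.colptr(col++);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        if (r1 <= r0) continue;
        for (int c = c0; c < c1; ++c) {
          float* d = dst + (size_t)(c + dc) * H + dr;
          const float* s = src + (size_t)c * H;
          for (int r = r0; r < r1; ++r) d[r] += s[r];
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Parameters

struct Param {
  fmat W;            // (Cin*k*k) x Cout
  frowvec b;         // 1 x Cout
  fmat gW; frowvec gb;
  fmat mW, vW; frowvec mb, vb;
  int k = 3;
  void init_state() {
    gW.zeros(W.n_rows, W.n_cols); gb.zeros(b.n_elem);
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
};

struct NetSpec {
  int depth, base, n_classes;
  bool residual;
  std::vector<int> ch;  // channels per level, length depth
};

static NetSpec parse_spec(const List& spec) {
  NetSpec s;
  s.depth = Rcpp::as<int>(spec["depth"]);
  s.base = Rcpp::as<int>(spec["base_channels"]);
  s.n_classes = Rcpp::as<int>(spec["n_classes"]);
  s.residual = Rcpp::as<bool>(spec["residual_blocks"]);
  if (s.depth < 2 || s.base < 4) stop("invalid U-Net spec");
  s.ch.resize(s.depth);
  for (int l = 0; l < s.depth; ++l) s.ch[l] = s.base << l;
  return s;
}

// Canonical parameter order:
//   stem conv3 (1 -> c1)
//   enc level l = 1..D:  convA3, convB3, [skip1 if cin != cout and residual]
//   dec level l = D-1..1: upproj1 (c_{l+1} -> c_l), convA3, convB3,
//                         [skip1 (2c_l -> c_l) if residual]
//   head conv1 (c1 -> K)
static void shape_list(const NetSpec& s, std::vector<std::array<int, 3>>& out) {
  out.clear();
  auto add = [&](int k, int cin, int cout) {
    out.push_back({k, cin, cout});
  };
  add(3, 1, s.ch[0]);
  for (int l = 0; l < s.depth; ++l) {
    int cin = (l == 0) ? s.ch[0] : s.ch[l - 1];
    add(3, cin, s.ch[l]);
    add(3, s.ch[l], s.ch[l]);
    if (s.residual && cin != s.ch[l]) add(1, cin, s.ch[l]);
  }
  for (int l = s.depth - 2; l >= 0; --l) {
    add(1, s.ch[l + 1], s.ch[l]);
    add(3, 2 * s.ch[l], s.ch[l]);
    add(3, s.ch[l], s.ch[l]);
    if (s.residual) add(1, 2 * s.ch[l], s.ch[l]);
  }
  add(1, s.ch[0], s.n_classes);
}

// [[Rcpp::export]]
List unet_shapes_cpp(List spec) {
  NetSpec s = parse_spec(spec);
  std::vector<std::array<int, 3>> shp;
  shape_list(s, shp);
  List out(shp.size());
  for (size_t i = 0; i < shp.size(); ++i)
    out[i] = IntegerVector::create(
        Named("k") = shp[i][0], Named("cin") = shp[i][1],
        Named("cout") = shp[i][2]);
  return out;
}

static std::vector<Param> load_params(const NetSpec& s, const List& weights) {
  std::vector<std::array<int, 3>> shp;
  shape_list(s, shp);
  List wl = weights["W"], bl = weights["b"];
  if ((size_t)wl.size() != shp.size()) stop("weight list length mismatch");
  std::vector<Param> ps(shp.size());
  for (size_t i = 0; i < shp.size(); ++i) {
    NumericMatrix w = wl[i];
    NumericVector b = bl[i];
    const int rows = shp[i][0] * shp[i][0] * shp[i][1];
    if (w.nrow() != rows || w.ncol() != shp[i][2] || b.size() != shp[i][2])
      stop("weight %d has wrong shape", (int)i + 1);
    ps[i].k = shp[i][0];
    ps[i].W = conv_to<fmat>::from(Rcpp::as<mat>(w));
    ps[i].b = conv_to<frowvec>::from(Rcpp::as<rowvec>(b));
    ps[i].init_state();
  }
  return ps;
}

static List dump_params(const std::vector<Param>& ps) {
  List wl(ps.size()), bl(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    wl[i] = Rcpp::wrap(conv_to<mat>::from(ps[i].W));
    bl[i] = Rcpp::wrap(conv_to<rowvec>::from(ps[i].b));
  }
  return List::create(Named("W") = wl, Named("b") = bl);
}

// ---------------------------------------------------------------------------
// Layer forward/backward

static fmat conv_fwd(const Param& p, const fmat& X, int H, int W) {
  fmat Y = (p.k == 3) ? fmat(im2col3(X, H, W) * p.W) : fmat(X * p.W);
  Y.each_row() += p.b;
  return Y;
}

// dY -> dX; accumulates gradients into p.
static fmat conv_bwd(Param& p, const fmat& X, const fmat& dY, int H, int W) {
  p.gb += sum(dY, 0);
  if (p.k == 3) {
    fmat cols = im2col3(X, H, W);
    p.gW += cols.t() * dY;
    return col2im3(dY * p.W.t(), H, W, X.n_cols);
  }
  p.gW += X.t() * dY;
  return dY * p.W.t();
}

static inline void relu_(fmat& X) {
  X.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// masks dY in place using post-activation values A (A > 0 <=> pre > 0)
static inline void relu_bwd_(fmat& dY, const fmat& A) {
  dY %= conv_to<fmat>::from(A > 0.0f);
}

static fmat maxpool2(const fmat& X, int H, int W, umat& argmax) {
  const int Ho = H / 2, Wo = W / 2, C = X.n_cols;
  fmat out(Ho * Wo, C);
  argmax.set_size(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    float* dst = out.colptr(ch);
    uword* am = argmax.colptr(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const size_t i00 = (size_t)(2 * c) * H + 2 * r;
        const size_t idx[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
        int best = 0;
        for (int j = 1; j < 4; ++j) if (src[idx[j]] > src[idx[best]]) best = j;
        const size_t o = (size_t)c * Ho + r;
        dst[o] = src[idx[best]];
        am[o] = idx[best];
      }
    }
  }
  return out;
}

static fmat maxpool2_bwd(const fmat& dY, const umat& argmax, int H, int W) {
  const int C = dY.n_cols;
  fmat out(H * W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* s = dY.colptr(ch);
    const uword* am = argmax.colptr(ch);
    float* d = out.colptr(ch);
    for (size_t i = 0; i < dY.n_rows; ++i) d[am[i]] += s[i];
  }
  return out;
}

static fmat upsample2(const fmat& X, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W, C = X.n_cols;
  fmat out(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    float* dst = out.colptr(ch);
    for (int c = 0; c < Wo; ++c) {
      const float* s = src + (size_t)(c / 2) * H;
      float* d = dst + (size_t)c * Ho;
      for (int r = 0; r < Ho; ++r) d[r] = s[r / 2];
    }
  }
  return out;
}

static fmat upsample2_bwd(const fmat& dY, int H, int W) {
  // H, W are the *input* (coarse) dimensions
  const int Ho = 2 * H, C = dY.n_cols;
  fmat out(H * W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* s = dY.colptr(ch);
    float* d = out.colptr(ch);
    for (int c = 0; c < 2 * W; ++c) {
      float* dcol = d + (size_t)(c / 2) * H;
      const float* scol = s + (size_t)c * Ho;
      for (int r = 0; r < Ho; ++r) dcol[r / 2] += scol[r];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Residual block

struct BlockCache {
  fmat x_in;   // block input
  fmat hA;     // post-relu of convA
  fmat out;    // block output (post final relu)
};

struct Net {
  NetSpec s;
  std::vector<Param> ps;
  // parameter indices
  int i_stem = 0;
  std::vector<int> enc_a, enc_b, enc_s;   // -1 where absent
  std::vector<int> dec_up, dec_a, dec_b, dec_s;
  int i_head = 0;

  void index_params() {
    int i = 0;
    i_stem = i++;
    enc_a.assign(s.depth, -1); enc_b.assign(s.depth, -1);
    enc_s.assign(s.depth, -1);
    for (int l = 0; l < s.depth; ++l) {
      int cin = (l == 0) ? s.ch[0] : s.ch[l - 1];
      enc_a[l] = i++; enc_b[l] = i++;
      if (s.residual && cin != s.ch[l]) enc_s[l] = i++;
    }
    dec_up.assign(s.depth, -1); dec_a.assign(s.depth, -1);
    dec_b.assign(s.depth, -1); dec_s.assign(s.depth, -1);
    for (int l = s.depth - 2; l >= 0; --l) {
      dec_up[l] = i++; dec_a[l] = i++; dec_b[l] = i++;
      if (s.residual) dec_s[l] = i++;
    }
    i_head = i++;
    if ((size_t)i != ps.size()) stop("internal: parameter indexing mismatch");
  }

  fmat block_fwd(int ia, int ib, int is, const fmat& X, int H, int W,
                 BlockCache* cache) const {
    fmat h = conv_fwd(ps[ia], X, H, W);
    relu_(h);
    fmat out = conv_fwd(ps[ib], h, H, W);
    if (s.residual) {
      if (is >= 0) out += conv_fwd(ps[is], X, H, W);
      else out += X;
    }
    relu_(out);
    if (cache) { cache->x_in = X; cache->hA = std::move(h); cache->out = out; }
    return out;
  }

  fmat block_bwd(int ia, int ib, int is, const BlockCache& c, fmat dOut,
                 int H, int W) {
    relu_bwd_(dOut, c.out);
    fmat dX(c.x_in.n_rows, c.x_in.n_cols, fill::zeros);
    if (s.residual) {
      if (is >= 0) dX += conv_bwd(ps[is], c.x_in, dOut, H, W);
      else dX += dOut;
    }
    fmat dh = conv_bwd(ps[ib], c.hA, dOut, H, W);
    relu_bwd_(dh, c.hA);
    dX += conv_bwd(ps[ia], c.x_in, dh, H, W);
    return dX;
  }
};

struct FwdCache {
  fmat x_in;
  fmat stem_out;
  std::vector<BlockCache> enc, dec;
  std::vector<umat> pool_arg;
  std::vector<fmat> up_in;      // decoder upsample inputs (coarse features)
  fmat head_in;
};

// Forward pass. x: npix x 1 normalized input. Returns logits npix x K.
static fmat net_forward(Net& net, const fmat& x, int H, int W,
                        FwdCache* cc) {
  const int D = net.s.depth;
  std::vector<fmat> feats(D);
  std::vector<int> Hs(D), Ws(D);
  fmat h = conv_fwd(net.ps[net.i_stem], x, H, W);
  relu_(h);
  if (cc) { cc->x_in = x; cc->stem_out = h; cc->enc.resize(D);
            cc->dec.resize(D); cc->pool_arg.resize(D); cc->up_in.resize(D); }
  int Hc = H, Wc = W;
  for (int l = 0; l < D; ++l) {
    if (l > 0) {
      umat am;
      h = maxpool2(h, Hc, Wc, am);
      Hc /= 2; Wc /= 2;
      if (cc) cc->pool_arg[l] = std::move(am);
    }
    h = net.block_fwd(net.enc_a[l], net.enc_b[l], net.enc_s[l], h, Hc, Wc,
                      cc ? &cc->enc[l] : nullptr);
    feats[l] = h; Hs[l] = Hc; Ws[l] = Wc;
  }
  for (int l = D - 2; l >= 0; --l) {
    if (cc) cc->up_in[l] = h;
    fmat up = upsample2(h, Hc, Wc);
    Hc *= 2; Wc *= 2;
    fmat proj = conv_fwd(net.ps[net.dec_up[l]], up, Hc, Wc);
    fmat cat = join_rows(proj, feats[l]);
    h = net.block_fwd(net.dec_a[l], net.dec_b[l], net.dec_s[l], cat, Hc, Wc,
                      cc ? &cc->dec[l] : nullptr);
  }
  if (cc) cc->head_in = h;
  return conv_fwd(net.ps[net.i_head], h, H, W);
}

// Softmax cross-entropy over pixels; y in {0..K-1}. Returns loss, fills
// dlogits (already divided by npix) and accuracy.
static double softmax_ce(const fmat& logits, const Col<int>& y, fmat& dlogits,
                         double& acc) {
  const int np = logits.n_rows, K = logits.n_cols;
  dlogits.set_size(np, K);
  double loss = 0.0;
  size_t correct = 0;
  for (int i = 0; i < np; ++i) {
    float m = logits(i, 0);
    int arg = 0;
    for (int k = 1; k < K; ++k)
      if (logits(i, k) > m) { m = logits(i, k); arg = k; }
    double Z = 0.0;
    for (int k = 0; k < K; ++k) Z += std::exp((double)logits(i, k) - m);
    const int yi = y(i);
    loss += -((double)logits(i, yi) - m - std::log(Z));
    for (int k = 0; k < K; ++k)
      dlogits(i, k) = (float)(std::exp((double)logits(i, k) - m) / Z
                              - (k == yi ? 1.0 : 0.0));
    if (arg == yi) ++correct;
  }
  dlogits /= (float)np;
  acc = (double)correct / np;
  return loss / np;
}

static void net_backward(Net& net, const FwdCache& cc, const fmat& dlogits,
                         int H, int W) {
  const int D = net.s.depth;
  int Hc = H, Wc = W;
  fmat d = conv_bwd(net.ps[net.i_head], cc.head_in, dlogits, H, W);
  std::vector<fmat> dfeats(D);  // grads flowing into encoder outputs via skips
  for (int l = 0; l < D - 1; ++l) {
    // decoder level l operates at resolution H/2^l
    d = net.block_bwd(net.dec_a[l], net.dec_b[l], net.dec_s[l], cc.dec[l],
                      std::move(d), Hc, Wc);
    const int cl = net.s.ch[l];
    fmat dproj = d.cols(0, cl - 1);
    dfeats[l] = d.cols(cl, 2 * cl - 1);
    fmat dup = conv_bwd(net.ps[net.dec_up[l]], upsample2(cc.up_in[l], Hc / 2, Wc / 2),
                        dproj, Hc, Wc);
    d = upsample2_bwd(dup, Hc / 2, Wc / 2);
    Hc /= 2; Wc /= 2;
  }
  // d now carries the gradient at the bottleneck output (level D-1)
  for (int l = D - 1; l >= 0; --l) {
    if (l < D - 1) d += dfeats[l];
    d = net.block_bwd(net.enc_a[l], net.enc_b[l], net.enc_s[l], cc.enc[l],
                      std::move(d), Hc, Wc);
    if (l > 0) {
      d = maxpool2_bwd(d, cc.pool_arg[l], Hc * 2, Wc * 2);
      Hc *= 2; Wc *= 2;
    }
  }
  // gradient w.r.t. stem output; image gradient itself is discarded
  relu_bwd_(d, cc.stem_out);
  conv_bwd(net.ps[net.i_stem], cc.x_in, d, Hc, Wc);
}

// ---------------------------------------------------------------------------
// Exported entry points

static fmat normalize_tile(const fmat& raw, float gray_max) {
  fmat x = raw / gray_max;
  x -= 0.5f;
  return x;
}

static void vflip_mat(fmat& x, int H, int W) {
  for (int c = 0; c < W; ++c) {
    float* p = x.colptr(0) + (size_t)c * H;
    std::reverse(p, p + H);
  }
}

static void vflip_labels(Col<int>& y, int H, int W) {
  for (int c = 0; c < W; ++c) {
    int* p = y.memptr() + (size_t)c * H;
    std::reverse(p, p + H);
  }
}

// [[Rcpp::export]]
NumericMatrix unet_predict_cpp(NumericMatrix x, List spec, List weights,
                               double gray_max) {
  NetSpec s = parse_spec(spec);
  Net net; net.s = s; net.ps = load_params(s, weights); net.index_params();
  const int H = x.nrow(), W = x.ncol();
  const int div = 1 << (s.depth - 1);
  if (H % div != 0 || W % div != 0)
    stop("tile side must be divisible by 2^(depth-1)");
  fmat raw = conv_to<fmat>::from(Rcpp::as<mat>(x));
  raw.reshape(H * W, 1);
  fmat xin = normalize_tile(raw, (float)gray_max);
  fmat logits = net_forward(net, xin, H, W, nullptr);
  // probability of the striosome class (class index 2 in R, column 2)
  NumericMatrix out(H, W);
  for (int i = 0; i < H * W; ++i) {
    float m = logits(i, 0);
    for (int k = 1; k < s.n_classes; ++k) m = std::max(m, logits(i, k));
    double Z = 0.0;
    for (int k = 0; k < s.n_classes; ++k)
      Z += std::exp((double)logits(i, k) - m);
    out[i] = std::exp((double)logits(i, 1) - m) / Z;
  }
  return out;
}

struct TileSet {
  std::vector<fmat> x;          // raw gray values, npix x 1
  std::vector<Col<int>> y;      // 0/1 labels
  std::vector<int> H, W;
};

static TileSet load_tiles(const List& tiles_x, const List& tiles_y) {
  TileSet t;
  const int n = tiles_x.size();
  t.x.reserve(n); t.y.reserve(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix xm = tiles_x[i];
    Rcpp::IntegerMatrix ym = tiles_y[i];
    if (xm.nrow() != ym.nrow() || xm.ncol() != ym.ncol())
      stop("tile %d: image/label size mismatch", i + 1);
    const int H = xm.nrow(), W = xm.ncol();
    fmat xf(H * W, 1);
    Col<int> yv(H * W);
    for (int j = 0; j < H * W; ++j) { xf(j, 0) = (float)xm[j]; yv(j) = ym[j]; }
    t.x.push_back(std::move(xf));
    t.y.push_back(std::move(yv));
    t.H.push_back(H); t.W.push_back(W);
  }
  return t;
}

static void eval_tiles(Net& net, const TileSet& ts,
                       const std::vector<int>& idx, float gray_max,
                       double& loss_out, double& acc_out) {
  double loss = 0.0, acc = 0.0;
  fmat dl;
  for (int id : idx) {
    fmat xin = normalize_tile(ts.x[id], gray_max);
    fmat logits = net_forward(net, xin, ts.H[id], ts.W[id], nullptr);
    double a;
    loss += softmax_ce(logits, ts.y[id], dl, a);
    acc += a;
  }
  loss_out = loss / idx.size();
  acc_out = acc / idx.size();
}

// [[Rcpp::export]]
List unet_eval_cpp(List tiles_x, List tiles_y, List spec, List weights,
                   double gray_max) {
  NetSpec s = parse_spec(spec);
  Net net; net.s = s; net.ps = load_params(s, weights); net.index_params();
  TileSet ts = load_tiles(tiles_x, tiles_y);
  std::vector<int> idx(ts.x.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  double loss, acc;
  eval_tiles(net, ts, idx, (float)gray_max, loss, acc);
  return List::create(Named("loss") = loss, Named("accuracy") = acc);
}

static void adam_step(std::vector<Param>& ps, double lr, long t, double nb) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  for (Param& p : ps) {
    p.gW /= (float)nb; p.gb /= (float)nb;
    p.mW = 0.9f * p.mW + 0.1f * p.gW;
    p.vW = 0.999f * p.vW + 0.001f * square(p.gW);
    p.mb = 0.9f * p.mb + 0.1f * p.gb;
    p.vb = 0.999f * p.vb + 0.001f * square(p.gb);
    p.W -= (float)lr * (p.mW / c1) / (sqrt(p.vW / c2) + eps);
    p.b -= (float)lr * (p.mb / c1) / (sqrt(p.vb / c2) + eps);
    p.gW.zeros(); p.gb.zeros();
  }
}

// arm: 1 = vertical flip only; 2 = vertical flip + photometric (brightness
// jitter on the image only; hue/saturation are identity on single-channel
// tiles). Labels are never photometrically altered.
// [[Rcpp::export]]
List unet_train_cpp(List tiles_x, List tiles_y, List spec, List weights,
                    IntegerVector train_idx, IntegerVector test_idx,
                    int batch_size, int total_epochs, double lr, int arm,
                    double brightness_jitter, int tiles_per_epoch, int seed,
                    double gray_max, bool verbose) {
  NetSpec s = parse_spec(spec);
  Net net; net.s = s; net.ps = load_params(s, weights); net.index_params();
  TileSet ts = load_tiles(tiles_x, tiles_y);
  const float gm = (float)gray_max;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> te(test_idx.begin(), test_idx.end());
  for (int id : tr) if (id < 0 || id >= (int)ts.x.size()) stop("bad train index");
  for (int id : te) if (id < 0 || id >= (int)ts.x.size()) stop("bad test index");
  if (tr.empty() || te.empty()) stop("need >= 1 training and >= 1 held-out tile");

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  NumericVector train_loss(total_epochs), test_loss(total_epochs),
      test_acc(total_epochs);
  long t_adam = 0;
  double best_loss = datum::inf;
  int best_epoch = -1;
  std::vector<fmat> bestW;
  std::vector<frowvec> bestb;

  FwdCache cc;
  fmat dlogits;
  for (int ep = 0; ep < total_epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    int n_use = (int)tr.size();
    if (tiles_per_epoch > 0 && tiles_per_epoch < n_use) n_use = tiles_per_epoch;
    double ep_loss = 0.0;
    int in_batch = 0, done = 0;
    for (int i = 0; i < n_use; ++i) {
      const int id = tr[i];
      fmat xr = ts.x[id];
      Col<int> y = ts.y[id];
      const int H = ts.H[id], W = ts.W[id];
      if (unif(rng) < 0.5) { vflip_mat(xr, H, W); vflip_labels(y, H, W); }
      if (arm == 2) {
        const float f = (float)(1.0 + brightness_jitter * (2.0 * unif(rng) - 1.0));
        xr *= f;
        xr.clamp(0.0f, gm);
      }
      fmat xin = normalize_tile(xr, gm);
      fmat logits = net_forward(net, xin, H, W, &cc);
      double a;
      ep_loss += softmax_ce(logits, y, dlogits, a);
      net_backward(net, cc, dlogits, H, W);
      if (++in_batch == batch_size || i == n_use - 1) {
        adam_step(net.ps, lr, ++t_adam, (double)in_batch);
        in_batch = 0;
      }
      ++done;
      if (done % 64 == 0) Rcpp::checkUserInterrupt();
    }
    train_loss[ep] = ep_loss / n_use;
    double tl, ta;
    eval_tiles(net, ts, te, gm, tl, ta);
    test_loss[ep] = tl; test_acc[ep] = ta;
    if (tl < best_loss) {
      best_loss = tl; best_epoch = ep;
      bestW.clear(); bestb.clear();
      for (const Param& p : net.ps) { bestW.push_back(p.W); bestb.push_back(p.b); }
    }
    if (!std::isfinite(train_loss[ep]) || !std::isfinite(tl))
      stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << ": train " << train_loss[ep]
                  << " test " << tl << " acc " << ta << std::endl;
  }

  List final_w = dump_params(net.ps);
  for (size_t i = 0; i < net.ps.size(); ++i) {
    net.ps[i].W = bestW[i]; net.ps[i].b = bestb[i];
  }
  List best_w = dump_params(net.ps);
  return List::create(
      Named("train_loss") = train_loss, Named("test_loss") = test_loss,
      Named("test_accuracy") = test_acc,
      Named("selected_epoch") = best_epoch + 1,
      Named("best_weights") = best_w, Named("final_weights") = final_w);
}

// Single-tile loss and parameter gradients (used for finite-difference
// verification of the backward pass).
// [[Rcpp::export]]
List unet_lossgrad_cpp(NumericMatrix x, Rcpp::IntegerMatrix y, List spec,
                       List weights, double gray_max) {
  NetSpec s = parse_spec(spec);
  Net net; net.s = s; net.ps = load_params(s, weights); net.index_params();
  const int H = x.nrow(), W = x.ncol();
  fmat raw(H * W, 1);
  Col<int> yv(H * W);
  for (int j = 0; j < H * W; ++j) { raw(j, 0) = (float)x[j]; yv(j) = y[j]; }
  fmat xin = normalize_tile(raw, (float)gray_max);
  FwdCache cc;
  fmat dlogits;
  fmat logits = net_forward(net, xin, H, W, &cc);
  double acc;
  double loss = softmax_ce(logits, yv, dlogits, acc);
  net_backward(net, cc, dlogits, H, W);
  List gW(net.ps.size()), gb(net.ps.size());
  for (size_t i = 0; i < net.ps.size(); ++i) {
    gW[i] = Rcpp::wrap(conv_to<mat>::from(net.ps[i].gW));
    gb[i] = Rcpp::wrap(conv_to<rowvec>::from(net.ps[i].gb));
  }
  return List::create(Named("loss") = loss, Named("accuracy") = acc,
                      Named("grad_W") = gW, Named("grad_b") = gb);
}
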