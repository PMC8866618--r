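// Minimal encoder-decoder (U-Net) heatmap regressor with Adam/MSE training.
//
// Single-channel 2-D inputs, 3x3 convs (pad 1) + leaky-ReLU double blocks,
// 2x2 max pooling, nearest-neighbour upsampling, skip concatenation, final
// 1x1 linear conv.  Leaky activations (slope 0.1) keep gradients flowing on
// sparse heatmap targets, where plain ReLU nets can stall in the
// predict-zero-everywhere basin.  Batch size 1; all randomness (init,
// shuffling, augmentation) is supplied from R, so training is
// bit-reproducible for a fixed R seed.

static const double LEAK = 0.1;

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct ConvLayer {
  mat W;            // (Cin * k * k) x Cout
  vec b;            // Cout
  mat mW, vW;       // Adam first/second moments
  vec mb, vb;
  int cin, cout, k; // k = 3 (pad 1) or 1 (pad 0)
};

struct UNet {
  int depth, base;
  std::vector<ConvLayer> layers;
  long t;           // Adam step counter
};

static int chanAt(int base, int lev) { return base << lev; }

// layer plan: encoder double blocks (incl. bottleneck), decoder double
// blocks, final 1x1
static void layerPlan(int depth, int base, std::vector<std::array<int,3>>& plan) {
  plan.clear();
  for (int lev = 0; lev < depth; ++lev) {
    int cin = (lev == 0) ? 1 : chanAt(base, lev - 1);
    int c = chanAt(base, lev);
    plan.push_back({cin, c, 3});
    plan.push_back({c, c, 3});
  }
  for (int lev = depth - 2; lev >= 0; --lev) {
    int c = chanAt(base, lev);
    plan.push_back({c + chanAt(base, lev + 1), c, 3});
    plan.push_back({c, c, 3});
  }
  plan.push_back({chanAt(base, 0), 1, 1});
}

// [[Rcpp::export(name = ".unetLayerShapes")]]
List unetLayerShapes(int depth, int base) {
  std::vector<std::array<int,3>> plan;
  layerPlan(depth, base, plan);
  List out(plan.size());
  for (size_t i = 0; i < plan.size(); ++i)
    out[i] = IntegerVector::create(_["cin"] = plan[i][0],
                                   _["cout"] = plan[i][1],
                                   _["k"] = plan[i][2]);
  return out;
}

// gather: colT(pixel, c*k*k + tap) = x(pixel shifted by tap, c); zero pad.
// Pixels are column-major within a slice, so every tap is a run of memcpys.
static void im2colT(const cube& x, int k, mat& colT) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, half = k / 2;
  colT.set_size(H * W, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* sl = x.slice_memptr(c);
    for (int dc = -half; dc <= half; ++dc)
      for (int dr = -half; dr <= half; ++dr) {
        const int q = c * k * k + (dr + half) * k + (dc + half);
        double* dst = colT.colptr(q);
        if (dr != 0 || dc != 0) std::fill(dst, dst + H * W, 0.0);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        for (int j = c0; j < c1; ++j)
          std::memcpy(dst + (size_t) j * H + r0,
                      sl + (size_t) (j + dc) * H + (r0 + dr),
                      sizeof(double) * (r1 - r0));
      }
  }
}

static void col2imAccT(const mat& dcolT, cube& dx, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, half = k / 2;
  for (int c = 0; c < C; ++c) {
    double* sl = dx.slice_memptr(c);
    for (int dc = -half; dc <= half; ++dc)
      for (int dr = -half; dr <= half; ++dr) {
        const int q = c * k * k + (dr + half) * k + (dc + half);
        const double* src = dcolT.colptr(q);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        for (int j = c0; j < c1; ++j) {
          double* d = sl + (size_t) (j + dc) * H + (r0 + dr);
          const double* s = src + (size_t) j * H + r0;
          for (int t = 0; t < r1 - r0; ++t) d[t] += s[t];
        }
      }
  }
}

static cube convForward(const ConvLayer& L, const cube& x, mat& colT) {
  im2colT(x, L.k, colT);
  mat outT = colT * L.W;            // HW x Cout
  outT.each_row() += L.b.t();
  cube out(x.n_rows, x.n_cols, L.cout);
  std::memcpy(out.memptr(), outT.memptr(), sizeof(double) * outT.n_elem);
  return out;
}

static cube maxPool2(const cube& x, ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword r = 2 * i + di, q = 2 * j + dj;
            const double v = x(r, q, c);
            if (v > best) { best = v; bi = r + q * x.n_rows; }
          }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return out;
}

static cube maxPoolBack(const cube& d, const ucube& idx, int H, int W) {
  cube dx(H, W, d.n_slices, fill::zeros);
  for (uword c = 0; c < d.n_slices; ++c)
    for (uword j = 0; j < d.n_cols; ++j)
      for (uword i = 0; i < d.n_rows; ++i)
        dx.slice(c)(idx(i, j, c)) += d(i, j, c);
  return dx;
}

static cube upsample2(const cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upsampleBack(const cube& d) {
  cube dx(d.n_rows / 2, d.n_cols / 2, d.n_slices, fill::zeros);
  for (uword c = 0; c < d.n_slices; ++c)
    for (uword j = 0; j < d.n_cols; ++j)
      for (uword i = 0; i < d.n_rows; ++i)
        dx(i / 2, j / 2, c) += d(i, j, c);
  return dx;
}

struct Ctx {
  std::vector<mat> cols;          // im2col input per executed conv
  std::vector<uvec> inDims;       // (H, W, C) per conv input
  std::vector<cube> outs;         // post-ReLU output per conv (raw for final)
  std::vector<ucube> poolIdx;     // per pooling step
  std::vector<uvec> poolDims;     // input dims per pooling step
  std::vector<cube> skips;
};

static cube runConv(UNet& net, int li, const cube& x, Ctx& ctx, bool relu) {
  mat col;
  cube out = convForward(net.layers[li], x, col);
  if (relu) out.transform([](double v) { return v > 0 ? v : LEAK * v; });
  ctx.cols[li] = std::move(col);
  ctx.inDims[li] = uvec{x.n_rows, x.n_cols, x.n_slices};
  ctx.outs[li] = out;
  return out;
}

static cube forwardPass(UNet& net, const mat& img, Ctx& ctx) {
  const size_t L = net.layers.size();
  ctx.cols.assign(L, mat());
  ctx.inDims.assign(L, uvec());
  ctx.outs.assign(L, cube());
  ctx.poolIdx.clear(); ctx.poolDims.clear(); ctx.skips.clear();
  cube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  int li = 0;
  for (int lev = 0; lev < net.depth; ++lev) {
    if (lev > 0) {
      ucube idx;
      ctx.poolDims.push_back(uvec{cur.n_rows, cur.n_cols});
      cur = maxPool2(cur, idx);
      ctx.poolIdx.push_back(idx);
    }
    cur = runConv(net, li++, cur, ctx, true);
    cur = runConv(net, li++, cur, ctx, true);
    if (lev < net.depth - 1) ctx.skips.push_back(cur);
  }
  for (int lev = net.depth - 2; lev >= 0; --lev) {
    cur = upsample2(cur);
    cur = join_slices(ctx.skips[lev], cur);
    cur = runConv(net, li++, cur, ctx, true);
    cur = runConv(net, li++, cur, ctx, true);
  }
  cur = runConv(net, li++, cur, ctx, false);  // final 1x1, linear
  return cur;
}

// beta2 = 0.99: a short second-moment memory lets the optimiser recover
// quickly from the large transient gradients of the first epochs, which
// otherwise suppress the small sparse-peak gradients for ~1/(1-beta2) steps
static void adamUpdate(ConvLayer& L, const mat& dW, const vec& db,
                       double lr, long t) {
  const double b1 = 0.9, b2 = 0.99, eps = 1e-8;
  L.mW = b1 * L.mW + (1 - b1) * dW;
  L.vW = b2 * L.vW + (1 - b2) * square(dW);
  L.mb = b1 * L.mb + (1 - b1) * db;
  L.vb = b2 * L.vb + (1 - b2) * square(db);
  const double c1 = 1 - std::pow(b1, (double) t);
  const double c2 = 1 - std::pow(b2, (double) t);
  L.W -= lr * (L.mW / c1) / (sqrt(L.vW / c2) + eps);
  L.b -= lr * (L.mb / c1) / (sqrt(L.vb / c2) + eps);
}

// backward through executed conv li; d is grad wrt its output (post-ReLU for
// relu layers).  Updates the layer in place, returns grad wrt its input.
static cube convBack(UNet& net, int li, cube d, Ctx& ctx, bool relu,
                     double lr) {
  ConvLayer& L = net.layers[li];
  if (relu)
    d %= LEAK + (1.0 - LEAK) * conv_to<cube>::from(ctx.outs[li] > 0);
  const size_t HW = d.n_rows * d.n_cols;
  const mat dYT(d.memptr(), HW, L.cout);      // HW x Cout view copy
  const mat dW = ctx.cols[li].t() * dYT;
  const vec db = sum(dYT, 0).t();
  const mat dcolT = dYT * L.W.t();
  cube dx(ctx.inDims[li](0), ctx.inDims[li](1), ctx.inDims[li](2),
          fill::zeros);
  col2imAccT(dcolT, dx, L.k);
  adamUpdate(L, dW, db, lr, net.t);
  return dx;
}

static double backwardPass(UNet& net, Ctx& ctx, const cube& out,
                           const mat& y, double lr) {
  net.t += 1;
  const double N = out.n_rows * out.n_cols;
  const mat diff = out.slice(0) - y;
  const double loss = accu(square(diff)) / N;
  cube d(out.n_rows, out.n_cols, 1);
  d.slice(0) = 2.0 * diff / N;
  int li = (int) net.layers.size() - 1;
  cube cur = convBack(net, li--, d, ctx, false, lr);
  std::vector<cube> dskip(net.depth - 1);
  for (int lev = 0; lev <= net.depth - 2; ++lev) {
    cur = convBack(net, li--, cur, ctx, true, lr);
    cur = convBack(net, li--, cur, ctx, true, lr);
    const int cs = chanAt(net.base, lev);
    dskip[lev] = cur.slices(0, cs - 1);
    cur = upsampleBack(cur.slices(cs, cur.n_slices - 1));
  }
  for (int lev = net.depth - 1; lev >= 0; --lev) {
    if (lev < net.depth - 1) cur += dskip[lev];
    cur = convBack(net, li--, cur, ctx, true, lr);
    cur = convBack(net, li--, cur, ctx, true, lr);
    if (lev > 0) {
      const uvec& pd = ctx.poolDims[lev - 1];
      cur = maxPoolBack(cur, ctx.poolIdx[lev - 1], pd(0), pd(1));
    }
  }
  return loss;
}

static UNet* asNet(SEXP ptr) {
  XPtr<UNet> p(ptr);
  return p.get();
}

// [[Rcpp::export(name = ".unetCreate")]]
SEXP unetCreate(List weights, int depth, int base) {
  std::vector<std::array<int,3>> plan;
  layerPlan(depth, base, plan);
  if ((size_t) weights.size() != plan.size())
    stop("weight list does not match the layer plan");
  XPtr<UNet> ptr(new UNet(), true);
  ptr->depth = depth;
  ptr->base = base;
  ptr->t = 0;
  for (size_t i = 0; i < plan.size(); ++i) {
    List wl = weights[i];
    ConvLayer L;
    L.cin = plan[i][0]; L.cout = plan[i][1]; L.k = plan[i][2];
    L.W = as<mat>(wl["W"]);
    L.b = as<vec>(wl["b"]);
    if ((int) L.W.n_rows != L.cin * L.k * L.k ||
        (int) L.W.n_cols != L.cout || (int) L.b.n_elem != L.cout)
      stop("weight %d has the wrong shape", (int) i + 1);
    L.mW = zeros<mat>(size(L.W)); L.vW = zeros<mat>(size(L.W));
    L.mb = zeros<vec>(L.cout); L.vb = zeros<vec>(L.cout);
    ptr->layers.push_back(std::move(L));
  }
  return ptr;
}

// [[Rcpp::export(name = ".unetTrainEpoch")]]
double unetTrainEpoch(SEXP ptr, const arma::cube& X, const arma::cube& Y,
                      const IntegerVector& order, double lr) {
  UNet* net = asNet(ptr);
  Ctx ctx;
  double tot = 0;
  for (int ii = 0; ii < order.size(); ++ii) {
    const int i = order[ii] - 1;
    const mat img = X.slice(i);
    cube out = forwardPass(*net, img, ctx);
    tot += backwardPass(*net, ctx, out, Y.slice(i), lr);
  }
  return tot / order.size();
}

// [[Rcpp::export(name = ".unetLoss")]]
double unetLoss(SEXP ptr, const arma::cube& X, const arma::cube& Y) {
  UNet* net = asNet(ptr);
  Ctx ctx;
  double tot = 0;
  for (uword i = 0; i < X.n_slices; ++i) {
    cube out = forwardPass(*net, X.slice(i), ctx);
    tot += accu(square(out.slice(0) - Y.slice(i))) / (X.n_rows * X.n_cols);
  }
  return tot / X.n_slices;
}

// [[Rcpp::export(name = ".unetPredict")]]
arma::mat unetPredict(SEXP ptr, const arma::mat& img) {
  UNet* net = asNet(ptr);
  Ctx ctx;
  cube out = forwardPass(*net, img, ctx);
  return out.slice(0);
}

// [[Rcpp::export(name = ".unetGetWeights")]]
List unetGetWeights(SEXP ptr) {
  UNet* net = asNet(ptr);
  List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i)
    out[i] = List::create(_["W"] = net->layers[i].W,
                          _["b"] = NumericVector(net->layers[i].b.begin(),
                                                 net->layers[i].b.end()));
  return out;
}

// Bilinear affine resampling: out(r, c) samples the input at
//   src = M (p - centre) + centre + shift     (0-based pixel coordinates)
// with constant fill outside the input.
// [[Rcpp::export(name = ".warpAffine")]]
arma::mat warpAffine(const arma::mat& img, double m11, double m12,
                     double m21, double m22, double tr, double tc,
                     double fill) {
  const int H = img.n_rows, W = img.n_cols;
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  mat out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double sr = m11 * (r - cr) + m12 * (c - cc) + cr + tr;
      const double sc = m21 * (r - cr) + m22 * (c - cc) + cc + tc;
      const int r0 = (int) std::floor(sr), c0 = (int) std::floor(sc);
      if (r0 < 0 || c0 < 0 || r0 + 1 >= H || c0 + 1 >= W) {
        out(r, c) = fill;
        continue;
      }
      const double fr = sr - r0, fc = sc - c0;
      out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) +
                  fr * (1 - fc) * img(r0 + 1, c0) +
                  (1 - fr) * fc * img(r0, c0 + 1) +
                  fr * fc * img(r0 + 1, c0 + 1);
    }
  return out;
}
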