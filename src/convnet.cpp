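// Low-level convolutional primitives for the CycleGAN networks.
// Activations are 3-D R arrays laid out (rows, cols, channels); weights are
// (C_out x C_in*k*k) matrices whose row layout is ch*k*k + ki*k + kj.
// R memory is borrowed (no copy) on both sides of every call; the im2col
// patch matrix built in the forward pass is returned as an external pointer
// and reused by the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube borrow_cube(Rcpp::NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  int C = (d.size() == 3) ? d[2] : 1;
  return cube(v.begin(), d[0], d[1], C, false, true);
}

static Rcpp::NumericVector alloc_cube(sword H, sword W, sword C) {
  Rcpp::NumericVector out(H * W * C);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  return out;
}

// reflect_101 index: -1 -> 1, n -> n-2 (never repeats the edge sample)
static inline sword reflect_idx(sword i, sword n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

static cube pad2d(const cube& x, int p, bool reflect) {
  const sword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H + 2 * p, W + 2 * p, C, fill::zeros);
  if (reflect) {
    for (sword c = 0; c < C; ++c)
      for (sword j = 0; j < W + 2 * p; ++j) {
        sword sj = reflect_idx(j - p, W);
        for (sword i = 0; i < H + 2 * p; ++i)
          out(i, j, c) = x(reflect_idx(i - p, H), sj, c);
      }
  } else {
    out.tube(p, p, p + H - 1, p + W - 1) = x;
  }
  return out;
}

// adjoint of pad2d: fold padded-gradient contributions back onto the interior
static void unpad2d_into(const cube& g, int p, bool reflect, cube& out) {
  const sword H = out.n_rows, W = out.n_cols, C = g.n_slices;
  out.zeros();
  if (reflect) {
    for (sword c = 0; c < C; ++c)
      for (sword j = 0; j < (sword)g.n_cols; ++j) {
        sword sj = reflect_idx(j - p, W);
        for (sword i = 0; i < (sword)g.n_rows; ++i)
          out(reflect_idx(i - p, H), sj, c) += g(i, j, c);
      }
  } else {
    out = g.tube(p, p, p + H - 1, p + W - 1);
  }
}

// patch matrix in transposed layout: (Ho*Wo) x (C*k*k), so each patch
// element index owns a contiguous column. Patch matrices and the GEMMs over
// them are single precision: these skinny products are memory-bound, and
// float halves the traffic; everything around them stays double.
static void im2colT(const cube& xp, int k, int stride, sword Ho, sword Wo,
                    fmat& colsT) {
  const sword C = xp.n_slices;
  colsT.set_size(Ho * Wo, C * k * k);
  const sword Hp = xp.n_rows;
  for (sword c = 0; c < C; ++c) {
    const double* sl = xp.slice_memptr(c);
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        float* dst = colsT.colptr(c * k * k + ki * k + kj);
        for (sword oc = 0; oc < Wo; ++oc) {
          const double* src = sl + (oc * stride + kj) * Hp + ki;
          float* d = dst + oc * Ho;
          for (sword orow = 0; orow < Ho; ++orow)
            d[orow] = (float)src[orow * stride];
        }
      }
  }
}

static cube col2imT(const fmat& dcolsT, int k, int stride, sword Hp, sword Wp,
                    sword C, sword Ho, sword Wo) {
  cube dxp(Hp, Wp, C, fill::zeros);
  for (sword c = 0; c < C; ++c) {
    double* sl = dxp.slice_memptr(c);
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const float* src = dcolsT.colptr(c * k * k + ki * k + kj);
        for (sword oc = 0; oc < Wo; ++oc) {
          double* dst = sl + (oc * stride + kj) * Hp + ki;
          const float* s = src + oc * Ho;
          for (sword orow = 0; orow < Ho; ++orow)
            dst[orow * stride] += s[orow];
        }
      }
  }
  return dxp;
}

// forward convolution; returns list(y, cols) where `cols` is an external
// pointer to the patch matrix, consumed by conv2d_bw
// [[Rcpp::export]]
Rcpp::List conv2d_fw(Rcpp::NumericVector x, const arma::mat& W,
                     const arma::vec& b, int k, int stride, int pad,
                     bool reflect, bool keep_cols = true) {
  cube xc = borrow_cube(x);
  cube xp = pad2d(xc, pad, reflect);
  const sword Ho = (xp.n_rows - k) / stride + 1;
  const sword Wo = (xp.n_cols - k) / stride + 1;
  Rcpp::XPtr<fmat> colsT(new fmat(), true);
  im2colT(xp, k, stride, Ho, Wo, *colsT);
  Rcpp::NumericVector out = alloc_cube(Ho, Wo, W.n_rows);
  mat om(out.begin(), Ho * Wo, W.n_rows, false, true);
  const fmat Wf = conv_to<fmat>::from(W);
  om = conv_to<mat>::from((*colsT) * Wf.t());
  om.each_row() += b.t();
  if (!keep_cols) colsT->reset();
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("cols") = colsT);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(Rcpp::NumericVector x, const arma::mat& W,
                     Rcpp::NumericVector dout, int k, int stride, int pad,
                     bool reflect, bool want_param_grads, SEXP cols) {
  cube xc = borrow_cube(x);
  cube dc = borrow_cube(dout);
  const sword Ho = dc.n_rows, Wo = dc.n_cols, Co = dc.n_slices;
  const mat dom(dc.memptr(), Ho * Wo, Co, false, true);
  const fmat domf = conv_to<fmat>::from(dom);
  Rcpp::List res;
  if (want_param_grads) {
    Rcpp::XPtr<fmat> colsT(cols);
    if (colsT->n_elem == 0) {  // cache was dropped: rebuild
      cube xp = pad2d(xc, pad, reflect);
      im2colT(xp, k, stride, Ho, Wo, *colsT);
    }
    mat dW = conv_to<mat>::from(domf.t() * (*colsT));
    vec db = sum(dom, 0).t();
    res = Rcpp::List::create(Rcpp::Named("dx") = R_NilValue,
                             Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  } else {
    res = Rcpp::List::create(Rcpp::Named("dx") = R_NilValue);
  }
  const fmat Wf = conv_to<fmat>::from(W);
  fmat dcolsT = domf * Wf;
  const sword Hp = xc.n_rows + 2 * pad, Wp = xc.n_cols + 2 * pad;
  cube dxp = col2imT(dcolsT, k, stride, Hp, Wp, xc.n_slices, Ho, Wo);
  Rcpp::NumericVector dxv = alloc_cube(xc.n_rows, xc.n_cols, xc.n_slices);
  cube dx(dxv.begin(), xc.n_rows, xc.n_cols, xc.n_slices, false, true);
  unpad2d_into(dxp, pad, reflect, dx);
  res["dx"] = dxv;
  return res;
}

// activation codes: 0 none, 1 relu, 2 leaky relu (0.2), 3 tanh
static inline double act_apply(double v, int act) {
  switch (act) {
    case 1: return v > 0 ? v : 0.0;
    case 2: return v > 0 ? v : 0.2 * v;
    case 3: return std::tanh(v);
    default: return v;
  }
}

// derivative through the activation expressed via the *activated* value y
static inline double act_bw(double dy, double y, int act) {
  switch (act) {
    case 1: return y > 0 ? dy : 0.0;
    case 2: return y > 0 ? dy : 0.2 * dy;
    case 3: return dy * (1.0 - y * y);
    default: return dy;
  }
}

// fused instance norm + activation
// [[Rcpp::export]]
Rcpp::List instnorm_act_fw(Rcpp::NumericVector x, const arma::vec& gamma,
                           const arma::vec& beta, double eps, int act) {
  cube xc = borrow_cube(x);
  const sword C = xc.n_slices;
  Rcpp::NumericVector yv = alloc_cube(xc.n_rows, xc.n_cols, C);
  cube y(yv.begin(), xc.n_rows, xc.n_cols, C, false, true);
  vec m(C), istd(C);
  for (sword c = 0; c < C; ++c) {
    const mat& sl = xc.slice(c);
    const double mu = accu(sl) / sl.n_elem;
    const double v = accu(square(sl - mu)) / sl.n_elem;
    const double is = 1.0 / std::sqrt(v + eps);
    m(c) = mu;
    istd(c) = is;
    const double a = is * gamma(c), b = beta(c) - mu * is * gamma(c);
    const double* src = xc.slice_memptr(c);
    double* dst = y.slice_memptr(c);
    for (uword i = 0; i < sl.n_elem; ++i)
      dst[i] = act_apply(a * src[i] + b, act);
  }
  return Rcpp::List::create(Rcpp::Named("y") = yv, Rcpp::Named("mean") = m,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List instnorm_act_bw(Rcpp::NumericVector x, const arma::vec& gamma,
                           const arma::vec& m, const arma::vec& istd,
                           Rcpp::NumericVector y_act, Rcpp::NumericVector dy,
                           int act) {
  cube xc = borrow_cube(x);
  cube yc = borrow_cube(y_act);
  cube dyc = borrow_cube(dy);
  const sword C = xc.n_slices;
  Rcpp::NumericVector dxv = alloc_cube(xc.n_rows, xc.n_cols, C);
  cube dx(dxv.begin(), xc.n_rows, xc.n_cols, C, false, true);
  vec dgamma(C), dbeta(C);
  for (sword c = 0; c < C; ++c) {
    const double* xs = xc.slice_memptr(c);
    const double* ys = yc.slice_memptr(c);
    const double* ds = dyc.slice_memptr(c);
    double* dxs = dx.slice_memptr(c);
    const uword N = xc.n_rows * xc.n_cols;
    double sg = 0.0, sgx = 0.0;
    for (uword i = 0; i < N; ++i) {
      const double g = act_bw(ds[i], ys[i], act);
      const double xhat = (xs[i] - m(c)) * istd(c);
      dxs[i] = g;        // reuse as scratch for the activation-backed grad
      sg += g;
      sgx += g * xhat;
    }
    dgamma(c) = sgx;
    dbeta(c) = sg;
    const double scale = gamma(c) * istd(c);
    const double mg = sg / N, mgx = sgx / N;
    for (uword i = 0; i < N; ++i) {
      const double xhat = (xs[i] - m(c)) * istd(c);
      dxs[i] = (dxs[i] - mg - xhat * mgx) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dxv,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// nearest-neighbour x2 upsampling ("unpooling with stride 2")
// [[Rcpp::export]]
Rcpp::NumericVector upsample2_fw(Rcpp::NumericVector x) {
  cube xc = borrow_cube(x);
  const sword H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  Rcpp::NumericVector outv = alloc_cube(2 * H, 2 * W, C);
  cube out(outv.begin(), 2 * H, 2 * W, C, false, true);
  for (sword c = 0; c < C; ++c)
    for (sword j = 0; j < W; ++j)
      for (sword i = 0; i < H; ++i) {
        const double v = xc(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return outv;
}

// [[Rcpp::export]]
Rcpp::NumericVector upsample2_bw(Rcpp::NumericVector dy) {
  cube dyc = borrow_cube(dy);
  const sword H = dyc.n_rows / 2, W = dyc.n_cols / 2, C = dyc.n_slices;
  Rcpp::NumericVector dxv = alloc_cube(H, W, C);
  cube dx(dxv.begin(), H, W, C, false, true);
  for (sword c = 0; c < C; ++c)
    for (sword j = 0; j < W; ++j)
      for (sword i = 0; i < H; ++i)
        dx(i, j, c) = dyc(2 * i, 2 * j, c) + dyc(2 * i + 1, 2 * j, c) +
                      dyc(2 * i, 2 * j + 1, c) + dyc(2 * i + 1, 2 * j + 1, c);
  return dxv;
}
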