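// Convolution primitives for the autodiff engine.
// Image tensors are R arrays with dim (H, W, C), column-major.
// Weight tensors have dim (KH, KW, IC, OC).
// pad_mode: 0 = zero, 1 = reflect (edge not repeated), 2 = replicate.
//
// im2col gather indices depend only on the geometry, so they are computed
// once per (H, W, C, KH, KW, stride, pad, mode) and cached; forward and
// backward then reduce to a gather, one or two GEMMs, and a scatter.

#include <RcppArmadillo.h>
#include <map>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int map_index(int i, int n, int mode) {
  if (i >= 0 && i < n) return i;
  if (mode == 0) return -1;
  if (mode == 2) return i < 0 ? 0 : n - 1;
  if (i < 0) return -i;          // reflect, border sample not repeated
  return 2 * n - 2 - i;
}

typedef std::array<long, 8> GeomKey;
static std::map<GeomKey, std::vector<long> > g_idx_cache;

static void conv_out_size(int H, int W, int KH, int KW, int stride, int pad,
                          int& OH, int& OW) {
  OH = (H + 2 * pad - KH) / stride + 1;
  OW = (W + 2 * pad - KW) / stride + 1;
  if (OH < 1 || OW < 1)
    stop("convolution output would be empty: input %dx%d, kernel %dx%d, stride %d, pad %d",
         H, W, KH, KW, stride, pad);
}

// linear source index (into H*W*C input, -1 = zero pad) for every im2col
// entry, ordered kh fastest, then kw, then c, then output position
static const std::vector<long>& gather_indices(int H, int W, int C, int KH,
                                               int KW, int stride, int pad,
                                               int mode, int OH, int OW) {
  GeomKey key = {H, W, C, KH, KW, stride, pad, mode};
  auto it = g_idx_cache.find(key);
  if (it != g_idx_cache.end()) return it->second;
  std::vector<long> idx((size_t)KH * KW * C * OH * OW);
  size_t t = 0;
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < KW; ++kw) {
          const int wj = map_index(ow * stride + kw - pad, W, mode);
          for (int kh = 0; kh < KH; ++kh, ++t) {
            const int hi = map_index(oh * stride + kh - pad, H, mode);
            idx[t] = (hi < 0 || wj < 0) ? -1
              : (long)hi + (long)wj * H + (long)c * H * W;
          }
        }
  auto res = g_idx_cache.emplace(key, std::move(idx));
  return res.first->second;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 3 || wd.size() != 4) stop("bad tensor rank");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int KH = wd[0], KW = wd[1], IC = wd[2], OC = wd[3];
  if (IC != C) stop("channel mismatch: input %d vs kernel %d", C, IC);
  if (pad_mode == 1 && (pad >= H || pad >= W)) stop("reflection pad too large");
  int OH, OW;
  conv_out_size(H, W, KH, KW, stride, pad, OH, OW);
  const int K = KH * KW * C, N = OH * OW;
  const std::vector<long>& idx =
    gather_indices(H, W, C, KH, KW, stride, pad, pad_mode, OH, OW);

  arma::mat cols(K, N);
  const double* xp = x.begin();
  double* cp = cols.memptr();
  const size_t total = (size_t)K * N;
  for (size_t t = 0; t < total; ++t) cp[t] = idx[t] < 0 ? 0.0 : xp[idx[t]];

  arma::mat Wm(const_cast<double*>(w.begin()), K, OC, false, true);
  arma::mat out = Wm.t() * cols;            // OC x N

  NumericVector res(N * OC);
  res.attr("dim") = IntegerVector::create(OH, OW, OC);
  double* r = res.begin();
  for (int oc = 0; oc < OC; ++oc) {
    const double boc = b[oc];
    for (int n = 0; n < N; ++n) r[n + (size_t)oc * N] = out(oc, n) + boc;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, int pad_mode, bool want_gw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int KH = wd[0], KW = wd[1], OC = wd[3];
  int OH, OW;
  conv_out_size(H, W, KH, KW, stride, pad, OH, OW);
  const int K = KH * KW * C, N = OH * OW;
  const std::vector<long>& idx =
    gather_indices(H, W, C, KH, KW, stride, pad, pad_mode, OH, OW);

  // gout arrives as (OH, OW, OC); view as N x OC without copy, use as needed
  arma::mat G(const_cast<double*>(gout.begin()), N, OC, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, OC, false, true);
  arma::mat gcols = Wm * G.t();             // K x N

  NumericVector gx(H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  double* gxp = gx.begin();
  const double* gc = gcols.memptr();
  const size_t total = (size_t)K * N;
  for (size_t t = 0; t < total; ++t)
    if (idx[t] >= 0) gxp[idx[t]] += gc[t];

  List outl;
  outl["gx"] = gx;
  if (want_gw) {
    arma::mat cols(K, N);
    const double* xp = x.begin();
    double* cp = cols.memptr();
    for (size_t t = 0; t < total; ++t) cp[t] = idx[t] < 0 ? 0.0 : xp[idx[t]];
    arma::mat gW = cols * G;                // K x OC
    NumericVector gw(K * OC);
    gw.attr("dim") = wd;
    std::copy(gW.begin(), gW.end(), gw.begin());
    NumericVector gb(OC);
    for (int oc = 0; oc < OC; ++oc) gb[oc] = arma::accu(G.col(oc));
    outl["gw"] = gw;
    outl["gb"] = gb;
  }
  return outl;
}

// separable valid correlation with a symmetric 1-D kernel (Gaussian window
// of the SSIM statistics); input (H, W, 1) -> output (H-K+1, W-K+1, 1)
// [[Rcpp::export]]
NumericVector cpp_sepconv_valid(NumericVector x, NumericVector k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const int K = k.size();
  const int OH = H - K + 1, OW = W - K + 1;
  if (OH < 1 || OW < 1) stop("image smaller than the window");
  arma::mat X(const_cast<double*>(x.begin()), H, W, false, true);
  arma::mat tmp(OH, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < OH; ++i) {
      double s = 0;
      for (int t = 0; t < K; ++t) s += k[t] * X(i + t, j);
      tmp(i, j) = s;
    }
  NumericVector res(OH * OW);
  res.attr("dim") = IntegerVector::create(OH, OW, 1);
  double* r = res.begin();
  for (int j = 0; j < OW; ++j)
    for (int i = 0; i < OH; ++i) {
      double s = 0;
      for (int t = 0; t < K; ++t) s += k[t] * tmp(i, j + t);
      r[i + (size_t)j * OH] = s;
    }
  return res;
}

// adjoint of cpp_sepconv_valid: zero-padded full correlation (kernel
// symmetric, so correlation and convolution coincide)
// [[Rcpp::export]]
NumericVector cpp_sepconv_valid_adjoint(NumericVector g, NumericVector k,
                                        int H, int W) {
  IntegerVector gd = g.attr("dim");
  const int OH = gd[0], OW = gd[1];
  const int K = k.size();
  arma::mat G(const_cast<double*>(g.begin()), OH, OW, false, true);
  arma::mat tmp(H, OW, arma::fill::zeros);
  for (int j = 0; j < OW; ++j)
    for (int i = 0; i < OH; ++i) {
      const double v = G(i, j);
      for (int t = 0; t < K; ++t) tmp(i + t, j) += k[t] * v;
    }
  NumericVector res(H * W);
  res.attr("dim") = IntegerVector::create(H, W, 1);
  double* r = res.begin();
  for (int j = 0; j < OW; ++j)
    for (int i = 0; i < H; ++i) {
      const double v = tmp(i, j);
      if (v != 0)
        for (int t = 0; t < K; ++t) r[i + (size_t)(j + t) * H] += k[t] * v;
    }
  return res;
}

// instance normalization over the spatial dims of each channel, with a
// per-channel affine (gamma, beta); channels are contiguous blocks of the
// column-major (H, W, C) array
// [[Rcpp::export]]
List cpp_inorm_forward(NumericVector x, NumericVector gamma,
                       NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size()), inv_sd(C);
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * HW;
    double mu = 0;
    for (size_t t = 0; t < HW; ++t) mu += xc[t];
    mu /= HW;
    double var = 0;
    for (size_t t = 0; t < HW; ++t) { const double d = xc[t] - mu; var += d * d; }
    const double is = 1.0 / std::sqrt(var / HW + eps);
    inv_sd[c] = is;
    const double gc = gamma[c], bc = beta[c];
    double* yc = yp + c * HW;
    double* hc = hp + c * HW;
    for (size_t t = 0; t < HW; ++t) {
      const double h = (xc[t] - mu) * is;
      hc[t] = h;
      yc[t] = gc * h + bc;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List cpp_inorm_backward(NumericVector g, NumericVector xhat,
                        NumericVector inv_sd, NumericVector gamma) {
  IntegerVector gd = g.attr("dim");
  const int H = gd[0], W = gd[1], C = gd[2];
  const size_t HW = (size_t)H * W;
  NumericVector gx(g.size()), dgamma(C), dbeta(C);
  gx.attr("dim") = gd;
  const double* gp = g.begin();
  const double* hp = xhat.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + c * HW;
    const double* hc = hp + c * HW;
    double sg = 0, sgh = 0;
    for (size_t t = 0; t < HW; ++t) { sg += gc[t]; sgh += gc[t] * hc[t]; }
    dbeta[c] = sg;
    dgamma[c] = sgh;
    const double gam = gamma[c], is = inv_sd[c];
    const double m1 = gam * sg / HW, m2 = gam * sgh / HW;
    double* gxc = gxp + c * HW;
    for (size_t t = 0; t < HW; ++t)
      gxc[t] = is * (gam * gc[t] - m1 - hc[t] * m2);
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  NumericVector res(4 * H * W * C);
  res.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  const double* xp = x.begin();
  double* r = res.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j) {
      const double* col = xp + (size_t)(j / 2) * H + (size_t)c * H * W;
      double* rc = r + (size_t)j * 2 * H + (size_t)c * 4 * H * W;
      for (int i = 0; i < 2 * H; ++i) rc[i] = col[i / 2];
    }
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_downsum2(NumericVector g) {
  // adjoint of nearest-neighbour x2 upsampling: 2x2 block sums
  IntegerVector gd = g.attr("dim");
  const int H2 = gd[0], W2 = gd[1], C = gd[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector res(H * W * C);
  res.attr("dim") = IntegerVector::create(H, W, C);
  const double* gp = g.begin();
  double* r = res.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j) {
      const double* gc = gp + (size_t)j * H2 + (size_t)c * H2 * W2;
      double* rc = r + (size_t)(j / 2) * H + (size_t)c * H * W;
      for (int i = 0; i < H2; ++i) rc[i / 2] += gc[i];
    }
  return res;
}
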