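// Low-level layer kernels for the encoder-decoder network.
//
// Feature maps are dense numeric 4-D arrays with dim (H, W, C, N) in R's
// column-major layout, so the slice for one image is contiguous and can be
// viewed as an (H*W) x C matrix without copying.  Convolutions are 3x3 (any
// odd k), stride 1, zero-padded to preserve the spatial size; they are
// evaluated as k*k shifted GEMMs, which keeps peak memory at one extra
// (H*W) x C buffer instead of a full im2col matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat shift_matrix(const arma::mat& X, int H, int W,
                                     int dy, int dx) {
  // S[h + H*w, c] = X[(h+dy) + H*(w+dx), c] where valid, 0 elsewhere.
  arma::mat S(X.n_rows, X.n_cols, arma::fill::zeros);
  const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);  // [h0, h1)
  const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  if (h0 >= h1 || w0 >= w1) return S;
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* src = X.colptr(c);
    double* dst = S.colptr(c);
    for (int w = w0; w < w1; ++w) {
      std::memcpy(dst + h0 + (arma::uword)H * w,
                  src + (h0 + dy) + (arma::uword)H * (w + dx),
                  sizeof(double) * (h1 - h0));
    }
  }
  return S;
}

static inline void shift_add_back(arma::mat& GX, const arma::mat& G, int H,
                                  int W, int dy, int dx) {
  // GX[(h+dy) + H*(w+dx), c] += G[h + H*w, c] (reverse of shift_matrix).
  const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
  const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  if (h0 >= h1 || w0 >= w1) return;
  for (arma::uword c = 0; c < G.n_cols; ++c) {
    const double* src = G.colptr(c);
    double* dst = GX.colptr(c);
    for (int w = w0; w < w1; ++w) {
      double* d = dst + (h0 + dy) + (arma::uword)H * (w + dx);
      const double* s = src + h0 + (arma::uword)H * w;
      for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
    }
  }
}

// Rearrange weights (k, k, Cin, Cout) into k*k matrices of size Cin x Cout.
static std::vector<arma::mat> weight_slices(const NumericVector& w, int k,
                                            int cin, int cout) {
  std::vector<arma::mat> ws((size_t)k * k);
  const double* wp = REAL(w);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      arma::mat m(cin, cout);
      for (int o = 0; o < cout; ++o)
        for (int c = 0; c < cin; ++c)
          m(c, o) = wp[kh + (size_t)k * kw + (size_t)k * k * c +
                       (size_t)k * k * cin * o];
      ws[kh + (size_t)k * kw] = m;
    }
  return ws;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims do not match input");
  const int pad = (k - 1) / 2;
  std::vector<arma::mat> ws = weight_slices(w, k, Cin, Cout);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::rowvec bias(REAL(b), Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(REAL(x) + (size_t)H * W * Cin * n, (size_t)H * W, Cin,
                false, true);
    arma::mat Y(REAL(y) + (size_t)H * W * Cout * n, (size_t)H * W, Cout,
                false, true);
    Y.each_row() = bias;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int dy = kh - pad, dx = kw - pad;
        if (dy == 0 && dx == 0) {
          Y += X * ws[kh + (size_t)k * kw];
        } else {
          Y += shift_matrix(X, H, W, dy, dx) * ws[kh + (size_t)k * kw];
        }
      }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  std::vector<arma::mat> ws = weight_slices(w, k, Cin, Cout);
  std::vector<arma::mat> gws((size_t)k * k, arma::mat(Cin, Cout, arma::fill::zeros));
  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::rowvec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat X(REAL(x) + (size_t)H * W * Cin * n, (size_t)H * W, Cin,
                false, true);
    arma::mat GY(REAL(gy) + (size_t)H * W * Cout * n, (size_t)H * W, Cout,
                 false, true);
    arma::mat GX(REAL(gx) + (size_t)H * W * Cin * n, (size_t)H * W, Cin,
                 false, true);
    gb += arma::sum(GY, 0);
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int dy = kh - pad, dx = kw - pad;
        arma::mat G = GY * ws[kh + (size_t)k * kw].t();  // (H*W) x Cin
        if (dy == 0 && dx == 0) {
          gws[kh + (size_t)k * kw] += X.t() * GY;
          GX += G;
        } else {
          gws[kh + (size_t)k * kw] +=
              shift_matrix(X, H, W, dy, dx).t() * GY;
          shift_add_back(GX, G, H, W, dy, dx);
        }
      }
  }
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  double* gwp = REAL(gw);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      const arma::mat& m = gws[kh + (size_t)k * kw];
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          gwp[kh + (size_t)k * kw + (size_t)k * k * c +
              (size_t)k * k * Cin * o] = m(c, o);
    }
  NumericVector gbv(Cout);
  for (int o = 0; o < Cout; ++o) gbv[o] = gb[o];
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}

// 2x2 stride-2 max pooling recording the argmax location of each window.
// Ties resolve to the first position in row-major scan order of the window:
// (0,0), (0,1), (1,0), (1,1).  Indices are 0-based linear positions in the
// (H, W) plane of the input (h + H*w).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("spatial dimensions must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* plane = xp + (size_t)H * W * cn;
    double* yplane = yp + (size_t)Ho * Wo * cn;
    int* iplane = ip + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        // row-major scan of the window for the tie rule
        const int cand[4] = {h + H * w, h + H * (w + 1), (h + 1) + H * w,
                             (h + 1) + H * (w + 1)};
        int best = cand[0];
        double bv = plane[cand[0]];
        for (int t = 1; t < 4; ++t)
          if (plane[cand[t]] > bv) { bv = plane[cand[t]]; best = cand[t]; }
        yplane[ho + (size_t)Ho * wo] = bv;
        iplane[ho + (size_t)Ho * wo] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Place each pooled value back at its recorded argmax location; zero-fill
// the rest.  Also the gradient of maxpool2_fwd.
// [[Rcpp::export(name = ".unpool2")]]
NumericVector unpool2(NumericVector y, IntegerVector idx, int H, int W) {
  IntegerVector yd = y.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector x((size_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* yp = REAL(y);
  const int* ip = INTEGER(idx);
  double* xp = REAL(x);
  const size_t plane_in = (size_t)Ho * Wo, plane_out = (size_t)H * W;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn)
    for (size_t j = 0; j < plane_in; ++j) {
      const int pos = ip[plane_in * cn + j];
      if (pos < 0 || pos >= (int)plane_out)
        stop("pooling index out of range for the requested output size");
      xp[plane_out * cn + pos] += yp[plane_in * cn + j];
    }
  return x;
}
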