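// Low-level conv / pool kernels for the her2lite CNN runtime.
// Tensor layout is column-major R arrays: activations (H, W, C, N),
// conv weights (k, k, Cin, Cout), depthwise weights (k, k, C).
// "same" convolutions use the ceil(H/stride) output rule with
// floor-biased left/top padding; pooling is always valid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size_same(int in, int stride) {
  return (in + stride - 1) / stride;
}
static inline int out_size_valid(int in, int k, int stride) {
  return (in - k) / stride + 1;
}

// Build the im2col matrix (k*k*Cin x Ho*Wo) for one sample.
// Row index = kh + k*(kw + k*cin); column index = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad_h, int pad_w,
                   int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      int h0 = ho * stride - pad_h;
      int w0 = wo * stride - pad_w;
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            int r = kh + k * (kw + k * c);
            col(r, p) = (hi >= 0 && hi < H && wi >= 0 && wi < W)
              ? xc[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back onto the (padded) input.
static void col2im(const arma::mat& col, int H, int W, int Cin,
                   int k, int stride, int pad_h, int pad_w,
                   int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      int h0 = ho * stride - pad_h;
      int w0 = wo * stride - pad_w;
      for (int c = 0; c < Cin; ++c) {
        double* dxc = dx + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            int r = kh + k * (kw + k * c);
            dxc[hi + (size_t)H * wi] += col(r, p);
          }
        }
      }
    }
  }
}

static void conv_geometry(int H, int W, int k, int stride, bool same,
                          int& Ho, int& Wo, int& pad_h, int& pad_w) {
  if (same) {
    Ho = out_size_same(H, stride);
    Wo = out_size_same(W, stride);
    int pht = std::max((Ho - 1) * stride + k - H, 0);
    int pwt = std::max((Wo - 1) * stride + k - W, 0);
    pad_h = pht / 2;
    pad_w = pwt / 2;
  } else {
    Ho = out_size_valid(H, k, stride);
    Wo = out_size_valid(W, k, stride);
    pad_h = pad_w = 0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, bool same) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho, Wo, pad_h, pad_w;
  conv_geometry(H, W, k, stride, same, Ho, Wo, pad_h, pad_w);
  if (Ho < 1 || Wo < 1) stop("convolution output collapses to zero size");

  arma::mat wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, k, stride, pad_h, pad_w, Ho, Wo, col);
    arma::mat yn = wmat.t() * col;           // Cout x P
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double b = bias[c];
      for (int p = 0; p < Ho * Wo; ++p) yp[p + (size_t)Ho * Wo * c] = yn(c, p) + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, bool same) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int pad_h, pad_w, Ho2, Wo2;
  conv_geometry(H, W, k, stride, same, Ho2, Wo2, pad_h, pad_w);

  arma::mat wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dwmat(k * k * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(k * k * Cin, Ho * Wo);
  arma::mat dyn(Cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    const double* dyp = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < Ho * Wo; ++p) dyn(c, p) = dyp[p + (size_t)Ho * Wo * c];
    im2col(xn, H, W, Cin, k, stride, pad_h, pad_w, Ho, Wo, col);
    dwmat += col * dyn.t();
    db += arma::sum(dyn, 1);
    arma::mat dcol = wmat * dyn;             // kkCin x P
    col2im(dcol, H, W, Cin, k, stride, pad_h, pad_w, Ho, Wo,
           dx.begin() + (size_t)H * W * Cin * n);
  }
  NumericVector dwv(dwmat.begin(), dwmat.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Depthwise convolution: weights (k, k, C), one filter per channel.
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w,
                               NumericVector bias, int stride, bool same) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho, Wo, pad_h, pad_w;
  conv_geometry(H, W, k, stride, same, Ho, Wo, pad_h, pad_w);
  if (Ho < 1 || Wo < 1) stop("depthwise convolution output collapses to zero size");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias[c];
          int h0 = ho * stride - pad_h, w0 = wo * stride - pad_w;
          for (int kw = 0; kw < k; ++kw) {
            int wi = w0 + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = h0 + kh;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[kh + k * kw];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, bool same) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  int pad_h, pad_w, Ho2, Wo2;
  conv_geometry(H, W, k, stride, same, Ho2, Wo2, pad_h, pad_w);
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)k * k * c;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dyc[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          db[c] += g;
          int h0 = ho * stride - pad_h, w0 = wo * stride - pad_w;
          for (int kw = 0; kw < k; ++kw) {
            int wi = w0 + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = h0 + kh;
              if (hi < 0 || hi >= H) continue;
              dxc[hi + (size_t)H * wi] += g * wc[kh + k * kw];
              dwc[kh + k * kw] += g * xc[hi + (size_t)H * wi];
            }
          }
        }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Valid max pooling; returns pooled values plus 1-based argmax indices
// into the flat input array so the backward pass is a scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H < k || W < k) stop("pooling window larger than input");
  int Ho = out_size_valid(H, k, stride), Wo = out_size_valid(W, k, stride);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = x.begin() + base;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride, w0 = wo * stride;
          double best = xc[h0 + (size_t)H * w0];
          size_t besti = h0 + (size_t)H * w0;
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
              size_t ii = (h0 + kh) + (size_t)H * (w0 + kw);
              if (xc[ii] > best) { best = xc[ii]; besti = ii; }
            }
          // outputs are written (ho fastest, then wo) per channel plane
          y[(size_t)Ho * Wo * (c + (size_t)C * n) + ho + (size_t)Ho * wo] = best;
          idx[(size_t)Ho * Wo * (c + (size_t)C * n) + ho + (size_t)Ho * wo] =
            (int)(base + besti) + 1;
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector xdim, IntegerVector idx,
                              NumericVector dy) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
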