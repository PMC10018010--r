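// Minimal CPU convolution engine backing the network module.
// Array layout follows R column-major conventions throughout:
//   activations  (H, W, C, N)   weights (kh, kw, Cin, Cout)
// so an (H*W x C) arma::mat view of one sample needs no copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int Cin,
                               int kh, int kw, int stride, int pad,
                               int Ho, int Wo) {
  arma::mat K(kh * kw * Cin, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int hi0 = ho * stride - pad;
      const int wi0 = wo * stride - pad;
      double* kc = K.colptr(col);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            kc[ki + kh * (kj + kw * ci)] = x[hi + H * (wi + W * ci)];
          }
        }
      }
    }
  }
  return K;
}

static inline void col2im_acc(const arma::mat& gK, double* gx,
                              int H, int W, int Cin, int kh, int kw,
                              int stride, int pad, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int hi0 = ho * stride - pad;
      const int wi0 = wo * stride - pad;
      const double* kc = gK.colptr(col);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            gx[hi + H * (wi + W * ci)] += kc[ki + kh * (kj + kw * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  const int xstr = H * W * Cin, ystr = Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat K = im2col(x.begin() + n * xstr, H, W, Cin, kh, kw,
                         stride, pad, Ho, Wo);
    arma::mat Y(y.begin() + n * ystr, Ho * Wo, Cout, false, true);
    Y = K.t() * Wm;
    Y.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), kh * kw * Cin, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  const int xstr = H * W * Cin, ystr = Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat K = im2col(x.begin() + n * xstr, H, W, Cin, kh, kw,
                         stride, pad, Ho, Wo);
    const arma::mat gY(const_cast<double*>(gy.begin()) + n * ystr,
                       Ho * Wo, Cout, false, true);
    gWm += K * gY;
    gbv += arma::sum(gY, 0).t();
    arma::mat gK = Wm * gY.t();
    col2im_acc(gK, gx.begin() + n * xstr, H, W, Cin, kh, kw, stride, pad,
               Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the input array (for the backward pass).
// [[Rcpp::export(name = ".maxpool2_forward_cpp")]]
List maxpool2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const int xoff = H * W * (c + C * n);
      const int yoff = Ho * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int ii = xoff + (2 * ho + di) + H * (2 * wo + dj);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          y[yoff + ho + Ho * wo] = best;
          idx[yoff + ho + Ho * wo] = bi + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward_cpp")]]
NumericVector maxpool2_backward_cpp(NumericVector gy, IntegerVector idx,
                                    IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export(name = ".upsample2_forward_cpp")]]
NumericVector upsample2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const int xoff = H * W * (c + C * n);
      const int yoff = Ho * Wo * (c + C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          y[yoff + h + Ho * w] = x[xoff + h / 2 + H * (w / 2)];
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward_cpp")]]
NumericVector upsample2_backward_cpp(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const int xoff = H * W * (c + C * n);
      const int yoff = Ho * Wo * (c + C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          gx[xoff + h / 2 + H * (w / 2)] += gy[yoff + h + Ho * w];
    }
  return gx;
}

// Symmetric Hausdorff distance between two point sets given as
// (row, col) coordinate matrices.
// [[Rcpp::export(name = ".hausdorff_cpp")]]
double hausdorff_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double hAB = 0.0;
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dr = a(i, 0) - b(j, 0), dc = a(i, 1) - b(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < dmin) dmin = d;
    }
    if (dmin > hAB) hAB = dmin;
  }
  double hBA = 0.0;
  for (int j = 0; j < nb; ++j) {
    double dmin = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double dr = a(i, 0) - b(j, 0), dc = a(i, 1) - b(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < dmin) dmin = d;
    }
    if (dmin > hBA) hBA = dmin;
  }
  return std::sqrt(hAB > hBA ? hAB : hBA);
}
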