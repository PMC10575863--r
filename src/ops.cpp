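// Dense and deformable 2-D convolution kernels.
//
// Tensor convention (matches the R side): feature maps are R arrays with
// dim = c(H, W, C, N), column-major, origin top-left, 0-based math indices.
// Weights are arrays dim = c(k, k, C_in, C_out) with taps enumerated
// row-major over the kernel window: tap t = i*k + j for row offset i and
// column offset j. Offset fields carry 2*k^2 channels per output location,
// channel 2t = dy and 2t+1 = dx for tap t (DCN v1: one offset pair per tap,
// shared across input channels, no modulation).
//
// Dense convolutions go through im2col + BLAS GEMM; the deformable kernel
// builds its column matrix by bilinear sampling (zero padding outside the
// frame) so the same GEMM applies, and the backward pass scatters gradients
// to the four interpolation corners and to the offsets analytically.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * c;
        for (int xo = 0; xo < Wo; ++xo) {
          const int xi = xo * stride + j - pad;
          const bool xok = (xi >= 0 && xi < W);
          for (int yo = 0; yo < Ho; ++yo) {
            const int yi = yo * stride + i - pad;
            col(r, yo + (size_t)Ho * xo) =
              (xok && yi >= 0 && yi < H) ? xc[yi + (size_t)H * xi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* gx, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * c;
        for (int xo = 0; xo < Wo; ++xo) {
          const int xi = xo * stride + j - pad;
          if (xi < 0 || xi >= W) continue;
          for (int yo = 0; yo < Ho; ++yo) {
            const int yi = yo * stride + i - pad;
            if (yi < 0 || yi >= H) continue;
            gc[yi + (size_t)H * xi] += col(r, yo + (size_t)Ho * xo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wd[2]);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat col(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat res = col.t() * Wm;           // (Ho*Wo) x Cout
    for (int oc = 0; oc < Cout; ++oc) res.col(oc) += b[oc];
    std::copy(res.begin(), res.end(), out.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat gWm(gw.begin(), k * k * C, Cout, false, true);
  arma::mat col(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    const arma::mat G(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                      (size_t)Ho * Wo, Cout, false, true);
    gWm += col * G;
    for (int oc = 0; oc < Cout; ++oc) gb[oc] += arma::accu(G.col(oc));
    arma::mat gcol = Wm * G.t();            // (k*k*C) x (Ho*Wo)
    col2im_add(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C,
               k, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear sample of one channel plane with zero padding outside
// [0, H-1] x [0, W-1]; corner weights returned for reuse.
struct BilinSite {
  int y0, x0, y1, x1;
  double fy, fx;
  bool v00, v01, v10, v11;  // corner validity
};

static inline BilinSite bilin_site(double sy, double sx, int H, int W) {
  BilinSite s;
  s.y0 = (int)std::floor(sy);
  s.x0 = (int)std::floor(sx);
  s.y1 = s.y0 + 1;
  s.x1 = s.x0 + 1;
  s.fy = sy - s.y0;
  s.fx = sx - s.x0;
  s.v00 = (s.y0 >= 0 && s.y0 < H && s.x0 >= 0 && s.x0 < W);
  s.v01 = (s.y0 >= 0 && s.y0 < H && s.x1 >= 0 && s.x1 < W);
  s.v10 = (s.y1 >= 0 && s.y1 < H && s.x0 >= 0 && s.x0 < W);
  s.v11 = (s.y1 >= 0 && s.y1 < H && s.x1 >= 0 && s.x1 < W);
  return s;
}

static inline double bilin_value(const double* xc, int H, const BilinSite& s) {
  const double a00 = s.v00 ? xc[s.y0 + (size_t)H * s.x0] : 0.0;
  const double a01 = s.v01 ? xc[s.y0 + (size_t)H * s.x1] : 0.0;
  const double a10 = s.v10 ? xc[s.y1 + (size_t)H * s.x0] : 0.0;
  const double a11 = s.v11 ? xc[s.y1 + (size_t)H * s.x1] : 0.0;
  return (1 - s.fy) * ((1 - s.fx) * a00 + s.fx * a01) +
         s.fy * ((1 - s.fx) * a10 + s.fx * a11);
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix map, NumericVector y,
                                  NumericVector x) {
  const int H = map.nrow(), W = map.ncol(), n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    BilinSite s = bilin_site(y[i], x[i], H, W);
    out[i] = bilin_value(map.begin(), H, s);
  }
  return out;
}

static void dcol_fill(const double* x, const double* off, int H, int W, int C,
                      int k, int pad, arma::mat& dcol) {
  const int k2 = k * k;
  for (int xo = 0; xo < W; ++xo) {
    for (int yo = 0; yo < H; ++yo) {
      const size_t q = yo + (size_t)H * xo;
      for (int t = 0; t < k2; ++t) {
        const int i = t / k, j = t % k;
        const double dy = off[yo + (size_t)H * (xo + (size_t)W * (2 * t))];
        const double dx = off[yo + (size_t)H * (xo + (size_t)W * (2 * t + 1))];
        const BilinSite s = bilin_site(yo + i - pad + dy, xo + j - pad + dx, H, W);
        for (int c = 0; c < C; ++c) {
          dcol(i + k * j + k2 * c, q) = bilin_value(x + (size_t)H * W * c, H, s);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_dconv2d_fw(NumericVector x, NumericVector w,
                             NumericVector b, NumericVector off) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  IntegerVector od = off.attr("dim");
  if (od[0] != H || od[1] != W || od[2] != 2 * k * k)
    stop("dconv2d: offset field shape mismatch");
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat dcol(k * k * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    dcol_fill(x.begin() + (size_t)H * W * C * n,
              off.begin() + (size_t)H * W * 2 * k * k * n, H, W, C, k, pad, dcol);
    arma::mat res = dcol.t() * Wm;
    for (int oc = 0; oc < Cout; ++oc) res.col(oc) += b[oc];
    std::copy(res.begin(), res.end(), out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dconv2d_bw(NumericVector x, NumericVector w, NumericVector off,
                    NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, k2 = k * k;
  NumericVector gx((size_t)H * W * C * N), gw(w.size()), gb(Cout), goff(off.size());
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  goff.attr("dim") = off.attr("dim");
  const arma::mat Wm(const_cast<double*>(w.begin()), k2 * C, Cout, false, true);
  arma::mat gWm(gw.begin(), k2 * C, Cout, false, true);
  arma::mat dcol(k2 * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const double* offn = off.begin() + (size_t)H * W * 2 * k2 * n;
    double* gxn = gx.begin() + (size_t)H * W * C * n;
    double* goffn = goff.begin() + (size_t)H * W * 2 * k2 * n;
    dcol_fill(xn, offn, H, W, C, k, pad, dcol);
    const arma::mat G(const_cast<double*>(gy.begin()) + (size_t)H * W * Cout * n,
                      (size_t)H * W, Cout, false, true);
    gWm += dcol * G;
    for (int oc = 0; oc < Cout; ++oc) gb[oc] += arma::accu(G.col(oc));
    arma::mat gcol = Wm * G.t();            // (k2*C) x (H*W)
    for (int xo = 0; xo < W; ++xo) {
      for (int yo = 0; yo < H; ++yo) {
        const size_t q = yo + (size_t)H * xo;
        for (int t = 0; t < k2; ++t) {
          const int i = t / k, j = t % k;
          const double dy = offn[yo + (size_t)H * (xo + (size_t)W * (2 * t))];
          const double dx = offn[yo + (size_t)H * (xo + (size_t)W * (2 * t + 1))];
          const BilinSite s = bilin_site(yo + i - pad + dy, xo + j - pad + dx, H, W);
          double gdy = 0.0, gdx = 0.0;
          for (int c = 0; c < C; ++c) {
            const double g = gcol(i + k * j + k2 * c, q);
            if (g == 0.0) continue;
            const double* xc = xn + (size_t)H * W * c;
            double* gc = gxn + (size_t)H * W * c;
            const double a00 = s.v00 ? xc[s.y0 + (size_t)H * s.x0] : 0.0;
            const double a01 = s.v01 ? xc[s.y0 + (size_t)H * s.x1] : 0.0;
            const double a10 = s.v10 ? xc[s.y1 + (size_t)H * s.x0] : 0.0;
            const double a11 = s.v11 ? xc[s.y1 + (size_t)H * s.x1] : 0.0;
            if (s.v00) gc[s.y0 + (size_t)H * s.x0] += g * (1 - s.fy) * (1 - s.fx);
            if (s.v01) gc[s.y0 + (size_t)H * s.x1] += g * (1 - s.fy) * s.fx;
            if (s.v10) gc[s.y1 + (size_t)H * s.x0] += g * s.fy * (1 - s.fx);
            if (s.v11) gc[s.y1 + (size_t)H * s.x1] += g * s.fy * s.fx;
            gdy += g * ((1 - s.fx) * (a10 - a00) + s.fx * (a11 - a01));
            gdx += g * ((1 - s.fy) * (a01 - a00) + s.fy * (a11 - a10));
          }
          goffn[yo + (size_t)H * (xo + (size_t)W * (2 * t))] += gdy;
          goffn[yo + (size_t)H * (xo + (size_t)W * (2 * t + 1))] += gdx;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["goff"] = goff);
}
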