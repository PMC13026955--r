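// Image kernels: BT.601 grayscale, uniform-LBP coding, and the fused
// flip + rotate + colour-jitter augmentation warp.

#include <Rcpp.h>
using namespace Rcpp;

// round half away from zero (matches the R-side convention)
static inline double rhu(double x) { return std::floor(x + 0.5); }

// [[Rcpp::export(name = ".gray601")]]
NumericMatrix gray601(NumericVector img) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix out(H, W);
  const double* p = REAL(img);
  for (R_xlen_t i = 0; i < HW; ++i)
    out[i] = rhu(0.299 * p[i] + 0.587 * p[i + HW] + 0.114 * p[i + 2 * HW]);
  return out;
}

// Uniform LBP codes (P = 8, R = 1, replicate padding) through a mapping
// table. Ring: clockwise from top-left of the 3x3 square, weight 2^p.
// [[Rcpp::export(name = ".lbp_u2")]]
IntegerMatrix lbp_u2(NumericMatrix img, IntegerVector table) {
  const int H = img.nrow(), W = img.ncol();
  static const int dy[8] = { -1, -1, -1, 0, 1, 1, 1, 0 };
  static const int dx[8] = { -1, 0, 1, 1, 1, 0, -1, -1 };
  IntegerMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double c = img(y, x);
      int code = 0;
      for (int p = 0; p < 8; ++p) {
        int sy = y + dy[p]; if (sy < 0) sy = 0; else if (sy >= H) sy = H - 1;
        int sx = x + dx[p]; if (sx < 0) sx = 0; else if (sx >= W) sx = W - 1;
        if (img(sy, sx) >= c) code |= (1 << p);
      }
      out(y, x) = table[code];
    }
  }
  return out;
}

// Fused augmentation: horizontal flip, rotation about the centre (bilinear,
// zero fill), then colour jitter — brightness scale f1, contrast blend f2
// about the post-brightness grayscale mean, saturation blend f3 against the
// per-pixel grayscale. Output clipped to [0, 255].
// [[Rcpp::export(name = ".augment_warp")]]
NumericVector augment_warp(NumericVector img, bool flip, double angle_deg,
                           double f1, double f2, double f3) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(3 * HW);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  const double* src = REAL(img);
  double* dst = REAL(out);

  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const bool rot = std::fabs(angle_deg) > 1e-12;

  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double sy, sx;
      if (rot) {
        const double ry = y - cy, rx = x - cx;
        sy = ca * ry - sa * rx + cy;
        sx = sa * ry + ca * rx + cx;
      } else { sy = y; sx = x; }
      double v[3] = { 0.0, 0.0, 0.0 };
      if (sy >= 0 && sy <= H - 1 && sx >= 0 && sx <= W - 1) {
        const int y0 = (int)sy, x0 = (int)sx;
        const int y1 = y0 < H - 1 ? y0 + 1 : y0;
        const int x1 = x0 < W - 1 ? x0 + 1 : x0;
        const double fy = sy - y0, fx = sx - x0;
        int sx0 = flip ? W - 1 - x0 : x0;
        int sx1 = flip ? W - 1 - x1 : x1;
        for (int c = 0; c < 3; ++c) {
          const double* pl = src + (R_xlen_t)c * HW;
          v[c] = pl[(R_xlen_t)sx0 * H + y0] * (1 - fy) * (1 - fx)
               + pl[(R_xlen_t)sx0 * H + y1] * fy * (1 - fx)
               + pl[(R_xlen_t)sx1 * H + y0] * (1 - fy) * fx
               + pl[(R_xlen_t)sx1 * H + y1] * fy * fx;
        }
      }
      const R_xlen_t j = (R_xlen_t)x * H + y;
      dst[j] = v[0]; dst[j + HW] = v[1]; dst[j + 2 * HW] = v[2];
    }
  }

  // brightness
  for (R_xlen_t i = 0; i < 3 * HW; ++i) dst[i] *= f1;
  // contrast about the grayscale mean
  double gsum = 0.0;
  for (R_xlen_t i = 0; i < HW; ++i)
    gsum += 0.299 * dst[i] + 0.587 * dst[i + HW] + 0.114 * dst[i + 2 * HW];
  const double gm = gsum / HW;
  for (R_xlen_t i = 0; i < 3 * HW; ++i) dst[i] = f2 * dst[i] + (1 - f2) * gm;
  // saturation against the per-pixel grayscale, then clip
  for (R_xlen_t i = 0; i < HW; ++i) {
    const double g = 0.299 * dst[i] + 0.587 * dst[i + HW] + 0.114 * dst[i + 2 * HW];
    for (int c = 0; c < 3; ++c) {
      double v = f3 * dst[i + (R_xlen_t)c * HW] + (1 - f3) * g;
      dst[i + (R_xlen_t)c * HW] = v < 0 ? 0 : (v > 255 ? 255 : v);
    }
  }
  return out;
}
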