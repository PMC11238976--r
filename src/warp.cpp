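#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-mapped affine warp with bilinear interpolation. M holds the
// inverse map (a11, a12, a13, a21, a22, a23) in 0-based pixel coordinates:
// source_x = a11*x + a12*y + a13, source_y = a21*x + a22*y + a23.
// Samples falling outside the source are set to the border constant.
// Exact at integer source coordinates, so integer translations are lossless.
// Bilinear resize with pixel-center alignment: output pixel (x, y) samples
// the source at ((x + 0.5) * w_src / w_out - 0.5, ...). Used to build the
// detection pyramids.
// [[Rcpp::export]]
IntegerMatrix cpp_resize(IntegerMatrix src, int out_h, int out_w) {
  int h = src.nrow(), w = src.ncol();
  IntegerMatrix out(out_h, out_w);
  double ry = static_cast<double>(h) / out_h;
  double rx = static_cast<double>(w) / out_w;
  for (int y = 0; y < out_h; ++y) {
    double ys = (y + 0.5) * ry - 0.5;
    if (ys < 0) ys = 0;
    if (ys > h - 1) ys = h - 1;
    int y0 = static_cast<int>(std::floor(ys));
    int y1 = y0 + 1 < h ? y0 + 1 : y0;
    double fy = ys - y0;
    for (int x = 0; x < out_w; ++x) {
      double xs = (x + 0.5) * rx - 0.5;
      if (xs < 0) xs = 0;
      if (xs > w - 1) xs = w - 1;
      int x0 = static_cast<int>(std::floor(xs));
      int x1 = x0 + 1 < w ? x0 + 1 : x0;
      double fx = xs - x0;
      double v = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                 fy * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
      out(y, x) = static_cast<int>(std::floor(v + 0.5));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix src, NumericVector M, double border) {
  int h = src.nrow(), w = src.ncol();
  NumericMatrix out(h, w);
  double a11 = M[0], a12 = M[1], a13 = M[2], a21 = M[3], a22 = M[4], a23 = M[5];
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double xs = a11 * x + a12 * y + a13;
      double ys = a21 * x + a22 * y + a23;
      // small tolerance so exact-boundary coordinates (e.g. 90-degree
      // rotations, where cos produces ~1e-17 residues) stay inside
      const double eps = 1e-9;
      if (xs < -eps || xs > w - 1 + eps || ys < -eps || ys > h - 1 + eps) {
        out(y, x) = border;
        continue;
      }
      if (xs < 0) xs = 0;
      if (xs > w - 1) xs = w - 1;
      if (ys < 0) ys = 0;
      if (ys > h - 1) ys = h - 1;
      int x0 = static_cast<int>(std::floor(xs));
      int y0 = static_cast<int>(std::floor(ys));
      int x1 = x0 + 1 < w ? x0 + 1 : x0;
      int y1 = y0 + 1 < h ? y0 + 1 : y0;
      double fx = xs - x0, fy = ys - y0;
      out(y, x) = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                  fy * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
    }
  }
  return out;
}
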