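#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bresenham circle of radius 3 used by the FAST-9/16 segment test
// (x = column offset, y = row offset), clockwise from 12 o'clock.
static const int CX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int CY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

// FAST-9/16 segment-test corner detector with 3x3 non-maximum suppression.
// A pixel is a corner when >= 9 contiguous circle pixels are all brighter
// than p + t or all darker than p - t. The score is the summed threshold
// excess over the qualifying polarity. Coordinates returned are 0-based.
// [[Rcpp::export]]
DataFrame cpp_fast_detect(IntegerMatrix img, int threshold, int margin, bool nonmax) {
  int h = img.nrow(), w = img.ncol();
  int m = margin < 3 ? 3 : margin;
  std::vector<int> sc(static_cast<size_t>(h) * w, 0);
  std::vector<int> xs, ys;
  for (int y = m; y < h - m; ++y) {
    for (int x = m; x < w - m; ++x) {
      int p = img(y, x);
      int d[16];
      for (int k = 0; k < 16; ++k) d[k] = img(y + CY[k], x + CX[k]) - p;
      int runB = 0, maxB = 0, runD = 0, maxD = 0;
      for (int k = 0; k < 32; ++k) {
        int dk = d[k & 15];
        if (dk > threshold) { if (++runB > maxB) maxB = runB; } else runB = 0;
        if (dk < -threshold) { if (++runD > maxD) maxD = runD; } else runD = 0;
      }
      int s = 0;
      if (maxB >= 9) {
        for (int k = 0; k < 16; ++k) if (d[k] > threshold) s += d[k] - threshold;
      } else if (maxD >= 9) {
        for (int k = 0; k < 16; ++k) if (d[k] < -threshold) s += -d[k] - threshold;
      } else {
        continue;
      }
      sc[static_cast<size_t>(y) * w + x] = s + 1; // +1 keeps zero = "not a corner"
      xs.push_back(x);
      ys.push_back(y);
    }
  }
  std::vector<double> ox, oy;
  std::vector<int> os;
  for (size_t i = 0; i < xs.size(); ++i) {
    int x = xs[i], y = ys[i];
    int s = sc[static_cast<size_t>(y) * w + x];
    if (nonmax) {
      bool keep = true;
      for (int dy = -1; dy <= 1 && keep; ++dy) {
        for (int dx = -1; dx <= 1 && keep; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int sn = sc[static_cast<size_t>(y + dy) * w + (x + dx)];
          if (sn > s) keep = false;
          // equal scores: the first candidate in scan order wins
          else if (sn == s && sn > 0 && (dy < 0 || (dy == 0 && dx < 0))) keep = false;
        }
      }
      if (!keep) continue;
    }
    // sub-pixel localization: 1-D parabola through the score profile in x
    // and y, clamped to half a pixel (keeps detections stable when the true
    // corner sits between pixels, e.g. after pyramid resampling)
    double fx = 0.0, fy = 0.0;
    {
      double sl = sc[static_cast<size_t>(y) * w + (x - 1)];
      double sr = sc[static_cast<size_t>(y) * w + (x + 1)];
      double den = sl - 2.0 * s + sr;
      if (den < 0) fx = 0.5 * (sl - sr) / den;
      double su = sc[static_cast<size_t>(y - 1) * w + x];
      double sd = sc[static_cast<size_t>(y + 1) * w + x];
      den = su - 2.0 * s + sd;
      if (den < 0) fy = 0.5 * (su - sd) / den;
      if (fx > 0.5) fx = 0.5;
      if (fx < -0.5) fx = -0.5;
      if (fy > 0.5) fy = 0.5;
      if (fy < -0.5) fy = -0.5;
    }
    ox.push_back(x + fx);
    oy.push_back(y + fy);
    os.push_back(s - 1);
  }
  return DataFrame::create(_["x"] = ox, _["y"] = oy, _["response"] = os);
}

// Cross-scale non-maximum suppression for multi-scale detections: keypoints
// are visited strongest-first (ties: smaller y, then x) and a candidate is
// dropped when an already accepted keypoint lies within
// radius_mult * max(scale_i, scale_j) pixels. This assigns each image
// structure a single scale, as scale-space detectors do. Returns a logical
// keep mask in input order.
// [[Rcpp::export]]
LogicalVector cpp_scale_nms(NumericVector x, NumericVector y,
                            NumericVector scale, NumericVector response,
                            double radius_mult, double max_scale) {
  int n = x.size();
  LogicalVector keep(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (response[a] != response[b]) return response[a] > response[b];
    if (y[a] != y[b]) return y[a] < y[b];
    return x[a] < x[b];
  });
  double cell = radius_mult * max_scale;
  if (cell < 1.0) cell = 1.0;
  // spatial hash of accepted points
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](double px, double py) {
    long long gx = static_cast<long long>(std::floor(px / cell));
    long long gy = static_cast<long long>(std::floor(py / cell));
    return (gx << 32) ^ (gy & 0xffffffffLL);
  };
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    bool ok = true;
    long long gx = static_cast<long long>(std::floor(x[i] / cell));
    long long gy = static_cast<long long>(std::floor(y[i] / cell));
    for (long long dy = -1; dy <= 1 && ok; ++dy) {
      for (long long dx = -1; dx <= 1 && ok; ++dx) {
        long long k = ((gx + dx) << 32) ^ ((gy + dy) & 0xffffffffLL);
        auto it = grid.find(k);
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double r = radius_mult * (scale[i] > scale[j] ? scale[i] : scale[j]);
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r * r) { ok = false; break; }
        }
      }
    }
    if (ok) {
      keep[i] = true;
      grid[key(x[i], y[i])].push_back(i);
    }
  }
  return keep;
}

// ---- shared sampling helpers -------------------------------------------------

// summed-area table, S(y, x) = sum of img[0..y-1, 0..x-1], size (h+1) x (w+1)
static void build_sat(const IntegerMatrix& img, std::vector<double>& S) {
  int h = img.nrow(), w = img.ncol();
  S.assign(static_cast<size_t>(h + 1) * (w + 1), 0.0);
  for (int y = 0; y < h; ++y) {
    double row = 0.0;
    for (int x = 0; x < w; ++x) {
      row += img(y, x);
      S[static_cast<size_t>(y + 1) * (w + 1) + (x + 1)] =
          S[static_cast<size_t>(y) * (w + 1) + (x + 1)] + row;
    }
  }
}

// mean over the clamped box [x-hw, x+hw] x [y-hw, y+hw]
static double box_mean(const std::vector<double>& S, int h, int w, int x, int y, int hw) {
  int x0 = x - hw, x1 = x + hw, y0 = y - hw, y1 = y + hw;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (x1 > w - 1) x1 = w - 1;
  if (y1 > h - 1) y1 = h - 1;
  int W = w + 1;
  double s = S[static_cast<size_t>(y1 + 1) * W + (x1 + 1)] -
             S[static_cast<size_t>(y0) * W + (x1 + 1)] -
             S[static_cast<size_t>(y1 + 1) * W + x0] +
             S[static_cast<size_t>(y0) * W + x0];
  return s / ((x1 - x0 + 1) * (y1 - y0 + 1));
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// box mean at a sub-pixel centre: bilinear interpolation of the four
// integer-centred box means, so descriptor samples vary continuously with
// refined keypoint positions
static double box_mean_sub(const std::vector<double>& S, int h, int w,
                           double X, double Y, int hw) {
  int x0 = static_cast<int>(std::floor(X));
  int y0 = static_cast<int>(std::floor(Y));
  double fx = X - x0, fy = Y - y0;
  double v00 = box_mean(S, h, w, x0, y0, hw);
  double v10 = box_mean(S, h, w, x0 + 1, y0, hw);
  double v01 = box_mean(S, h, w, x0, y0 + 1, hw);
  double v11 = box_mean(S, h, w, x0 + 1, y0 + 1, hw);
  return (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11);
}

static double bilinear(const IntegerMatrix& img, double X, double Y) {
  int h = img.nrow(), w = img.ncol();
  X = clampd(X, 0.0, w - 1.0);
  Y = clampd(Y, 0.0, h - 1.0);
  int x0 = static_cast<int>(std::floor(X)), y0 = static_cast<int>(std::floor(Y));
  int x1 = x0 + 1 < w ? x0 + 1 : x0;
  int y1 = y0 + 1 < h ? y0 + 1 : y0;
  double fx = X - x0, fy = Y - y0;
  double v00 = img(y0, x0), v10 = img(y0, x1), v01 = img(y1, x0), v11 = img(y1, x1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11);
}

// Harris corner response over a (2*block+1)^2 window of Sobel gradients,
// used to rank keypoints (noise-induced segment-test corners in flat
// regions score orders of magnitude below true structure corners).
// [[Rcpp::export]]
NumericVector cpp_harris_response(IntegerMatrix img, NumericVector x,
                                  NumericVector y, int block, double k) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int cx = static_cast<int>(std::lround(x[i]));
    int cy = static_cast<int>(std::lround(y[i]));
    double sxx = 0, syy = 0, sxy = 0;
    for (int dy = -block; dy <= block; ++dy) {
      int yy = cy + dy;
      if (yy < 1 || yy > h - 2) continue;
      for (int dx = -block; dx <= block; ++dx) {
        int xx = cx + dx;
        if (xx < 1 || xx > w - 2) continue;
        double gx = (img(yy - 1, xx + 1) + 2.0 * img(yy, xx + 1) + img(yy + 1, xx + 1)) -
                    (img(yy - 1, xx - 1) + 2.0 * img(yy, xx - 1) + img(yy + 1, xx - 1));
        double gy = (img(yy + 1, xx - 1) + 2.0 * img(yy + 1, xx) + img(yy + 1, xx + 1)) -
                    (img(yy - 1, xx - 1) + 2.0 * img(yy - 1, xx) + img(yy - 1, xx + 1));
        sxx += gx * gx;
        syy += gy * gy;
        sxy += gx * gy;
      }
    }
    out[i] = (sxx * syy - sxy * sxy) - k * (sxx + syy) * (sxx + syy);
  }
  return out;
}

// Gradient-based sub-pixel corner refinement (the classic iterative
// corner-localization step): around the current estimate, every window
// pixel contributes its gradient outer product; the refined corner is the
// point orthogonal to all gradients, q = (sum G_i)^-1 (sum G_i p_i).
// Iterated a few times with the window recentred; displacement is clamped
// to the window. Keeps descriptor sampling centred on the same physical
// corner regardless of the pyramid level a keypoint was detected on.
// [[Rcpp::export]]
List cpp_corner_refine(IntegerMatrix img, NumericVector x, NumericVector y,
                       NumericVector win_half, int iters) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size();
  NumericVector ox(n), oy(n);
  for (int i = 0; i < n; ++i) {
    double px = x[i], py = y[i];
    int wh = static_cast<int>(win_half[i]);
    if (wh < 2) wh = 2;
    for (int it = 0; it < iters; ++it) {
      int cx = static_cast<int>(std::lround(px));
      int cy = static_cast<int>(std::lround(py));
      double a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0;
      for (int dy = -wh; dy <= wh; ++dy) {
        int yy = cy + dy;
        if (yy < 1 || yy > h - 2) continue;
        for (int dx = -wh; dx <= wh; ++dx) {
          int xx = cx + dx;
          if (xx < 1 || xx > w - 2) continue;
          double gx = 0.5 * (img(yy, xx + 1) - img(yy, xx - 1));
          double gy = 0.5 * (img(yy + 1, xx) - img(yy - 1, xx));
          a11 += gx * gx;
          a12 += gx * gy;
          a22 += gy * gy;
          b1 += gx * gx * xx + gx * gy * yy;
          b2 += gx * gy * xx + gy * gy * yy;
        }
      }
      double det = a11 * a22 - a12 * a12;
      if (std::fabs(det) < 1e-12) break;
      double qx = (a22 * b1 - a12 * b2) / det;
      double qy = (a11 * b2 - a12 * b1) / det;
      // clamp to the search window around the original estimate
      if (qx < x[i] - wh) qx = x[i] - wh;
      if (qx > x[i] + wh) qx = x[i] + wh;
      if (qy < y[i] - wh) qy = y[i] - wh;
      if (qy > y[i] + wh) qy = y[i] + wh;
      if (std::fabs(qx - px) < 1e-3 && std::fabs(qy - py) < 1e-3) {
        px = qx; py = qy;
        break;
      }
      px = qx; py = qy;
    }
    if (px < 0) px = 0;
    if (px > w - 1) px = w - 1;
    if (py < 0) py = 0;
    if (py > h - 1) py = h - 1;
    ox[i] = px;
    oy[i] = py;
  }
  return List::create(_["x"] = ox, _["y"] = oy);
}

// ---- orientation -------------------------------------------------------------

// Intensity-centroid orientation over a disc, degrees in [0, 360).
// [[Rcpp::export]]
NumericVector cpp_orientation_ic(IntegerMatrix img, NumericVector x, NumericVector y, int radius) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int cx = static_cast<int>(std::lround(x[i]));
    int cy = static_cast<int>(std::lround(y[i]));
    double m10 = 0.0, m01 = 0.0;
    for (int dy = -radius; dy <= radius; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= h) continue;
      int dxm = static_cast<int>(std::floor(std::sqrt(
          static_cast<double>(radius) * radius - static_cast<double>(dy) * dy)));
      for (int dx = -dxm; dx <= dxm; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= w) continue;
        double v = img(yy, xx);
        m10 += dx * v;
        m01 += dy * v;
      }
    }
    double a = std::atan2(m01, m10) * 180.0 / M_PI;
    if (a < 0) a += 360.0;
    if (a >= 360.0) a -= 360.0;
    out[i] = a;
  }
  return out;
}

// ---- BRIEF-style descriptor (ORB and REF backends) ---------------------------

// pattern: n_bits x 4 integer matrix of point-pair offsets (x1, y1, x2, y2).
// Each sample is a box mean of half-width smooth_hw; bit b = s(p1) < s(p2).
// Offsets are steered by the keypoint orientation (degrees) and scaled by
// the per-keypoint scale (pattern and smoothing grow with scale, adapting
// the descriptor to pyramid detections); orientation 0 and scale 1 leave
// the pattern untouched. Output: one column of packed bytes per keypoint,
// padded to a multiple of 8 bytes.
// [[Rcpp::export]]
RawMatrix cpp_brief_describe(IntegerMatrix img, NumericVector x, NumericVector y,
                             NumericVector orientation_deg, NumericVector scale,
                             IntegerMatrix pattern, int smooth_hw) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size(), nbits = pattern.nrow();
  int nbytes = ((nbits + 7) / 8 + 7) / 8 * 8;
  RawMatrix out(nbytes, n);
  std::vector<double> S;
  build_sat(img, S);
  for (int i = 0; i < n; ++i) {
    double cx = x[i], cy = y[i];
    double th = orientation_deg[i] * M_PI / 180.0;
    double sc = scale[i];
    double c = std::cos(th), s = std::sin(th);
    int hw = static_cast<int>(std::lround(sc * smooth_hw));
    if (hw < 1) hw = 1;
    for (int b = 0; b < nbits; ++b) {
      double px1 = pattern(b, 0), py1 = pattern(b, 1);
      double px2 = pattern(b, 2), py2 = pattern(b, 3);
      double v1 = box_mean_sub(S, h, w, cx + sc * (c * px1 - s * py1),
                               cy + sc * (s * px1 + c * py1), hw);
      double v2 = box_mean_sub(S, h, w, cx + sc * (c * px2 - s * py2),
                               cy + sc * (s * px2 + c * py2), hw);
      if (v1 < v2) out(b >> 3, i) |= static_cast<Rbyte>(1 << (b & 7));
    }
  }
  return out;
}

// ---- BRISK-style radial-pattern descriptor -----------------------------------

// pts: 60 x 3 matrix (x, y, smoothing half-width) of pattern points on
// concentric rings. short_pairs (0-based, n x 2) give the 512 comparison
// bits; long_pairs estimate the pattern orientation from the smoothed
// intensity gradient before the pattern is rotated.
// [[Rcpp::export]]
RawMatrix cpp_brisk_describe(IntegerMatrix img, NumericVector x, NumericVector y,
                             NumericVector scale, NumericMatrix pts,
                             IntegerMatrix short_pairs, IntegerMatrix long_pairs) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size(), npts = pts.nrow(), nbits = short_pairs.nrow();
  int nbytes = ((nbits + 7) / 8 + 7) / 8 * 8;
  RawMatrix out(nbytes, n);
  std::vector<double> S;
  build_sat(img, S);
  std::vector<double> v0(npts), v(npts);
  for (int i = 0; i < n; ++i) {
    double cx = x[i], cy = y[i];
    double sc = scale[i];
    for (int j = 0; j < npts; ++j) {
      int hw = static_cast<int>(std::lround(sc * pts(j, 2)));
      if (hw < 1) hw = 1;
      v0[j] = box_mean_sub(S, h, w, cx + sc * pts(j, 0), cy + sc * pts(j, 1), hw);
    }
    double gx = 0.0, gy = 0.0;
    for (int q = 0; q < long_pairs.nrow(); ++q) {
      int a = long_pairs(q, 0), b = long_pairs(q, 1);
      double dx = sc * (pts(b, 0) - pts(a, 0));
      double dy = sc * (pts(b, 1) - pts(a, 1));
      double n2 = dx * dx + dy * dy;
      if (n2 <= 0) continue;
      double diff = v0[b] - v0[a];
      gx += diff * dx / n2;
      gy += diff * dy / n2;
    }
    double th = std::atan2(gy, gx);
    double c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < npts; ++j) {
      int hw = static_cast<int>(std::lround(sc * pts(j, 2)));
      if (hw < 1) hw = 1;
      double rx = c * pts(j, 0) - s * pts(j, 1);
      double ry = s * pts(j, 0) + c * pts(j, 1);
      v[j] = box_mean_sub(S, h, w, cx + sc * rx, cy + sc * ry, hw);
    }
    for (int b = 0; b < nbits; ++b) {
      if (v[short_pairs(b, 0)] < v[short_pairs(b, 1)]) {
        out(b >> 3, i) |= static_cast<Rbyte>(1 << (b & 7));
      }
    }
  }
  return out;
}

// ---- MLDB-style descriptor (AKAZE backend) -----------------------------------

// Modified-local-difference-binary: over an oriented square patch of
// half-width half_base * scale, grids of 2x2, 3x3 and 4x4 cells are formed;
// per cell the mean intensity and mean x/y derivative (step = scale) are
// computed from a 3x3 sample lattice per cell, and every cell pair is
// compared per channel: 3 * (6 + 36 + 120) = 486 bits.
// [[Rcpp::export]]
RawMatrix cpp_mldb_describe(IntegerMatrix img, NumericVector x, NumericVector y,
                            NumericVector orientation_deg, double scale, int half_base) {
  static const int grids[3] = {2, 3, 4};
  int n = x.size();
  int nbits = 0;
  for (int g = 0; g < 3; ++g) {
    int cells = grids[g] * grids[g];
    nbits += 3 * cells * (cells - 1) / 2;
  }
  int nbytes = ((nbits + 7) / 8 + 7) / 8 * 8;
  RawMatrix out(nbytes, n);
  double half = half_base * scale;
  double step = scale < 1.0 ? 1.0 : scale;
  for (int i = 0; i < n; ++i) {
    double cx = x[i], cy = y[i];
    double th = orientation_deg[i] * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    int bit = 0;
    for (int g = 0; g < 3; ++g) {
      int G = grids[g];
      int lat = 3 * G; // sample lattice per axis
      int cells = G * G;
      std::vector<double> mi(cells, 0.0), mdx(cells, 0.0), mdy(cells, 0.0);
      std::vector<int> cnt(cells, 0);
      for (int sy = 0; sy < lat; ++sy) {
        double v = -half + (sy + 0.5) * (2.0 * half / lat);
        for (int sx = 0; sx < lat; ++sx) {
          double u = -half + (sx + 0.5) * (2.0 * half / lat);
          double X = cx + c * u - s * v;
          double Y = cy + s * u + c * v;
          double I0 = bilinear(img, X, Y);
          // derivatives along the rotated patch axes
          double dxv = bilinear(img, X + step * c, Y + step * s) -
                       bilinear(img, X - step * c, Y - step * s);
          double dyv = bilinear(img, X - step * s, Y + step * c) -
                       bilinear(img, X + step * s, Y - step * c);
          int cell = (sy / 3) * G + (sx / 3);
          mi[cell] += I0;
          mdx[cell] += dxv;
          mdy[cell] += dyv;
          cnt[cell] += 1;
        }
      }
      for (int cidx = 0; cidx < cells; ++cidx) {
        mi[cidx] /= cnt[cidx];
        mdx[cidx] /= cnt[cidx];
        mdy[cidx] /= cnt[cidx];
      }
      const std::vector<double>* chans[3] = {&mi, &mdx, &mdy};
      for (int ch = 0; ch < 3; ++ch) {
        const std::vector<double>& m = *chans[ch];
        for (int a = 0; a < cells; ++a) {
          for (int b = a + 1; b < cells; ++b) {
            if (m[a] > m[b]) out(bit >> 3, i) |= static_cast<Rbyte>(1 << (bit & 7));
            ++bit;
          }
        }
      }
    }
  }
  return out;
}
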