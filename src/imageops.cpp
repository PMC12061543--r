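#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric reflection: ... c b a | a b c ... | c b a ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable Gaussian convolution with reflective borders.
// Kernel radius = max(1, ceil(3*sigma)); sigma == 0 returns the input.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0.0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // along rows (vertical direction, first index)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * img(reflect_idx(i + d, H), j);
      tmp(i, j) = acc;
    }
  // along columns (horizontal direction, second index)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * tmp(i, reflect_idx(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// Local mean over an odd window x window neighbourhood, reflective borders.
// Separable direct sums (no integral image) so summation order is simple.
// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix img, int window) {
  int H = img.nrow(), W = img.ncol();
  int r = window / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += img(reflect_idx(i + d, H), j);
      tmp(i, j) = acc;
    }
  double denom = (double)window * (double)window;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += tmp(i, reflect_idx(j + d, W));
      out(i, j) = acc / denom;
    }
  return out;
}

// Connected components of a binary mask by BFS in raster (row-major) order,
// so component ids are assigned in raster order of each component's first
// pixel. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next_id = 0;
  std::deque<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next_id;
      lab(i, j) = next_id;
      q.clear();
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop_front();
        for (int t = 0; t < nn; ++t) {
          int ri = p.first + dr[t], cj = p.second + dc[t];
          if (ri < 0 || ri >= H || cj < 0 || cj >= W) continue;
          if (mask(ri, cj) != 0 && lab(ri, cj) == 0) {
            lab(ri, cj) = next_id;
            q.push_back(std::make_pair(ri, cj));
          }
        }
      }
    }
  return lab;
}

// Binary dilation with a Euclidean disk (dx^2 + dy^2 <= radius^2).
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_disk(IntegerMatrix mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), 0);
  std::vector<int> offr, offc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) {
        offr.push_back(a);
        offc.push_back(b);
      }
  int no = (int)offr.size();
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0) continue;
      for (int t = 0; t < no; ++t) {
        int ri = i + offr[t], cj = j + offc[t];
        if (ri >= 0 && ri < H && cj >= 0 && cj < W) out(ri, cj) = 1;
      }
    }
  return out;
}

// Stamp filled disks (vessel cross-sections) at fractional centres into a
// binary mask. rows/cols are 1-based centre coordinates, radii in pixels.
// [[Rcpp::export]]
IntegerMatrix cpp_stamp_disks(int H, int W, NumericVector rows,
                              NumericVector cols, NumericVector radii) {
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), 0);
  int n = rows.size();
  for (int t = 0; t < n; ++t) {
    double cr = rows[t] - 1.0, cc = cols[t] - 1.0, rad = radii[t];
    int lo_r = std::max(0, (int)std::floor(cr - rad));
    int hi_r = std::min(H - 1, (int)std::ceil(cr + rad));
    int lo_c = std::max(0, (int)std::floor(cc - rad));
    int hi_c = std::min(W - 1, (int)std::ceil(cc + rad));
    double r2 = rad * rad;
    for (int i = lo_r; i <= hi_r; ++i)
      for (int j = lo_c; j <= hi_c; ++j) {
        double dy = i - cr, dx = j - cc;
        if (dy * dy + dx * dx <= r2) out(i, j) = 1;
      }
  }
  return out;
}
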