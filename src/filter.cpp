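#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Symmetric (mirror) reflection of an out-of-range index into [0, n-1];
// p[-1] maps to p[1], p[n] to p[n-2].  Assumes |overshoot| < n.
static inline int reflect(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// 2-D correlation with an odd-sized kernel under reflect padding.  Used by
// the classical edge operators (Sobel/Prewitt/Gaussian smoothing); kernels
// are small so plain loops suffice.
// [[Rcpp::export(name = ".cg_filter2_reflect")]]
NumericMatrix cg_filter2_reflect(NumericMatrix x, NumericMatrix k) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = k.nrow(), kw = k.ncol();
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel dimensions must be odd");
  if (kh > 2 * H - 1 || kw > 2 * W - 1) stop("kernel larger than image");
  const int ry = kh / 2, rx = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int dx = -rx; dx <= rx; ++dx) {
        int jj = reflect(j + dx, W);
        for (int dy = -ry; dy <= ry; ++dy) {
          int ii = reflect(i + dy, H);
          acc += x(ii, jj) * k(dy + ry, dx + rx);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Hysteresis thresholding for Canny: seeds are pixels >= high; weak pixels
// (>= low) are kept when 8-connected to a seed.  nms holds the
// non-maximum-suppressed magnitudes.
// [[Rcpp::export(name = ".cg_hysteresis")]]
LogicalMatrix cg_hysteresis(NumericMatrix nms, double low, double high) {
  const int H = nms.nrow(), W = nms.ncol();
  LogicalMatrix keep(H, W);
  std::vector<int> stack;
  stack.reserve(H * W / 4);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (nms(i, j) >= high) {
        keep(i, j) = true;
        stack.push_back(j * H + i);
      }
  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int ur = u % H, uc = u / H;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= H || vc < 0 || vc >= W) continue;
      if (!keep(vr, vc) && nms(vr, vc) >= low) {
        keep(vr, vc) = true;
        stack.push_back(vc * H + vr);
      }
    }
  }
  return keep;
}
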