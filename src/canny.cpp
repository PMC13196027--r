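#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Canny edge detector: binomial smoothing, Sobel gradients,
// non-maximum suppression along the quantized gradient direction and
// two-threshold hysteresis (weak edges kept when 8-connected to a
// strong pixel).

static inline int reflc(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// [[Rcpp::export]]
LogicalMatrix canny_cpp(NumericMatrix frame, int smooth_passes, double low,
                        double high) {
  int nr = frame.nrow(), nc = frame.ncol();
  std::vector<double> a(frame.begin(), frame.end());
  std::vector<double> t((size_t)nr * nc);
  for (int p = 0; p < smooth_passes; ++p) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        t[(size_t)c * nr + r] = 0.25 * a[(size_t)c * nr + reflc(r - 1, nr)] +
                                0.5 * a[(size_t)c * nr + r] +
                                0.25 * a[(size_t)c * nr + reflc(r + 1, nr)];
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        a[(size_t)c * nr + r] = 0.25 * t[(size_t)reflc(c - 1, nc) * nr + r] +
                                0.5 * t[(size_t)c * nr + r] +
                                0.25 * t[(size_t)reflc(c + 1, nc) * nr + r];
  }
  auto at = [&](int r, int c) { return a[(size_t)reflc(c, nc) * nr + reflc(r, nr)]; };
  std::vector<double> gx((size_t)nr * nc), gy((size_t)nr * nc),
      mag((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double sx = at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1) -
                  at(r - 1, c - 1) - 2 * at(r, c - 1) - at(r + 1, c - 1);
      double sy = at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1) -
                  at(r - 1, c - 1) - 2 * at(r - 1, c) - at(r - 1, c + 1);
      size_t k = (size_t)c * nr + r;
      gx[k] = sx; gy[k] = sy; mag[k] = std::sqrt(sx * sx + sy * sy);
    }
  // 0 = strong, 1 = weak, 2 = out
  std::vector<unsigned char> cls((size_t)nr * nc, 2);
  std::vector<size_t> seeds;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      size_t k = (size_t)c * nr + r;
      double m = mag[k];
      if (m < low) continue;
      // quantize gradient direction into 4 sectors
      double angl = std::atan2(gy[k], gx[k]);
      int s = ((int)std::lround(angl / (M_PI / 4)) % 4 + 4) % 4;
      int dr = 0, dc = 0;
      switch (s) {
        case 0: dr = 0; dc = 1; break;   // horizontal gradient
        case 1: dr = 1; dc = 1; break;
        case 2: dr = 1; dc = 0; break;
        case 3: dr = 1; dc = -1; break;
      }
      double m1 = mag[(size_t)reflc(c + dc, nc) * nr + reflc(r + dr, nr)];
      double m2 = mag[(size_t)reflc(c - dc, nc) * nr + reflc(r - dr, nr)];
      if (m < m1 || m < m2) continue;
      if (m >= high) { cls[k] = 0; seeds.push_back(k); }
      else cls[k] = 1;
    }
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), FALSE);
  std::vector<size_t> stack = seeds;
  while (!stack.empty()) {
    size_t k = stack.back(); stack.pop_back();
    if (out[k]) continue;
    out[k] = TRUE;
    int r = (int)(k % nr), c = (int)(k / nr);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int rr = r + dr, cc2 = c + dc;
        if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
        size_t kk = (size_t)cc2 * nr + rr;
        if (!out[kk] && cls[kk] != 2) stack.push_back(kk);
      }
  }
  return out;
}
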