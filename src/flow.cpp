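#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dense pyramidal Lucas-Kanade optical flow.
//
// Frames are numeric matrices in [0,1], rows = image y (downward),
// columns = image x. Displacements are reported as (dx, dy) in pixels
// per frame pair, i.e. frame_b(x + dx, y + dy) ~ frame_a(x, y).
//
// The estimator solves, per pixel, the windowed normal equations
//   [ Sxx Sxy ] [du]   [ -Sxt ]
//   [ Sxy Syy ] [dv] = [ -Syt ]
// with uniform window sums computed by integral images, iterating the
// warp of frame_b at each pyramid level (coarse to fine).

typedef std::vector<double> Vec;

struct Img {
  int nr, nc;
  Vec v; // column-major like R
  Img(int nr_, int nc_) : nr(nr_), nc(nc_), v((size_t)nr_ * nc_, 0.0) {}
  inline double &at(int r, int c) { return v[(size_t)c * nr + r]; }
  inline double cat(int r, int c) const { return v[(size_t)c * nr + r]; }
};

static Img fromR(const NumericMatrix &m) {
  Img out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.v.begin());
  return out;
}

// reflective border lookup
static inline int refl(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// separable [1 2 1]/4 smoothing
static Img blur121(const Img &a) {
  Img t(a.nr, a.nc), out(a.nr, a.nc);
  for (int c = 0; c < a.nc; ++c)
    for (int r = 0; r < a.nr; ++r)
      t.at(r, c) = 0.25 * a.cat(refl(r - 1, a.nr), c) + 0.5 * a.cat(r, c) +
                   0.25 * a.cat(refl(r + 1, a.nr), c);
  for (int c = 0; c < a.nc; ++c)
    for (int r = 0; r < a.nr; ++r)
      out.at(r, c) = 0.25 * t.cat(r, refl(c - 1, a.nc)) + 0.5 * t.cat(r, c) +
                     0.25 * t.cat(r, refl(c + 1, a.nc));
  return out;
}

static Img downsample(const Img &a) {
  Img s = blur121(a);
  int nr = (a.nr + 1) / 2, nc = (a.nc + 1) / 2;
  Img out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out.at(r, c) = s.cat(std::min(2 * r, a.nr - 1), std::min(2 * c, a.nc - 1));
  return out;
}

static inline double bilinear(const Img &a, double r, double c) {
  if (r < 0) r = 0; if (r > a.nr - 1) r = a.nr - 1;
  if (c < 0) c = 0; if (c > a.nc - 1) c = a.nc - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, a.nr - 1), c1 = std::min(c0 + 1, a.nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * a.cat(r0, c0) + fc * a.cat(r0, c1)) +
         fr * ((1 - fc) * a.cat(r1, c0) + fc * a.cat(r1, c1));
}

// integral-image box sum with half-width hw (uniform window)
static Img boxsum(const Img &a, int hw) {
  int nr = a.nr, nc = a.nc;
  // integral image with zero padding row/col 0
  std::vector<double> ii((size_t)(nr + 1) * (nc + 1), 0.0);
  for (int c = 0; c < nc; ++c) {
    double rowsum = 0.0;
    for (int r = 0; r < nr; ++r) {
      rowsum += a.cat(r, c);
      ii[(size_t)(c + 1) * (nr + 1) + (r + 1)] =
          ii[(size_t)c * (nr + 1) + (r + 1)] + rowsum;
    }
  }
  Img out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - hw), c1 = std::min(nc - 1, c + hw);
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - hw), r1 = std::min(nr - 1, r + hw);
      out.at(r, c) = ii[(size_t)(c1 + 1) * (nr + 1) + (r1 + 1)] -
                     ii[(size_t)c0 * (nr + 1) + (r1 + 1)] -
                     ii[(size_t)(c1 + 1) * (nr + 1) + r0] +
                     ii[(size_t)c0 * (nr + 1) + r0];
    }
  }
  return out;
}

// one refinement pass at a single pyramid level; u = dx (cols), v = dy (rows)
static void lk_refine(const Img &A, const Img &B, Img &u, Img &v, int hw,
                      int iters, double min_eig) {
  int nr = A.nr, nc = A.nc;
  Img Ix(nr, nc), Iy(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      Ix.at(r, c) = 0.5 * (A.cat(r, refl(c + 1, nc)) - A.cat(r, refl(c - 1, nc)));
      Iy.at(r, c) = 0.5 * (A.cat(refl(r + 1, nr), c) - A.cat(refl(r - 1, nr), c));
    }
  Img Ixx(nr, nc), Ixy(nr, nc), Iyy(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double gx = Ix.cat(r, c), gy = Iy.cat(r, c);
      Ixx.at(r, c) = gx * gx;
      Ixy.at(r, c) = gx * gy;
      Iyy.at(r, c) = gy * gy;
    }
  Img Sxx = boxsum(Ixx, hw), Sxy = boxsum(Ixy, hw), Syy = boxsum(Iyy, hw);
  Img Ixt(nr, nc), Iyt(nr, nc);
  const double eps = 1e-6; // Tikhonov floor keeps flat regions at zero flow
  for (int it = 0; it < iters; ++it) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double bt = bilinear(B, r + v.cat(r, c), c + u.cat(r, c)) - A.cat(r, c);
        Ixt.at(r, c) = Ix.cat(r, c) * bt;
        Iyt.at(r, c) = Iy.cat(r, c) * bt;
      }
    Img Sxt = boxsum(Ixt, hw), Syt = boxsum(Iyt, hw);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double a11 = Sxx.cat(r, c) + eps, a12 = Sxy.cat(r, c),
               a22 = Syy.cat(r, c) + eps;
        // smaller eigenvalue of the structure tensor: windows without
        // two-dimensional texture (flat background, pure noise) carry
        // no displacement evidence and keep zero flow
        double tr2 = 0.5 * (a11 + a22);
        double dd = 0.5 * (a11 - a22);
        double lmin = tr2 - std::sqrt(dd * dd + a12 * a12);
        if (lmin < min_eig) continue;
        double det = a11 * a22 - a12 * a12;
        if (det < 1e-12) continue;
        double bx = -Sxt.cat(r, c), by = -Syt.cat(r, c);
        double du = (a22 * bx - a12 * by) / det;
        double dv = (a11 * by - a12 * bx) / det;
        // single-pass step clamp: LK linearization only holds locally
        double lim = 1.5;
        if (du > lim) du = lim; else if (du < -lim) du = -lim;
        if (dv > lim) dv = lim; else if (dv < -lim) dv = -lim;
        u.at(r, c) += du;
        v.at(r, c) += dv;
      }
  }
}

// [[Rcpp::export]]
List lk_flow_cpp(NumericMatrix frame_a, NumericMatrix frame_b, int window,
                 int levels, int iterations, int presmooth, double min_eig) {
  if (frame_a.nrow() != frame_b.nrow() || frame_a.ncol() != frame_b.ncol())
    stop("frames must share dimensions");
  int hw = std::max(1, window / 2);
  std::vector<Img> pa, pb;
  Img a0 = fromR(frame_a), b0 = fromR(frame_b);
  for (int k = 0; k < presmooth; ++k) { a0 = blur121(a0); b0 = blur121(b0); }
  pa.push_back(a0);
  pb.push_back(b0);
  for (int l = 1; l < levels; ++l) {
    if (pa.back().nr < 2 * window || pa.back().nc < 2 * window) break;
    pa.push_back(downsample(pa.back()));
    pb.push_back(downsample(pb.back()));
  }
  int top = (int)pa.size() - 1;
  Img u(pa[top].nr, pa[top].nc), v(pa[top].nr, pa[top].nc);
  for (int l = top; l >= 0; --l) {
    lk_refine(pa[l], pb[l], u, v, hw, iterations, min_eig);
    if (l > 0) { // upsample flow to the next finer level
      Img u2(pa[l - 1].nr, pa[l - 1].nc), v2(pa[l - 1].nr, pa[l - 1].nc);
      for (int c = 0; c < u2.nc; ++c)
        for (int r = 0; r < u2.nr; ++r) {
          u2.at(r, c) = 2.0 * bilinear(u, r / 2.0, c / 2.0);
          v2.at(r, c) = 2.0 * bilinear(v, r / 2.0, c / 2.0);
        }
      u = u2;
      v = v2;
    }
  }
  NumericMatrix dx(frame_a.nrow(), frame_a.ncol()),
      dy(frame_a.nrow(), frame_a.ncol());
  std::copy(u.v.begin(), u.v.end(), dx.begin());
  std::copy(v.v.begin(), v.v.end(), dy.begin());
  return List::create(_["dx"] = dx, _["dy"] = dy);
}
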