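// Compiled kernels for the registration engine.
//
// Conventions (package-wide): images are R matrices indexed [row, col];
// point coordinates are 0-based (x, y) = (col, row); pixel centers sit at
// integer coordinates; image bounds are the half-open box [0, W) x [0, H).
// Displacement fields are stored as per-pixel OFFSETS (ux, uy), i.e. the
// mapped coordinate of grid point (x, y) is (x + ux[y,x], y + uy[y,x]).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// samplers

// bilinear sample with clamped borders (used for resampling fields / resize)
static inline double sample_clamped(const NumericMatrix &img, double x, double y) {
  const int H = img.nrow(), W = img.ncol();
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// bilinear sample, out-of-bounds -> fill
static inline double sample_fill(const NumericMatrix &img, double x, double y,
                                 double fill) {
  const int H = img.nrow(), W = img.ncol();
  if (x < 0 || y < 0 || x > W - 1 || y > H - 1) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

static inline double sample_nearest(const NumericMatrix &img, double x, double y,
                                    double fill) {
  const int H = img.nrow(), W = img.ncol();
  long xi = std::lround(x), yi = std::lround(y);
  if (xi < 0 || yi < 0 || xi >= W || yi >= H) return fill;
  return img(yi, xi);
}

// [[Rcpp::export]]
NumericVector cpp_sample_bilinear(NumericMatrix img, NumericVector xs,
                                  NumericVector ys) {
  const int n = xs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_clamped(img, xs[i], ys[i]);
  return out;
}

// ---------------------------------------------------------------------------
// warping

// generic warp: source coordinates given per output pixel
// interp: 0 = nearest, 1 = bilinear
// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix mapx, NumericMatrix mapy,
                       int interp, double fill) {
  const int H = mapx.nrow(), W = mapx.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = interp == 1 ? sample_fill(img, mapx(i, j), mapy(i, j), fill)
                              : sample_nearest(img, mapx(i, j), mapy(i, j), fill);
  return out;
}

// warp through a backward affine map: src = A (x, y)' + b
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector A, NumericVector b,
                              int out_h, int out_w, int interp, double fill) {
  NumericMatrix out(out_h, out_w);
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3];
  for (int j = 0; j < out_w; ++j) {
    for (int i = 0; i < out_h; ++i) {
      double sx = a11 * j + a12 * i + b[0];
      double sy = a21 * j + a22 * i + b[1];
      out(i, j) = interp == 1 ? sample_fill(img, sx, sy, fill)
                              : sample_nearest(img, sx, sy, fill);
    }
  }
  return out;
}

// warp through field-then-affine backward map: src = A (x + ux, y + uy)' + b
// (the nonrigid total field composed with the affine initialization)
// [[Rcpp::export]]
NumericMatrix cpp_warp_field_affine(NumericMatrix img, NumericMatrix ux,
                                    NumericMatrix uy, NumericVector A,
                                    NumericVector b, int interp, double fill) {
  const int H = ux.nrow(), W = ux.ncol();
  NumericMatrix out(H, W);
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double px = j + ux(i, j), py = i + uy(i, j);
      double sx = a11 * px + a12 * py + b[0];
      double sy = a21 * px + a22 * py + b[1];
      out(i, j) = interp == 1 ? sample_fill(img, sx, sy, fill)
                              : sample_nearest(img, sx, sy, fill);
    }
  }
  return out;
}

// resize with clamped-border bilinear (or nearest) sampling;
// coordinate map follows the pixel-center convention:
//   x_src = (x_out + 0.5) * W_in / W_out - 0.5
// [[Rcpp::export]]
NumericMatrix cpp_resize(NumericMatrix img, int out_h, int out_w, int interp) {
  NumericMatrix out(out_h, out_w);
  const double sx = (double)img.ncol() / out_w, sy = (double)img.nrow() / out_h;
  for (int j = 0; j < out_w; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    for (int i = 0; i < out_h; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      if (interp == 1) out(i, j) = sample_clamped(img, xs, ys);
      else {
        double xc = std::min(std::max(xs, 0.0), (double)img.ncol() - 1);
        double yc = std::min(std::max(ys, 0.0), (double)img.nrow() - 1);
        out(i, j) = img((int)std::lround(yc), (int)std::lround(xc));
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflected borders

// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  // horizontal pass
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int jj = j + d;
        if (jj < 0) jj = -jj - 1;            // reflect
        if (jj >= W) jj = 2 * W - jj - 1;
        if (jj < 0) jj = 0; if (jj >= W) jj = W - 1;
        acc += k[d + r] * img(i, jj);
      }
      tmp(i, j) = acc;
    }
  }
  // vertical pass
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        if (ii < 0) ii = 0; if (ii >= H) ii = H - 1;
        acc += k[d + r] * tmp(ii, j);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// windowed (local) normalized cross-correlation via summed-area tables

struct Sat {
  int H, W;
  std::vector<double> t;
  Sat(const NumericMatrix &m, const NumericMatrix *m2 = nullptr)
      : H(m.nrow()), W(m.ncol()), t((H + 1) * (W + 1), 0.0) {
    for (int i = 0; i < H; ++i) {
      double row = 0;
      for (int j = 0; j < W; ++j) {
        row += m2 ? m(i, j) * (*m2)(i, j) : m(i, j);
        t[(i + 1) * (W + 1) + (j + 1)] = t[i * (W + 1) + (j + 1)] + row;
      }
    }
  }
  inline double q(int i0, int j0, int i1, int j1) const { // inclusive box
    return t[(i1 + 1) * (W + 1) + (j1 + 1)] - t[i0 * (W + 1) + (j1 + 1)] -
           t[(i1 + 1) * (W + 1) + j0] + t[i0 * (W + 1) + j0];
  }
};

// mean over pixels of windowed NCC (window radius r, box window);
// zero-variance windows contribute 0.  If grad, also return the force field
// (local-NCC ascent direction w.r.t. the moving image I), per-pixel
//   2 * cross / (varI * varJ) * ((J - Jbar) - cross/varI * (I - Ibar)) * grad(I)
// [[Rcpp::export]]
List cpp_local_ncc(NumericMatrix I, NumericMatrix J, int r, bool grad) {
  const int H = I.nrow(), W = I.ncol();
  if (J.nrow() != H || J.ncol() != W)
    stop("dimension mismatch in local NCC: %dx%d vs %dx%d", H, W, J.nrow(), J.ncol());
  Sat sI(I), sJ(J), sII(I, &I), sJJ(J, &J), sIJ(I, &J);
  const double eps = 1e-10;
  double total = 0;
  NumericMatrix gx, gy;
  if (grad) { gx = NumericMatrix(H, W); gy = NumericMatrix(H, W); }
  for (int i = 0; i < H; ++i) {
    int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
    for (int j = 0; j < W; ++j) {
      int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
      double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
      double mI = sI.q(i0, j0, i1, j1) / n, mJ = sJ.q(i0, j0, i1, j1) / n;
      double vI = sII.q(i0, j0, i1, j1) - n * mI * mI;
      double vJ = sJJ.q(i0, j0, i1, j1) - n * mJ * mJ;
      double cr = sIJ.q(i0, j0, i1, j1) - n * mI * mJ;
      if (vI > eps && vJ > eps) {
        total += cr / std::sqrt(vI * vJ);
        if (grad) {
          double f = 2.0 * cr / (vI * vJ) *
                     ((J(i, j) - mJ) - cr / vI * (I(i, j) - mI));
          double dx = (I(i, std::min(j + 1, W - 1)) - I(i, std::max(j - 1, 0))) * 0.5;
          double dy = (I(std::min(i + 1, H - 1), j) - I(std::max(i - 1, 0), j)) * 0.5;
          gx(i, j) = f * dx;
          gy(i, j) = f * dy;
        }
      }
    }
  }
  double value = total / ((double)H * W);
  if (grad) return List::create(_["value"] = value, _["gx"] = gx, _["gy"] = gy);
  return List::create(_["value"] = value);
}

// ---------------------------------------------------------------------------
// displacement-field algebra

// compose: u'(x) = s(x) + u(x + s(x))   (all offsets on the same grid)
// [[Rcpp::export]]
List cpp_compose_field(NumericMatrix ux, NumericMatrix uy, NumericMatrix sx,
                       NumericMatrix sy) {
  const int H = ux.nrow(), W = ux.ncol();
  NumericMatrix ox(H, W), oy(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double px = j + sx(i, j), py = i + sy(i, j);
      ox(i, j) = sx(i, j) + sample_clamped(ux, px, py);
      oy(i, j) = sy(i, j) + sample_clamped(uy, px, py);
    }
  }
  return List::create(_["ux"] = ox, _["uy"] = oy);
}

// fixed-point inversion: find v with v(x) = -u(x + v(x))
// [[Rcpp::export]]
List cpp_invert_field(NumericMatrix ux, NumericMatrix uy, int max_iter,
                      double tol) {
  const int H = ux.nrow(), W = ux.ncol();
  NumericMatrix vx(H, W), vy(H, W);
  for (int it = 0; it < max_iter; ++it) {
    double worst = 0;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double px = j + vx(i, j), py = i + vy(i, j);
        double nx = -sample_clamped(ux, px, py);
        double ny = -sample_clamped(uy, px, py);
        double d = std::abs(nx - vx(i, j)) + std::abs(ny - vy(i, j));
        if (d > worst) worst = d;
        vx(i, j) = nx;
        vy(i, j) = ny;
      }
    }
    if (worst < tol) break;
  }
  return List::create(_["ux"] = vx, _["uy"] = vy);
}

// ---------------------------------------------------------------------------
// mean-shift filtering (joint spatial/range, circular spatial window)

// channels are expected on a 0..255 scale; color distance is Euclidean over
// the 3 channels; termination when combined spatial+color shift < eps
// [[Rcpp::export]]
List cpp_mean_shift(NumericMatrix c1, NumericMatrix c2, NumericMatrix c3,
                    int sp, double sr, int max_iter, double eps) {
  const int H = c1.nrow(), W = c1.ncol();
  NumericMatrix o1(H, W), o2(H, W), o3(H, W);
  const double sr2 = sr * sr;
  // subsample the spatial window at large radii: the window mean over a
  // stride-2 lattice is indistinguishable at these smoothing scales and
  // cuts the cost by the stride squared
  const int st = std::max(1, sp / 10);
  std::vector<std::pair<int, int> > disk;
  for (int dy = -sp; dy <= sp; dy += st)
    for (int dx = -sp; dx <= sp; dx += st)
      if (dx * dx + dy * dy <= sp * sp) disk.push_back(std::make_pair(dx, dy));
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double x = j, y = i, v1 = c1(i, j), v2 = c2(i, j), v3 = c3(i, j);
      for (int it = 0; it < max_iter; ++it) {
        int cx = (int)std::lround(x), cy = (int)std::lround(y);
        double mx = 0, my = 0, m1 = 0, m2 = 0, m3 = 0;
        int n = 0;
        for (size_t d = 0; d < disk.size(); ++d) {
          int qx = cx + disk[d].first, qy = cy + disk[d].second;
          if (qx < 0 || qy < 0 || qx >= W || qy >= H) continue;
          double d1 = c1(qy, qx) - v1, d2 = c2(qy, qx) - v2, d3 = c3(qy, qx) - v3;
          if (d1 * d1 + d2 * d2 + d3 * d3 > sr2) continue;
          mx += qx; my += qy; m1 += c1(qy, qx); m2 += c2(qy, qx); m3 += c3(qy, qx);
          ++n;
        }
        if (n == 0) break;
        mx /= n; my /= n; m1 /= n; m2 /= n; m3 /= n;
        double shift = std::sqrt((mx - x) * (mx - x) + (my - y) * (my - y)) +
                       std::sqrt((m1 - v1) * (m1 - v1) + (m2 - v2) * (m2 - v2) +
                                 (m3 - v3) * (m3 - v3));
        x = mx; y = my; v1 = m1; v2 = m2; v3 = m3;
        if (shift < eps) break;
      }
      o1(i, j) = v1; o2(i, j) = v2; o3(i, j) = v3;
    }
  }
  return List::create(_["c1"] = o1, _["c2"] = o2, _["c3"] = o3);
}

// ---------------------------------------------------------------------------
// total-variation denoising (Chambolle's dual projection algorithm)

// [[Rcpp::export]]
NumericMatrix cpp_tv_denoise(NumericMatrix f, double weight, int n_iter) {
  const int H = f.nrow(), W = f.ncol();
  std::vector<double> px(H * W, 0.0), py(H * W, 0.0), div(H * W, 0.0);
  const double tau = 0.25;
  NumericMatrix u(H, W);
  for (int it = 0; it < n_iter; ++it) {
    // u = f - weight * div p ; then gradient of u drives the dual update
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        double d = px[i * W + j] + py[i * W + j];
        if (j > 0) d -= px[i * W + j - 1];
        if (i > 0) d -= py[(i - 1) * W + j];
        div[i * W + j] = d;
        u(i, j) = f(i, j) - weight * d;
      }
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        double gx = (j < W - 1) ? u(i, j + 1) - u(i, j) : 0.0;
        double gy = (i < H - 1) ? u(i + 1, j) - u(i, j) : 0.0;
        double nx = px[i * W + j] - tau / weight * gx;
        double ny = py[i * W + j] - tau / weight * gy;
        double nrm = std::max(1.0, std::sqrt(nx * nx + ny * ny));
        px[i * W + j] = nx / nrm;
        py[i * W + j] = ny / nrm;
      }
  }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double d = px[i * W + j] + py[i * W + j];
      if (j > 0) d -= px[i * W + j - 1];
      if (i > 0) d -= py[(i - 1) * W + j];
      u(i, j) = f(i, j) - weight * d;
    }
  return u;
}

// ---------------------------------------------------------------------------
// binary morphology (disk) and 8-connected component labeling

// [[Rcpp::export]]
LogicalMatrix cpp_morph_disk(LogicalMatrix m, int radius, int dilate) {
  const int H = m.nrow(), W = m.ncol();
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int> > disk;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= radius * radius)
        disk.push_back(std::make_pair(dx, dy));
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      bool hit = dilate ? false : true;
      for (size_t d = 0; d < disk.size(); ++d) {
        int qy = i + disk[d].second, qx = j + disk[d].first;
        bool v = (qx >= 0 && qy >= 0 && qx < W && qy < H) ? (bool)m(qy, qx) : false;
        if (dilate) { if (v) { hit = true; break; } }
        else        { if (!v) { hit = false; break; } }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ii = p.first + dy, jj = p.second + dx;
            if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
            if (m(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  }
  return lab;
}
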