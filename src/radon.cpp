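// Parallel-beam Radon transform, backprojection, and rigid 2D resampling.
// Geometry: detector axis has the same length as the image's first dimension;
// rotation is about the pixel-grid centre ((H-1)/2, (W-1)/2). Projections are
// line sums in pixel units (the forward/inverse pair is self-consistent, so
// reconstructed values come back on the input HU scale).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double bilinear(const arma::mat& img, double x, double y) {
  // x indexes rows, y columns; zero outside the grid
  const int H = img.n_rows, W = img.n_cols;
  if (x < 0 || y < 0 || x > H - 1 || y > W - 1) return 0.0;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, H - 1), y1 = std::min(y0 + 1, W - 1);
  const double fx = x - x0, fy = y - y0;
  return img(x0, y0) * (1 - fx) * (1 - fy) + img(x1, y0) * fx * (1 - fy) +
         img(x0, y1) * (1 - fx) * fy + img(x1, y1) * fx * fy;
}

// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& angles) {
  const int H = img.n_rows, W = img.n_cols;
  const double cx = (H - 1) / 2.0, cy = (W - 1) / 2.0;
  const int nd = H;                       // detector bins
  arma::mat sino(nd, angles.n_elem, arma::fill::zeros);
  for (arma::uword a = 0; a < angles.n_elem; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int t = 0; t < nd; ++t) {
      const double dt = t - cx;
      double acc = 0.0;
      for (int s = 0; s < W; ++s) {
        const double ds = s - cy;
        const double x = cx + dt * ca - ds * sa;
        const double y = cy + dt * sa + ds * ca;
        acc += bilinear(img, x, y);
      }
      sino(t, a) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fsino, const arma::vec& angles,
                          int H, int W) {
  const double cx = (H - 1) / 2.0, cy = (W - 1) / 2.0;
  const int nd = fsino.n_rows;
  arma::mat img(H, W, arma::fill::zeros);
  for (arma::uword a = 0; a < angles.n_elem; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int j = 0; j < W; ++j) {
      const double dy = j - cy;
      for (int i = 0; i < H; ++i) {
        const double dt = (i - cx) * ca + dy * sa + cx;
        if (dt < 0 || dt > nd - 1) continue;
        const int t0 = (int)std::floor(dt);
        const int t1 = std::min(t0 + 1, nd - 1);
        const double ft = dt - t0;
        img(i, j) += fsino(t0, a) * (1 - ft) + fsino(t1, a) * ft;
      }
    }
  }
  img *= M_PI / (2.0 * angles.n_elem);
  return img;
}

// Resample img onto its own grid under a rigid map applied to output
// coordinates: p' = R (p - c) + c + t (pixel units, x = rows).
// Returns the resampled image and a validity mask (1 where the sampling
// point fell inside the source grid).
// [[Rcpp::export]]
List cpp_resample_rigid2d(const arma::mat& img, double ca, double sa,
                          double tx, double ty, double cx, double cy,
                          double fill) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W), valid(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    const double dy = j - cy;
    for (int i = 0; i < H; ++i) {
      const double dx = i - cx;
      const double x = cx + ca * dx - sa * dy + tx;
      const double y = cy + sa * dx + ca * dy + ty;
      if (x < 0 || y < 0 || x > H - 1 || y > W - 1) {
        out(i, j) = fill;
      } else {
        out(i, j) = bilinear(img, x, y);
        valid(i, j) = 1.0;
      }
    }
  }
  return List::create(_["img"] = out, _["valid"] = valid);
}

// Joint intensity histogram over the overlap region under a rigid in-plane
// map, Parzen-smoothed with a linear (tent) kernel on both axes. fixed and
// moving are (H, W, S) stacks sharing one in-plane transform.
// [[Rcpp::export]]
List cpp_joint_hist_rigid(const arma::cube& fixed, const arma::cube& moving,
                          double ca, double sa, double tx, double ty,
                          double cx, double cy, int bins,
                          double fmin, double fmax, double mmin, double mmax) {
  const int H = fixed.n_rows, W = fixed.n_cols, S = fixed.n_slices;
  arma::mat hist(bins, bins, arma::fill::zeros);
  long n_total = (long)H * W * S, n_overlap = 0;
  const double fscale = (bins - 1) / std::max(fmax - fmin, 1e-12);
  const double mscale = (bins - 1) / std::max(mmax - mmin, 1e-12);
  for (int s = 0; s < S; ++s) {
    const arma::mat& F = fixed.slice(s);
    const arma::mat& M = moving.slice(s);
    for (int j = 0; j < W; ++j) {
      const double dy = j - cy;
      for (int i = 0; i < H; ++i) {
        const double dx = i - cx;
        const double x = cx + ca * dx - sa * dy + tx;
        const double y = cy + sa * dx + ca * dy + ty;
        if (x < 0 || y < 0 || x > H - 1 || y > W - 1) continue;
        ++n_overlap;
        const double mv = bilinear(M, x, y);
        double bf = (F(i, j) - fmin) * fscale;
        double bm = (mv - mmin) * mscale;
        bf = std::min(std::max(bf, 0.0), (double)(bins - 1));
        bm = std::min(std::max(bm, 0.0), (double)(bins - 1));
        const int f0 = std::min((int)std::floor(bf), bins - 2);
        const int m0 = std::min((int)std::floor(bm), bins - 2);
        const double wf = bf - f0, wm = bm - m0;
        hist(f0, m0)         += (1 - wf) * (1 - wm);
        hist(f0 + 1, m0)     += wf * (1 - wm);
        hist(f0, m0 + 1)     += (1 - wf) * wm;
        hist(f0 + 1, m0 + 1) += wf * wm;
      }
    }
  }
  return List::create(_["hist"] = hist, _["n_overlap"] = n_overlap,
                      _["n_total"] = n_total);
}
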