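// Fan-beam projector and backprojector on a flat (equispatial) detector.
// Detector coordinates are expressed on the virtual detector line through the
// isocenter, perpendicular to the source direction; the physical panel
// coordinate u maps to s = u * SID / SDD. The source travels on a circle of
// radius SID around the isocenter. Slices are square pixel grids with the
// isocenter at the grid center; pixel (i, j) (1-based in R) has world
// coordinates x = (i - (H+1)/2) * spacing, y = (j - (W+1)/2) * spacing.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double bilin(const arma::mat& img, double fi, double fj) {
  // fi, fj are 0-based fractional pixel indices; outside the grid -> 0
  const int H = img.n_rows, W = img.n_cols;
  if (fi < 0 || fj < 0 || fi > H - 1 || fj > W - 1) return 0.0;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
  if (i0 >= H - 1) i0 = H - 2;
  if (j0 >= W - 1) j0 = W - 2;
  const double a = fi - i0, b = fj - j0;
  return (1 - a) * (1 - b) * img(i0, j0) + a * (1 - b) * img(i0 + 1, j0) +
         (1 - a) * b * img(i0, j0 + 1) + a * b * img(i0 + 1, j0 + 1);
}

// Line integral of attenuation [1/mm * mm] along each (view, bin) ray.
// [[Rcpp::export]]
NumericMatrix cpp_fan_project(NumericMatrix slice, double spacing,
                              NumericVector betas, NumericVector sdet,
                              double sid, double step) {
  const int H = slice.nrow(), W = slice.ncol();
  arma::mat img(slice.begin(), H, W, false);
  const int nv = betas.size(), nb = sdet.size();
  NumericMatrix out(nv, nb);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  // grid bounding circle radius (mm), used to clip the sampled ray segment
  const double rad = 0.5 * spacing * std::sqrt((double)H * H + (double)W * W) + spacing;
  for (int v = 0; v < nv; ++v) {
    const double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    const double sx = sid * cb, sy = sid * sb;     // source
    const double ex = -sb, ey = cb;                // detector direction
    for (int b = 0; b < nb; ++b) {
      const double dx0 = sdet[b] * ex - sx, dy0 = sdet[b] * ey - sy;
      const double len = std::sqrt(dx0 * dx0 + dy0 * dy0);
      const double ux = dx0 / len, uy = dy0 / len;
      // clip [t0, t1] to the sphere |S + t u| <= rad
      const double pb = sx * ux + sy * uy;             // = d/dt |S+tu|^2 / 2
      const double disc = pb * pb - (sid * sid - rad * rad);
      if (disc <= 0) { out(v, b) = 0.0; continue; }
      const double t0 = -pb - std::sqrt(disc), t1 = -pb + std::sqrt(disc);
      double acc = 0.0;
      const int ns = (int)std::ceil((t1 - t0) / step);
      const double dt = (t1 - t0) / ns;
      for (int s = 0; s < ns; ++s) {
        const double t = t0 + (s + 0.5) * dt;
        const double px = sx + t * ux, py = sy + t * uy;
        acc += bilin(img, ci + px / spacing, cj + py / spacing);
      }
      out(v, b) = acc * dt;
    }
  }
  return out;
}

// Backprojection of filtered, weighted projections Q (n_views x n_bins) with
// the fan-beam distance weight 1/U^2, U = (SID - P.a_hat)/SID. Linear
// interpolation along the virtual detector coordinate.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix Q, NumericVector betas,
                                  NumericVector sdet, double sid,
                                  int H, int W, double spacing, double dbeta) {
  const int nv = betas.size(), nb = sdet.size();
  const double s0 = sdet[0], ds = sdet[1] - sdet[0];
  NumericMatrix out(H, W);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    for (int j = 0; j < W; ++j) {
      const double y = (j - cj) * spacing;
      for (int i = 0; i < H; ++i) {
        const double x = (i - ci) * spacing;
        const double pa = x * cb + y * sb;    // P . a_hat
        const double pe = -x * sb + y * cb;   // P . e_hat
        const double U = (sid - pa) / sid;
        if (U <= 0.05) continue;              // behind/near the source
        const double su = sid * pe / (sid - pa);
        const double fb = (su - s0) / ds;
        if (fb < 0 || fb > nb - 1) continue;
        int b0 = (int)std::floor(fb);
        if (b0 >= nb - 1) b0 = nb - 2;
        const double fr = fb - b0;
        const double q = (1 - fr) * Q(v, b0) + fr * Q(v, b0 + 1);
        out(i, j) += dbeta * q / (U * U);
      }
    }
  }
  return out;
}
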