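// Fan-beam projection / reconstruction kernels.
//
// Coordinate convention (used by every routine in the package):
//   * image is n x n, stored column-major as an R matrix [row, col];
//   * pixel (row r, col c), 0-based, has Cartesian coordinates
//       x = c - (n-1)/2,  y = r - (n-1)/2   (unit pixel size);
//   * the rotation centre is the image centre (0, 0);
//   * at view angle phi the source sits at S = D * (cos phi, sin phi);
//   * the virtual flat detector passes through the rotation centre,
//     along u = (-sin phi, cos phi); channel w (0-based) has detector
//     coordinate t_w = (w - (nch-1)/2) * tau.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Chord length of the ray S + t*dir (unit dir) through one ellipse.
static inline double ellipse_chord(double sx, double sy,
                                   double dx, double dy,
                                   double cx, double cy,
                                   double a, double b, double th) {
  const double ct = std::cos(th), st = std::sin(th);
  const double ox = sx - cx, oy = sy - cy;
  const double oxi = ox * ct + oy * st,  oeta = -ox * st + oy * ct;
  const double dxi = dx * ct + dy * st,  deta = -dx * st + dy * ct;
  const double ia2 = 1.0 / (a * a), ib2 = 1.0 / (b * b);
  const double A = dxi * dxi * ia2 + deta * deta * ib2;
  const double B = 2.0 * (oxi * dxi * ia2 + oeta * deta * ib2);
  const double C = oxi * oxi * ia2 + oeta * oeta * ib2 - 1.0;
  const double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return 0.0;
  return std::sqrt(disc) / A;  // |t2 - t1| for unit direction
}

// Closed-form fan-beam sinogram of a set of ellipses.
// ellipses: k x 6 matrix (cx, cy, a, b, theta, mu).
// [[Rcpp::export]]
arma::mat cpp_analytic_fan(const arma::mat& ellipses,
                           const arma::vec& angles,
                           double D, int n_channels, double tau) {
  const int nv = angles.n_elem, nc = n_channels, ne = ellipses.n_rows;
  const double c0 = (nc - 1) / 2.0;
  arma::mat P(nv, nc, arma::fill::zeros);
  for (int k = 0; k < nv; ++k) {
    const double cphi = std::cos(angles[k]), sphi = std::sin(angles[k]);
    const double sx = D * cphi, sy = D * sphi;
    const double ux = -sphi, uy = cphi;
    for (int w = 0; w < nc; ++w) {
      const double t = (w - c0) * tau;
      double dx = t * ux - sx, dy = t * uy - sy;
      const double nrm = std::sqrt(dx * dx + dy * dy);
      dx /= nrm; dy /= nrm;
      double acc = 0.0;
      for (int e = 0; e < ne; ++e)
        acc += ellipses(e, 5) * ellipse_chord(sx, sy, dx, dy,
                                              ellipses(e, 0), ellipses(e, 1),
                                              ellipses(e, 2), ellipses(e, 3),
                                              ellipses(e, 4));
      P(k, w) = acc;
    }
  }
  return P;
}

// Additive raster of ellipses: pixel-centre membership test.
// [[Rcpp::export]]
arma::mat cpp_rasterize(const arma::mat& ellipses, int n) {
  const int ne = ellipses.n_rows;
  const double c0 = (n - 1) / 2.0;
  arma::mat img(n, n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    const double cx = ellipses(e, 0), cy = ellipses(e, 1);
    const double a = ellipses(e, 2), b = ellipses(e, 3);
    const double th = ellipses(e, 4), mu = ellipses(e, 5);
    const double ct = std::cos(th), st = std::sin(th);
    const double rmax = std::max(a, b);
    const int rlo = std::max(0, (int)std::floor(cy - rmax + c0));
    const int rhi = std::min(n - 1, (int)std::ceil(cy + rmax + c0));
    const int clo = std::max(0, (int)std::floor(cx - rmax + c0));
    const int chi = std::min(n - 1, (int)std::ceil(cx + rmax + c0));
    for (int c = clo; c <= chi; ++c) {
      const double x = c - c0 - cx;
      for (int r = rlo; r <= rhi; ++r) {
        const double y = r - c0 - cy;
        const double xi = x * ct + y * st, eta = -x * st + y * ct;
        if (xi * xi / (a * a) + eta * eta / (b * b) <= 1.0)
          img(r, c) += mu;
      }
    }
  }
  return img;
}

static inline double bilinear(const arma::mat& img, int n,
                              double x, double y) {
  // (x, y) in Cartesian pixel units; zero outside the image.
  const double c0 = (n - 1) / 2.0;
  const double cc = x + c0, rr = y + c0;
  const int c = (int)std::floor(cc), r = (int)std::floor(rr);
  if (c < -1 || c > n - 1 || r < -1 || r > n - 1) return 0.0;
  const double fc = cc - c, fr = rr - r;
  double v = 0.0;
  if (r >= 0 && c >= 0)         v += (1 - fr) * (1 - fc) * img(r, c);
  if (r >= 0 && c + 1 <= n - 1) v += (1 - fr) * fc * img(r, c + 1);
  if (r + 1 <= n - 1 && c >= 0) v += fr * (1 - fc) * img(r + 1, c);
  if (r + 1 <= n - 1 && c + 1 <= n - 1) v += fr * fc * img(r + 1, c + 1);
  return v;
}

// Ray-driven raster forward projector (Joseph-style sampling).
// [[Rcpp::export]]
arma::mat cpp_forward_project(const arma::mat& img,
                              const arma::vec& angles,
                              double D, int n_channels, double tau,
                              double step) {
  const int n = img.n_rows, nv = angles.n_elem, nc = n_channels;
  const double c0 = (nc - 1) / 2.0;
  const double Rc = (n / 2.0) * std::sqrt(2.0) + 1.0;  // circumscribed + margin
  arma::mat P(nv, nc, arma::fill::zeros);
  for (int k = 0; k < nv; ++k) {
    const double cphi = std::cos(angles[k]), sphi = std::sin(angles[k]);
    const double sx = D * cphi, sy = D * sphi;
    const double ux = -sphi, uy = cphi;
    for (int w = 0; w < nc; ++w) {
      const double t = (w - c0) * tau;
      double dx = t * ux - sx, dy = t * uy - sy;
      const double nrm = std::sqrt(dx * dx + dy * dy);
      dx /= nrm; dy /= nrm;
      // intersect |S + t d| = Rc
      const double sd = sx * dx + sy * dy;
      const double disc = sd * sd - (D * D - Rc * Rc);
      if (disc <= 0.0) continue;
      const double rt = std::sqrt(disc);
      const double t0 = -sd - rt, t1 = -sd + rt;
      double acc = 0.0;
      for (double tt = t0 + step / 2.0; tt < t1; tt += step)
        acc += bilinear(img, n, sx + tt * dx, sy + tt * dy);
      P(k, w) = acc * step;
    }
  }
  return P;
}

// Exact adjoint of cpp_forward_project: smear sinogram values back
// along the same sample points with transposed bilinear weights.
// [[Rcpp::export]]
arma::mat cpp_backsmear(const arma::mat& P,
                        const arma::vec& angles,
                        double D, double tau, int n, double step) {
  const int nv = angles.n_elem, nc = P.n_cols;
  const double c0 = (nc - 1) / 2.0;
  const double pc0 = (n - 1) / 2.0;
  const double Rc = (n / 2.0) * std::sqrt(2.0) + 1.0;
  arma::mat img(n, n, arma::fill::zeros);
  for (int k = 0; k < nv; ++k) {
    const double cphi = std::cos(angles[k]), sphi = std::sin(angles[k]);
    const double sx = D * cphi, sy = D * sphi;
    const double ux = -sphi, uy = cphi;
    for (int w = 0; w < nc; ++w) {
      const double v = P(k, w) ;
      if (v == 0.0) continue;
      const double t = (w - c0) * tau;
      double dx = t * ux - sx, dy = t * uy - sy;
      const double nrm = std::sqrt(dx * dx + dy * dy);
      dx /= nrm; dy /= nrm;
      const double sd = sx * dx + sy * dy;
      const double disc = sd * sd - (D * D - Rc * Rc);
      if (disc <= 0.0) continue;
      const double rt = std::sqrt(disc);
      const double t0 = -sd - rt, t1 = -sd + rt;
      const double vs = v * step;
      for (double tt = t0 + step / 2.0; tt < t1; tt += step) {
        const double cc = sx + tt * dx + pc0, rr = sy + tt * dy + pc0;
        const int c = (int)std::floor(cc), r = (int)std::floor(rr);
        if (c < -1 || c > n - 1 || r < -1 || r > n - 1) continue;
        const double fc = cc - c, fr = rr - r;
        if (r >= 0 && c >= 0)         img(r, c) += (1 - fr) * (1 - fc) * vs;
        if (r >= 0 && c + 1 <= n - 1) img(r, c + 1) += (1 - fr) * fc * vs;
        if (r + 1 <= n - 1 && c >= 0) img(r + 1, c) += fr * (1 - fc) * vs;
        if (r + 1 <= n - 1 && c + 1 <= n - 1) img(r + 1, c + 1) += fr * fc * vs;
      }
    }
  }
  return img;
}

// Row-wise 'same' convolution with a symmetric tapped kernel.
// Zero rows are skipped (zero-filled incomplete sinograms).
// taps has odd length 2h+1; offsets with zero taps are skipped.
// [[Rcpp::export]]
arma::mat cpp_filter_rows(const arma::mat& P, const arma::vec& taps) {
  const int nv = P.n_rows, nc = P.n_cols;
  const int h = (taps.n_elem - 1) / 2;
  // collect non-zero offsets once (even offsets of the ramp are zero)
  std::vector<int> offs; std::vector<double> tv;
  for (int m = 0; m < (int)taps.n_elem; ++m)
    if (taps[m] != 0.0) { offs.push_back(m - h); tv.push_back(taps[m]); }
  arma::mat Q(nv, nc, arma::fill::zeros);
  for (int k = 0; k < nv; ++k) {
    bool nz = false;
    for (int j = 0; j < nc; ++j) if (P(k, j) != 0.0) { nz = true; break; }
    if (!nz) continue;
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (size_t m = 0; m < offs.size(); ++m) {
        const int src = j - offs[m];
        if (src >= 0 && src < nc) acc += tv[m] * P(k, src);
      }
      Q(k, j) = acc;
    }
  }
  return Q;
}

// Pixel-driven weighted fan-beam back-projection:
//   out(x, y) = sum_k  D^2 / (D - r.e_s)^2 * interp(Q_k, s*(x, y))
// with s* = D (r.u) / (D - r.e_s); linear interpolation between
// channels; rays outside the detector contribute 0; pixels outside the
// inscribed circle are left at 0. Zero rows of Q are skipped.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& Q,
                          const arma::vec& angles,
                          double D, double tau, int out_size) {
  const int nv = angles.n_elem, nc = Q.n_cols, n = out_size;
  const double c0 = (nc - 1) / 2.0;
  const double pc0 = (n - 1) / 2.0;
  const double R2 = (n / 2.0) * (n / 2.0);
  arma::mat img(n, n, arma::fill::zeros);
  for (int k = 0; k < nv; ++k) {
    bool nz = false;
    for (int j = 0; j < nc; ++j) if (Q(k, j) != 0.0) { nz = true; break; }
    if (!nz) continue;
    const double cphi = std::cos(angles[k]), sphi = std::sin(angles[k]);
    for (int c = 0; c < n; ++c) {
      const double x = c - pc0;
      for (int r = 0; r < n; ++r) {
        const double y = r - pc0;
        if (x * x + y * y > R2) continue;
        const double L = D - (x * cphi + y * sphi);
        const double s = D * (-x * sphi + y * cphi) / L;
        const double idx = s / tau + c0;
        const int i0 = (int)std::floor(idx);
        if (i0 < 0 || i0 >= nc - 1) continue;
        const double f = idx - i0;
        const double q = (1 - f) * Q(k, i0) + f * Q(k, i0 + 1);
        img(r, c) += q * (D * D) / (L * L);
      }
    }
  }
  return img;
}
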