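#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Joseph-type ray-driven parallel-beam projector for a single x-z slice.
//
// Image: nx x nz matrix (column-major), pixel (i, k) centred at
//   x = i - (nx - 1)/2,  z = k - (nz - 1)/2   (0-based i, k; unit pixels).
// Detector: sigma = nx bins, bin j at t = j - (nx - 1)/2, rotation about the
// image centre.  Angle theta (degrees): 0 degrees projects along z onto the
// x-axis; positive angles rotate counterclockwise (x right, z up).  The ray
// for bin j is { (x, z) : x cos(theta) + z sin(theta) = t_j }.
//
// For |theta| <= 45 deg rays are driven along z (one linearly interpolated
// sample per image column crossing, weight 1/|cos|); otherwise along x
// (weight 1/|sin|, run on a transposed copy for contiguous access).  The
// adjoint scatters with the identical weights, so it is the exact algebraic
// transpose of the forward map -- required by the conjugate-gradient solver.

static const double DEG = 0.017453292519943295;

// Accumulate one driven line family: for each drive index k (n_drive lines,
// spacing coordinate `perp` of size n_perp), sample detector bins j with
// interpolation coordinate u(j) = base_k + j * du into `img` organised as
// img[perp + k * n_perp].  forward: buf[j] += w * interp; adjoint: scatter.
static inline void drive(const double *img, double *buf, bool forward,
                         int n_perp, int n_drive, int sigma,
                         double c_perp, double c_drive, double ct,
                         double ratio_num, double ratio_den, double w,
                         double *img_out) {
  // u(j, k) = ((j - ct) - (k - c_drive) * ratio_num) / ratio_den + c_perp
  const double du = 1.0 / ratio_den;
  for (int k = 0; k < n_drive; ++k) {
    const double zk = k - c_drive;
    double u = ((0.0 - ct) - zk * ratio_num) / ratio_den + c_perp;
    const double *col = img + (std::size_t)k * n_perp;
    double *col_out = img_out ? img_out + (std::size_t)k * n_perp : 0;
    for (int j = 0; j < sigma; ++j, u += du) {
      const double uf = std::floor(u);
      const int i0 = (int)uf;
      const double w1 = u - uf;
      if (forward) {
        double acc = 0.0;
        if (i0 >= 0 && i0 < n_perp) acc += (1.0 - w1) * col[i0];
        if (i0 + 1 >= 0 && i0 + 1 < n_perp) acc += w1 * col[i0 + 1];
        buf[j] += w * acc;
      } else {
        const double val = w * buf[j];
        if (i0 >= 0 && i0 < n_perp) col_out[i0] += (1.0 - w1) * val;
        if (i0 + 1 >= 0 && i0 + 1 < n_perp) col_out[i0 + 1] += w1 * val;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_forward(NumericMatrix f, NumericVector theta_deg) {
  const int nx = f.nrow(), nz = f.ncol(), sigma = nx, ntheta = theta_deg.size();
  NumericMatrix y(ntheta, sigma);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0, ct = (sigma - 1) / 2.0;
  const double *fp = f.begin();
  // transposed copy for the x-driven (steep-angle) branch
  std::vector<double> ft;
  std::vector<double> buf(sigma);
  for (int a = 0; a < ntheta; ++a) {
    const double th = theta_deg[a] * DEG, c = std::cos(th), s = std::sin(th);
    std::fill(buf.begin(), buf.end(), 0.0);
    if (std::fabs(c) >= std::fabs(s)) {
      drive(fp, buf.data(), true, nx, nz, sigma, cx, cz, ct, s, c,
            1.0 / std::fabs(c), 0);
    } else {
      if (ft.empty()) {
        ft.resize((std::size_t)nx * nz);
        for (int k = 0; k < nz; ++k)
          for (int i = 0; i < nx; ++i)
            ft[(std::size_t)i * nz + k] = fp[(std::size_t)k * nx + i];
      }
      drive(ft.data(), buf.data(), true, nz, nx, sigma, cz, cx, ct, c, s,
            1.0 / std::fabs(s), 0);
    }
    for (int j = 0; j < sigma; ++j) y(a, j) = buf[j];
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_adjoint(NumericMatrix y, int nx, int nz,
                                NumericVector theta_deg) {
  const int sigma = nx, ntheta = theta_deg.size();
  if (y.nrow() != ntheta || y.ncol() != sigma)
    stop("sinogram dimensions do not match angle count / detector size");
  NumericMatrix f(nx, nz);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0, ct = (sigma - 1) / 2.0;
  double *fp = f.begin();
  std::vector<double> ft;          // transposed accumulator, lazily created
  std::vector<double> buf(sigma);
  for (int a = 0; a < ntheta; ++a) {
    const double th = theta_deg[a] * DEG, c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < sigma; ++j) buf[j] = y(a, j);
    if (std::fabs(c) >= std::fabs(s)) {
      drive(0, buf.data(), false, nx, nz, sigma, cx, cz, ct, s, c,
            1.0 / std::fabs(c), fp);
    } else {
      if (ft.empty()) ft.assign((std::size_t)nx * nz, 0.0);
      drive(0, buf.data(), false, nz, nx, sigma, cz, cx, ct, c, s,
            1.0 / std::fabs(s), ft.data());
    }
  }
  if (!ft.empty())
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i)
        fp[(std::size_t)k * nx + i] += ft[(std::size_t)i * nz + k];
  return f;
}

// Pixel-driven linear-interpolation backprojection (classical WBP smearing):
// each pixel reads the filtered projection at t = x cos + z sin.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix y, int nx, int nz,
                              NumericVector theta_deg) {
  const int sigma = nx, ntheta = theta_deg.size();
  if (y.nrow() != ntheta || y.ncol() != sigma)
    stop("sinogram dimensions do not match angle count / detector size");
  NumericMatrix f(nx, nz);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0, ct = (sigma - 1) / 2.0;
  std::vector<double> row(sigma);
  for (int a = 0; a < ntheta; ++a) {
    const double th = theta_deg[a] * DEG, c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < sigma; ++j) row[j] = y(a, j);
    for (int k = 0; k < nz; ++k) {
      const double base = (k - cz) * s + ct;
      double t = -cx * c + base;
      double *col = f.begin() + (std::size_t)k * nx;
      for (int i = 0; i < nx; ++i, t += c) {
        const double tf = std::floor(t);
        const int j0 = (int)tf;
        const double w1 = t - tf;
        double acc = 0.0;
        if (j0 >= 0 && j0 < sigma) acc += (1.0 - w1) * row[j0];
        if (j0 + 1 >= 0 && j0 + 1 < sigma) acc += w1 * row[j0 + 1];
        col[i] += acc;
      }
    }
  }
  return f;
}

// --- Precomputed-weight plan -------------------------------------------------
// For iterative solvers the same projector is applied thousands of times with
// a fixed angle set and grid; the interpolation positions and weights are
// then precomputed once.  Each sample (angle a, drive line k, bin j) stores a
// base index p and tap weights (wa, wb) applying to col[p], col[p+1], with
// taps clamped inside the grid and zero-weighted when a ray exits it, so the
// apply loops are branch-free.  Weights are float32; forward and adjoint use
// the same table and therefore remain exact algebraic transposes.

struct RadonPlan {
  int nx, nz, sigma, ntheta;
  std::vector<unsigned char> steep;  // per angle: 1 = x-driven (transposed)
  std::vector<int> p;
  std::vector<float> wa, wb;
  bool any_steep;
};

static void plan_angle(RadonPlan &pl, int n_perp, int n_drive, int sigma,
                       double c_perp, double c_drive, double ct,
                       double ratio_num, double ratio_den, double w) {
  const double du = 1.0 / ratio_den;
  for (int k = 0; k < n_drive; ++k) {
    const double zk = k - c_drive;
    double u = ((0.0 - ct) - zk * ratio_num) / ratio_den + c_perp;
    for (int j = 0; j < sigma; ++j, u += du) {
      const double uf = std::floor(u);
      const int i0 = (int)uf;
      const double w1 = u - uf;
      int p = 0; double wa = 0.0, wb = 0.0;
      if (i0 >= 0 && i0 + 1 < n_perp) {
        p = i0; wa = w * (1.0 - w1); wb = w * w1;
      } else if (i0 == -1) {
        p = 0; wa = w * w1; wb = 0.0;           // only tap i0+1 = 0 inside
      } else if (i0 == n_perp - 1) {
        p = n_perp - 2; wa = 0.0; wb = w * (1.0 - w1);  // only tap i0 inside
      }
      pl.p.push_back(p);
      pl.wa.push_back((float)wa);
      pl.wb.push_back((float)wb);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_radon_plan(int nx, int nz, NumericVector theta_deg) {
  RadonPlan *pl = new RadonPlan();
  const int sigma = nx, ntheta = theta_deg.size();
  pl->nx = nx; pl->nz = nz; pl->sigma = sigma; pl->ntheta = ntheta;
  pl->any_steep = false;
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0, ct = (sigma - 1) / 2.0;
  pl->p.reserve((std::size_t)ntheta * sigma * std::max(nx, nz));
  for (int a = 0; a < ntheta; ++a) {
    const double th = theta_deg[a] * DEG, c = std::cos(th), s = std::sin(th);
    const bool steep = std::fabs(c) < std::fabs(s);
    pl->steep.push_back(steep);
    if (!steep)
      plan_angle(*pl, nx, nz, sigma, cx, cz, ct, s, c, 1.0 / std::fabs(c));
    else {
      plan_angle(*pl, nz, nx, sigma, cz, cx, ct, c, s, 1.0 / std::fabs(s));
      pl->any_steep = true;
    }
  }
  XPtr<RadonPlan> ptr(pl, true);
  return ptr;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_forward_plan(NumericMatrix f, SEXP plan) {
  XPtr<RadonPlan> pl(plan);
  const int nx = pl->nx, nz = pl->nz, sigma = pl->sigma, ntheta = pl->ntheta;
  if (f.nrow() != nx || f.ncol() != nz) stop("image shape does not match plan");
  NumericMatrix y(ntheta, sigma);
  const double *fp = f.begin();
  std::vector<double> ft;
  if (pl->any_steep) {
    ft.resize((std::size_t)nx * nz);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i)
        ft[(std::size_t)i * nz + k] = fp[(std::size_t)k * nx + i];
  }
  std::vector<double> buf(sigma);
  std::size_t pos = 0;
  for (int a = 0; a < ntheta; ++a) {
    const bool steep = pl->steep[a];
    const int n_perp = steep ? nz : nx, n_drive = steep ? nx : nz;
    const double *img = steep ? ft.data() : fp;
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int k = 0; k < n_drive; ++k) {
      const double *col = img + (std::size_t)k * n_perp;
      const int *pp = pl->p.data() + pos;
      const float *wap = pl->wa.data() + pos;
      const float *wbp = pl->wb.data() + pos;
      for (int j = 0; j < sigma; ++j) {
        const int q = pp[j];
        buf[j] += wap[j] * col[q] + wbp[j] * col[q + 1];
      }
      pos += sigma;
    }
    for (int j = 0; j < sigma; ++j) y(a, j) = buf[j];
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_adjoint_plan(NumericMatrix y, SEXP plan) {
  XPtr<RadonPlan> pl(plan);
  const int nx = pl->nx, nz = pl->nz, sigma = pl->sigma, ntheta = pl->ntheta;
  if (y.nrow() != ntheta || y.ncol() != sigma)
    stop("sinogram shape does not match plan");
  NumericMatrix f(nx, nz);
  double *fp = f.begin();
  std::vector<double> ft;
  if (pl->any_steep) ft.assign((std::size_t)nx * nz, 0.0);
  std::vector<double> buf(sigma);
  std::size_t pos = 0;
  for (int a = 0; a < ntheta; ++a) {
    const bool steep = pl->steep[a];
    const int n_perp = steep ? nz : nx, n_drive = steep ? nx : nz;
    double *img = steep ? ft.data() : fp;
    for (int j = 0; j < sigma; ++j) buf[j] = y(a, j);
    for (int k = 0; k < n_drive; ++k) {
      double *col = img + (std::size_t)k * n_perp;
      const int *pp = pl->p.data() + pos;
      const float *wap = pl->wa.data() + pos;
      const float *wbp = pl->wb.data() + pos;
      // two passes: within each, the target indices are strictly monotone
      // (|du| >= 1), so read-modify-writes never alias and pipeline freely
      for (int j = 0; j < sigma; ++j) col[pp[j]] += wap[j] * buf[j];
      for (int j = 0; j < sigma; ++j) col[pp[j] + 1] += wbp[j] * buf[j];
      pos += sigma;
    }
  }
  if (pl->any_steep)
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i)
        fp[(std::size_t)k * nx + i] += ft[(std::size_t)i * nz + k];
  return f;
}
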