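#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Low-level numerical kernels shared by the resampling, registration and
// fusion code. All voxel coordinates are 0-based; out-of-field samples
// evaluate to 0 (background-dominant images).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector src, IntegerVector dim,
                          NumericVector x, NumericVector y, NumericVector z,
                          int nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = x.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double xi = x[p], yi = y[p], zi = z[p];
    if (!R_finite(xi) || !R_finite(yi) || !R_finite(zi)) { out[p] = 0.0; continue; }
    if (nearest) {
      int i = (int)std::lround(xi), j = (int)std::lround(yi), k = (int)std::lround(zi);
      out[p] = (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
                 ? src[idx3(i, j, k, nx, ny)] : 0.0;
    } else {
      int i0 = (int)std::floor(xi), j0 = (int)std::floor(yi), k0 = (int)std::floor(zi);
      double fx = xi - i0, fy = yi - j0, fz = zi - k0;
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk) {
        int k = k0 + dk; if (k < 0 || k >= nz) continue;
        double wz = dk ? fz : 1.0 - fz; if (wz == 0.0) continue;
        for (int dj = 0; dj < 2; ++dj) {
          int j = j0 + dj; if (j < 0 || j >= ny) continue;
          double wy = dj ? fy : 1.0 - fy; if (wy == 0.0) continue;
          for (int di = 0; di < 2; ++di) {
            int i = i0 + di; if (i < 0 || i >= nx) continue;
            double wx = di ? fx : 1.0 - fx; if (wx == 0.0) continue;
            acc += wx * wy * wz * src[idx3(i, j, k, nx, ny)];
          }
        }
      }
      out[p] = acc;
    }
  }
  return out;
}

// Separable Gaussian convolution, kernel truncated at 3*sigma and
// renormalized at the borders (normalized convolution), sigma in voxels.
static void blur_axis(std::vector<double> &buf, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) return;
  std::vector<double> w(2 * r + 1);
  for (int t = -r; t <= r; ++t) w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
  int nline = nx * ny * nz / len;
  for (int line = 0; line < nline; ++line) {
    // compute base index of this line
    int a, b, base;
    if (axis == 0)      { a = line % ny; b = line / ny; base = idx3(0, a, b, nx, ny); }
    else if (axis == 1) { a = line % nx; b = line / nx; base = idx3(a, 0, b, nx, ny); }
    else                { a = line % nx; b = line / nx; base = idx3(a, b, 0, nx, ny); }
    for (int i = 0; i < len; ++i) {
      double acc = 0.0, ws = 0.0;
      int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
      for (int t = lo; t <= hi; ++t) {
        double wt = w[t - i + r];
        acc += wt * buf[base + t * stride];
        ws += wt;
      }
      tmp[base + i * stride] = acc / ws;
    }
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector src, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(src.begin(), src.end()), tmp(buf.size());
  blur_axis(buf, tmp, nx, ny, nz, 0, sigma);
  blur_axis(buf, tmp, nx, ny, nz, 1, sigma);
  blur_axis(buf, tmp, nx, ny, nz, 2, sigma);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}

static inline void bspline_w(double f, double w[4]) {
  double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}

// Cubic B-spline displacement field evaluation, as three separable 4-tap
// passes per component. coef: (ncx, ncy, ncz, 3); control point with
// 0-based array index a sits at voxel coordinate (a - 1) * spacing, so the
// lattice pads the grid by one control point on each side.

static void bspline_axis_weights(int nvox, double spacing,
                                 std::vector<int> &idx, std::vector<double> &w) {
  idx.resize(nvox); w.resize(4 * nvox);
  for (int v = 0; v < nvox; ++v) {
    double t = v / spacing;
    int i = (int)std::floor(t);
    idx[v] = i;
    bspline_w(t - i, &w[4 * v]);
  }
}

// expand along the fastest axis: in (nin, nline) -> out (nout, nline)
static void expand_x(const double *in, double *out, int nin, int nout,
                     int nline, const std::vector<int> &idx,
                     const std::vector<double> &w) {
  for (int l = 0; l < nline; ++l) {
    const double *ip = in + (R_xlen_t)l * nin;
    double *op = out + (R_xlen_t)l * nout;
    for (int v = 0; v < nout; ++v) {
      double acc = 0.0;
      const double *wv = &w[4 * v];
      for (int t = 0; t < 4; ++t) {
        int c = idx[v] + t;
        if (c >= 0 && c < nin) acc += wv[t] * ip[c];
      }
      op[v] = acc;
    }
  }
}

// move axis `ax` (1 = middle, 2 = last) of a (n0, n1, n2) array to front
static void rotate_to_front(const std::vector<double> &in, std::vector<double> &out,
                            int n0, int n1, int n2, int ax) {
  if (ax == 1) {        // (n0,n1,n2) -> (n1,n0,n2)
    for (int k = 0; k < n2; ++k)
      for (int j = 0; j < n1; ++j)
        for (int i = 0; i < n0; ++i)
          out[j + (R_xlen_t)n1 * (i + (R_xlen_t)n0 * k)] =
            in[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
  } else {              // (n0,n1,n2) -> (n2,n0,n1)
    for (int k = 0; k < n2; ++k)
      for (int j = 0; j < n1; ++j)
        for (int i = 0; i < n0; ++i)
          out[k + (R_xlen_t)n2 * (i + (R_xlen_t)n0 * j)] =
            in[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
  }
}

// one component: (ncx,ncy,ncz) control grid -> (nx,ny,nz) dense field
static void bspline_eval_comp(const double *cf, double *out,
                              int ncx, int ncy, int ncz,
                              int nx, int ny, int nz,
                              const std::vector<int> &ix, const std::vector<double> &wx,
                              const std::vector<int> &iy, const std::vector<double> &wy,
                              const std::vector<int> &iz, const std::vector<double> &wz) {
  std::vector<double> a((R_xlen_t)nx * ncy * ncz);
  expand_x(cf, a.data(), ncx, nx, ncy * ncz, ix, wx);          // (nx,ncy,ncz)
  std::vector<double> b((R_xlen_t)ncy * nx * ncz);
  rotate_to_front(a, b, nx, ncy, ncz, 1);                      // (ncy,nx,ncz)
  std::vector<double> c((R_xlen_t)ny * nx * ncz);
  expand_x(b.data(), c.data(), ncy, ny, nx * ncz, iy, wy);     // (ny,nx,ncz)
  std::vector<double> d((R_xlen_t)ncz * ny * nx);
  rotate_to_front(c, d, ny, nx, ncz, 2);                       // (ncz,ny,nx)
  std::vector<double> e((R_xlen_t)nz * ny * nx);
  expand_x(d.data(), e.data(), ncz, nz, ny * nx, iz, wz);      // (nz,ny,nx)
  // transpose (nz,ny,nx) -> (nx,ny,nz)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] =
          e[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
}

// [[Rcpp::export]]
NumericVector bspline_eval_cpp(NumericVector coef, IntegerVector cdim,
                               IntegerVector dim, double spacing) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz, nctrl = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(nvox * 3);
  std::vector<int> ix, iy, iz;
  std::vector<double> wx, wy, wz;
  bspline_axis_weights(nx, spacing, ix, wx);
  bspline_axis_weights(ny, spacing, iy, wy);
  bspline_axis_weights(nz, spacing, iz, wz);
  for (int c = 0; c < 3; ++c)
    bspline_eval_comp(&coef[0] + c * nctrl, &out[0] + c * nvox,
                      ncx, ncy, ncz, nx, ny, nz, ix, wx, iy, wy, iz, wz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// adjoint of expand_x: out (nin, nline) accumulates from in (nout, nline)
static void reduce_x(const double *in, double *out, int nin, int nout,
                     int nline, const std::vector<int> &idx,
                     const std::vector<double> &w) {
  for (int l = 0; l < nline; ++l) {
    const double *ip = in + (R_xlen_t)l * nout;
    double *op = out + (R_xlen_t)l * nin;
    for (int v = 0; v < nout; ++v) {
      double g = ip[v];
      if (g == 0.0) continue;
      const double *wv = &w[4 * v];
      for (int t = 0; t < 4; ++t) {
        int c = idx[v] + t;
        if (c >= 0 && c < nin) op[c] += wv[t] * g;
      }
    }
  }
}

// Adjoint of bspline_eval_cpp: scatter a dense per-voxel gradient field back
// to the control lattice (exact transpose of the separable passes).
// [[Rcpp::export]]
NumericVector bspline_adjoint_cpp(NumericVector grad, IntegerVector dim,
                                  IntegerVector cdim, double spacing) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz, nctrl = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(nctrl * 3);
  std::vector<int> ix, iy, iz;
  std::vector<double> wx, wy, wz;
  bspline_axis_weights(nx, spacing, ix, wx);
  bspline_axis_weights(ny, spacing, iy, wy);
  bspline_axis_weights(nz, spacing, iz, wz);
  for (int c = 0; c < 3; ++c) {
    const double *gp = &grad[0] + c * nvox;
    // transpose (nx,ny,nz) -> (nz,ny,nx)
    std::vector<double> e((R_xlen_t)nz * ny * nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          e[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)] =
            gp[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
    std::vector<double> d((R_xlen_t)ncz * ny * nx, 0.0);
    reduce_x(e.data(), d.data(), ncz, nz, ny * nx, iz, wz);    // (ncz,ny,nx)
    // (ncz,ny,nx) -> (ny,nx,ncz): move axis 0 to the back
    std::vector<double> tmp((R_xlen_t)ny * nx * ncz);
    for (int k = 0; k < nx; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < ncz; ++i)
          tmp[j + (R_xlen_t)ny * (k + (R_xlen_t)nx * i)] =
            d[i + (R_xlen_t)ncz * (j + (R_xlen_t)ny * k)];
    std::vector<double> b((R_xlen_t)ncy * nx * ncz, 0.0);
    reduce_x(tmp.data(), b.data(), ncy, ny, nx * ncz, iy, wy); // (ncy,nx,ncz)
    std::vector<double> a((R_xlen_t)nx * ncy * ncz);
    for (int k = 0; k < ncz; ++k)
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ncy; ++i)
          a[j + (R_xlen_t)nx * (i + (R_xlen_t)ncy * k)] =
            b[i + (R_xlen_t)ncy * (j + (R_xlen_t)nx * k)];
    std::vector<double> cfinal((R_xlen_t)ncx * ncy * ncz, 0.0);
    reduce_x(a.data(), cfinal.data(), ncx, nx, ncy * ncz, ix, wx);
    double *op = &out[0] + c * nctrl;
    std::copy(cfinal.begin(), cfinal.end(), op);
  }
  out.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
  return out;
}

// Even-odd point-in-polygon for a set of query points against a set of
// polygons on one slice. Polygons are concatenated vertex lists (closed or
// open; closure is implied). A point lying on an edge counts as inside.
// [[Rcpp::export]]
LogicalVector pip_cpp(NumericVector px, NumericVector py,
                      NumericVector vx, NumericVector vy, IntegerVector lens) {
  const int np = px.size(), npoly = lens.size();
  LogicalVector out(np);
  const double eps = 1e-9;
  for (int p = 0; p < np; ++p) {
    double x = px[p], y = py[p];
    int cross = 0; bool onedge = false;
    int off = 0;
    for (int g = 0; g < npoly && !onedge; ++g) {
      int m = lens[g];
      for (int a = 0; a < m; ++a) {
        int b = (a + 1) % m;
        double x1 = vx[off + a], y1 = vy[off + a];
        double x2 = vx[off + b], y2 = vy[off + b];
        if (x1 == x2 && y1 == y2) continue;
        // on-segment test
        double dx = x2 - x1, dy = y2 - y1;
        double t = ((x - x1) * dx + (y - y1) * dy) / (dx * dx + dy * dy);
        if (t >= -eps && t <= 1 + eps) {
          double qx = x1 + t * dx, qy = y1 + t * dy;
          if (std::fabs(qx - x) < eps && std::fabs(qy - y) < eps) { onedge = true; break; }
        }
        // ray casting along +x
        if ((y1 > y) != (y2 > y)) {
          double xint = x1 + (y - y1) * dx / dy;
          if (xint > x) ++cross;
        }
      }
      off += m;
    }
    out[p] = onedge || (cross % 2 == 1);
  }
  return out;
}

// 6-connected component labelling of a binary mask (BFS).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> queue;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    queue.clear(); queue.push_back(s);
    while (!queue.empty()) {
      int v = queue.back(); queue.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; queue.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Per-voxel top-k selection over a (nvox x ntmpl) similarity matrix.
// Returns a logical matrix of the same shape with exactly k TRUE per row;
// ties broken by ascending template (column) index.
// [[Rcpp::export]]
LogicalMatrix topk_rows_cpp(NumericMatrix sim, int k) {
  const int n = sim.nrow(), m = sim.ncol();
  LogicalMatrix out(n, m);
  std::vector<int> ord(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) ord[j] = j;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return sim(i, a) > sim(i, b);
    });
    for (int j = 0; j < k; ++j) out(i, ord[j]) = true;
  }
  return out;
}
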