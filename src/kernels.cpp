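#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parallel-beam line-integral projection of a 3D volume about its vertical
// (z) axis. Volume is an R array [x, y, z], column-major. The detector
// coordinate u lies along e_u = (cos t, sin t); integration runs along
// e_t = (-sin t, cos t) in ny unit steps, so the returned values are path
// integrals in voxel units (multiply by the pitch for physical lengths).
// Rotation uses bilinear interpolation in the (x, y) plane; samples outside
// the grid contribute zero.
// [[Rcpp::export]]
NumericMatrix cpp_project_volume(NumericVector vol, int nx, int ny, int nz,
                                 double theta) {
  NumericMatrix out(nx, nz);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const int nut = nx * ny;
  // precompute sampling stencils for one (u, t) plane
  std::vector<int> idx(nut, -1);
  std::vector<double> w00(nut), w10(nut), w01(nut), w11(nut);
  for (int t = 0; t < ny; ++t) {
    const double dt = t - cy;
    for (int u = 0; u < nx; ++u) {
      const double du = u - cx;
      const double px = cx + du * ct - dt * st;
      const double py = cy + du * st + dt * ct;
      const int k = u + nx * t;
      if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1) continue;
      int i0 = (int)std::floor(px), j0 = (int)std::floor(py);
      if (i0 >= nx - 1) i0 = nx - 2;
      if (j0 >= ny - 1) j0 = ny - 2;
      const double fx = px - i0, fy = py - j0;
      idx[k] = i0 + nx * j0;
      w00[k] = (1 - fx) * (1 - fy);
      w10[k] = fx * (1 - fy);
      w01[k] = (1 - fx) * fy;
      w11[k] = fx * fy;
    }
  }
  const double *v = REAL(vol);
  for (int z = 0; z < nz; ++z) {
    const double *slice = v + (size_t)z * nx * ny;
    double *col = &out(0, z);
    for (int t = 0; t < ny; ++t) {
      const int base = nx * t;
      for (int u = 0; u < nx; ++u) {
        const int k = u + base;
        const int id = idx[k];
        if (id < 0) continue;
        col[u] += w00[k] * slice[id] + w10[k] * slice[id + 1] +
                  w01[k] * slice[id + nx] + w11[k] * slice[id + nx + 1];
      }
    }
  }
  return out;
}

// Same as cpp_project_volume but integrates two volumes sharing one
// sampling stencil (e.g. the delta and beta volumes of a phantom).
// [[Rcpp::export]]
List cpp_project_volume2(NumericVector volA, NumericVector volB, int nx,
                         int ny, int nz, double theta) {
  NumericMatrix outA(nx, nz), outB(nx, nz);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const int nut = nx * ny;
  std::vector<int> idx(nut, -1);
  std::vector<double> w00(nut), w10(nut), w01(nut), w11(nut);
  for (int t = 0; t < ny; ++t) {
    const double dt = t - cy;
    for (int u = 0; u < nx; ++u) {
      const double du = u - cx;
      const double px = cx + du * ct - dt * st;
      const double py = cy + du * st + dt * ct;
      const int k = u + nx * t;
      if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1) continue;
      int i0 = (int)std::floor(px), j0 = (int)std::floor(py);
      if (i0 >= nx - 1) i0 = nx - 2;
      if (j0 >= ny - 1) j0 = ny - 2;
      const double fx = px - i0, fy = py - j0;
      idx[k] = i0 + nx * j0;
      w00[k] = (1 - fx) * (1 - fy);
      w10[k] = fx * (1 - fy);
      w01[k] = (1 - fx) * fy;
      w11[k] = fx * fy;
    }
  }
  const double *va = REAL(volA), *vb = REAL(volB);
  for (int z = 0; z < nz; ++z) {
    const double *sa = va + (size_t)z * nx * ny;
    const double *sb = vb + (size_t)z * nx * ny;
    double *ca = &outA(0, z);
    double *cb = &outB(0, z);
    for (int t = 0; t < ny; ++t) {
      const int base = nx * t;
      for (int u = 0; u < nx; ++u) {
        const int k = u + base;
        const int id = idx[k];
        if (id < 0) continue;
        ca[u] += w00[k] * sa[id] + w10[k] * sa[id + 1] +
                 w01[k] * sa[id + nx] + w11[k] * sa[id + nx + 1];
        cb[u] += w00[k] * sb[id] + w10[k] * sb[id + 1] +
                 w01[k] * sb[id + nx] + w11[k] * sb[id + nx + 1];
      }
    }
  }
  return List::create(_["a"] = outA, _["b"] = outB);
}

// Backprojection of one filtered sinogram slice (nu x nangles) onto an
// nx x nx grid. center is the 0-based rotation-axis column in the sinogram;
// the reconstruction grid is centred at (nx-1)/2. Linear interpolation
// along u; the caller applies the pi/n_angles quadrature factor.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector cosv,
                              NumericVector sinv, double center, int nx) {
  const int nu = sino.nrow(), na = sino.ncol();
  NumericMatrix out(nx, nx);
  const double c = 0.5 * (nx - 1);
  for (int a = 0; a < na; ++a) {
    const double ct = cosv[a], st = sinv[a];
    const double *s = &sino(0, a);
    for (int y = 0; y < nx; ++y) {
      const double uy = center + (y - c) * st;
      double *col = &out(0, y);
      for (int x = 0; x < nx; ++x) {
        const double u = uy + (x - c) * ct;
        if (u < 0 || u > nu - 1) continue;
        int i0 = (int)u;
        if (i0 >= nu - 1) i0 = nu - 2;
        const double f = u - i0;
        col[x] += (1 - f) * s[i0] + f * s[i0 + 1];
      }
    }
  }
  return out;
}

// Seeded 3D region growing: flood fill from seed (0-based x,y,z) including
// voxels with lo <= value <= hi under 6- or 26-connectivity.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, int nx, int ny, int nz,
                              int sx, int sy, int sz, double lo, double hi,
                              int connectivity) {
  const double *v = REAL(vol);
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector mask(n, false);
  int *m = LOGICAL(mask);
  std::vector<int> offx, offy, offz;
  if (connectivity == 6) {
    int ox[] = {1, -1, 0, 0, 0, 0}, oy[] = {0, 0, 1, -1, 0, 0},
        oz[] = {0, 0, 0, 0, 1, -1};
    offx.assign(ox, ox + 6); offy.assign(oy, oy + 6); offz.assign(oz, oz + 6);
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
        }
  }
  const size_t s0 = (size_t)sx + (size_t)nx * sy + (size_t)nx * ny * sz;
  if (v[s0] < lo || v[s0] > hi) return mask;
  std::vector<size_t> stack;
  stack.push_back(s0);
  m[s0] = 1;
  const int nb = (int)offx.size();
  while (!stack.empty()) {
    const size_t p = stack.back();
    stack.pop_back();
    const int z = (int)(p / ((size_t)nx * ny));
    const int r = (int)(p % ((size_t)nx * ny));
    const int y = r / nx, x = r % nx;
    for (int k = 0; k < nb; ++k) {
      const int qx = x + offx[k], qy = y + offy[k], qz = z + offz[k];
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      const size_t q = (size_t)qx + (size_t)nx * qy + (size_t)nx * ny * qz;
      if (m[q]) continue;
      if (v[q] >= lo && v[q] <= hi) {
        m[q] = 1;
        stack.push_back(q);
      }
    }
  }
  return mask;
}
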