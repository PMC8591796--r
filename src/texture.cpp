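// Texture-matrix accumulation and grid resampling kernels.
// Volumes are passed as flat vectors in R column-major order with
// dims = (nx, ny, nz): linear index = x + nx*(y + ny*z), 0-based here.
// Level arrays use 0 for out-of-mask voxels and 1..Ng inside the mask.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// The 13 unique 3D direction offsets at Chebyshev distance 1 (half of the
// 26-neighbourhood; the other half is covered by symmetrization).
static const int N_DIR = 13;
static const int DIRS[N_DIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0},
  {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".cppGlcmCounts")]]
IntegerVector cppGlcmCounts(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(ng * ng * N_DIR);
  for (int d = 0; d < N_DIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    const int base = d * ng * ng;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          // symmetrized: record both (i,j) and (j,i)
          out[base + (li - 1) + ng * (lj - 1)] += 1;
          out[base + (lj - 1) + ng * (li - 1)] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, N_DIR);
  return out;
}

// [[Rcpp::export(name = ".cppGlrlmCounts")]]
IntegerVector cppGlrlmCounts(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int lmax = nx > ny ? nx : ny;
  if (nz > lmax) lmax = nz;
  IntegerVector out(ng * lmax * N_DIR);
  for (int d = 0; d < N_DIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    const int base = d * ng * lmax;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // line starts: predecessor along -d is out of bounds
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            continue;
          int cx = x, cy = y, cz = z;
          int runLevel = 0, runLen = 0;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            const int l = levels[idx3(cx, cy, cz, nx, ny)];
            if (l == runLevel && l != 0) {
              ++runLen;
            } else {
              if (runLevel != 0)
                out[base + (runLevel - 1) + ng * (runLen - 1)] += 1;
              runLevel = l;
              runLen = (l != 0) ? 1 : 0;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (runLevel != 0)
            out[base + (runLevel - 1) + ng * (runLen - 1)] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, N_DIR);
  return out;
}

// Zones: 26-connected components of constant level within the mask.
// Returns a two-column matrix (level, size), one row per zone.
// [[Rcpp::export(name = ".cppGlszmZones")]]
IntegerMatrix cppGlszmZones(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize, stack;
  stack.reserve(256);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i0 = idx3(x, y, z, nx, ny);
        const int l = levels[i0];
        if (l == 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          ++size;
          const int cz = i / (nx * ny);
          const int cy = (i - cz * nx * ny) / nx;
          const int cx = i - nx * (cy + ny * cz);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                    z2 < 0 || z2 >= nz)
                  continue;
                const int j = idx3(x2, y2, z2, nx, ny);
                if (!seen[j] && levels[j] == l) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zlev.push_back(l);
        zsize.push_back(size);
      }
  IntegerMatrix out(zlev.size(), 2);
  for (size_t k = 0; k < zlev.size(); ++k) {
    out(k, 0) = zlev[k];
    out(k, 1) = zsize[k];
  }
  return out;
}

// NGTDM accumulators: per level i, n_i (voxels with >= 1 in-mask neighbour)
// and s_i = sum over those voxels of |i - mean(26-neighbourhood levels)|.
// [[Rcpp::export(name = ".cppNgtdm")]]
NumericMatrix cppNgtdm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2); // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = levels[idx3(x, y, z, nx, ny)];
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz)
                continue;
              const int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj == 0) continue;
              sum += lj;
              ++cnt;
            }
        if (cnt == 0) continue; // isolated voxel: excluded
        out(l - 1, 0) += 1.0;
        out(l - 1, 1) += std::fabs((double)l - sum / cnt);
      }
  return out;
}

// GLDM: dependence d(v) = # in-mask 26-neighbours with |level diff| <= alpha.
// Counts matrix is ng x 27 with columns d = 0..26.
// [[Rcpp::export(name = ".cppGldmCounts")]]
IntegerMatrix cppGldmCounts(IntegerVector levels, IntegerVector dims, int ng,
                            int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = levels[idx3(x, y, z, nx, ny)];
        if (l == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz)
                continue;
              const int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj == 0) continue;
              if (std::abs(lj - l) <= alpha) ++dep;
            }
        out(l - 1, dep) += 1;
      }
  return out;
}

// Trilinear (dose) and nearest-neighbour (mask) resampling onto a grid with
// the same origin and new spacing; source index clamped to the volume.
// [[Rcpp::export(name = ".cppResample")]]
NumericVector cppResample(NumericVector values, IntegerVector dims,
                          NumericVector spacing, IntegerVector newDims,
                          NumericVector newSpacing, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = newDims[0], my = newDims[1], mz = newDims[2];
  NumericVector out(mx * (double)my * mz);
  std::vector<double> fx(mx), fy(my), fz(mz);
  for (int i = 0; i < mx; ++i) {
    double v = i * newSpacing[0] / spacing[0];
    fx[i] = v < 0 ? 0 : (v > nx - 1 ? nx - 1 : v);
  }
  for (int i = 0; i < my; ++i) {
    double v = i * newSpacing[1] / spacing[1];
    fy[i] = v < 0 ? 0 : (v > ny - 1 ? ny - 1 : v);
  }
  for (int i = 0; i < mz; ++i) {
    double v = i * newSpacing[2] / spacing[2];
    fz[i] = v < 0 ? 0 : (v > nz - 1 ? nz - 1 : v);
  }
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        const double gx = fx[x], gy = fy[y], gz = fz[z];
        double val;
        if (nearest) {
          const int ix = (int)std::lround(gx);
          const int iy = (int)std::lround(gy);
          const int iz = (int)std::lround(gz);
          val = values[idx3(ix, iy, iz, nx, ny)];
        } else {
          int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
              z0 = (int)std::floor(gz);
          if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
          if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
          if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
          const int x1 = nx > 1 ? x0 + 1 : x0;
          const int y1 = ny > 1 ? y0 + 1 : y0;
          const int z1 = nz > 1 ? z0 + 1 : z0;
          const double tx = gx - x0, ty = gy - y0, tz = gz - z0;
          const double c000 = values[idx3(x0, y0, z0, nx, ny)];
          const double c100 = values[idx3(x1, y0, z0, nx, ny)];
          const double c010 = values[idx3(x0, y1, z0, nx, ny)];
          const double c110 = values[idx3(x1, y1, z0, nx, ny)];
          const double c001 = values[idx3(x0, y0, z1, nx, ny)];
          const double c101 = values[idx3(x1, y0, z1, nx, ny)];
          const double c011 = values[idx3(x0, y1, z1, nx, ny)];
          const double c111 = values[idx3(x1, y1, z1, nx, ny)];
          const double c00 = c000 * (1 - tx) + c100 * tx;
          const double c10 = c010 * (1 - tx) + c110 * tx;
          const double c01 = c001 * (1 - tx) + c101 * tx;
          const double c11 = c011 * (1 - tx) + c111 * tx;
          const double c0 = c00 * (1 - ty) + c10 * ty;
          const double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        out[idx3(x, y, z, mx, my)] = val;
      }
  out.attr("dim") = newDims;
  return out;
}
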