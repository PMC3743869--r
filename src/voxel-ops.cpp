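#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// separable per axis with a physical sampling pitch per axis, so anisotropic
// voxels are handled exactly. Distances are to the nearest *background*
// voxel center, in the same units as `spacing`.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double s2, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      // intersection of parabola q with parabola v[k]; s2 is pitch^2
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector occ, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // a large *finite* seed: true infinity breaks the lower-envelope
  // intersection arithmetic (s = -Inf can pop the stack past index 0)
  const double BIG = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = occ[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, s2, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, s2, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + nxny * k];
      dt1d(f, d, nz, s2, v, z);
      for (int k = 0; k < nz; ++k) out[base + nxny * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand): a foreground voxel is simple iff
//   (a) the foreground part of its 26-neighbourhood has exactly one
//       26-connected component, and
//   (b) the background part of its 18-neighbourhood has exactly one
//       6-connected component that is 6-adjacent to the voxel.
// Deleting a simple point preserves the topology of the object (26-connected
// foreground / 6-connected background).
// ---------------------------------------------------------------------------

static inline int cubeIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool isSimple(const bool nb[27]) {
  // (a) 26-components of foreground in N26*
  {
    bool seen[27] = {false};
    int ncomp = 0;
    for (int s = 0; s < 27; ++s) {
      if (s == 13 || !nb[s] || seen[s]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      // BFS
      int stack[27], top = 0;
      stack[top++] = s;
      seen[s] = true;
      while (top > 0) {
        int c = stack[--top];
        int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x = cx + dx, y = cy + dy, z = cz + dz;
              if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1)
                continue;
              int t = cubeIndex(x, y, z);
              if (t == 13 || !nb[t] || seen[t]) continue;
              seen[t] = true;
              stack[top++] = t;
            }
      }
    }
    if (ncomp != 1) return false;
  }
  // (b) 6-components of background within N18, 6-adjacent to center
  {
    bool seen[27] = {false};
    int ncomp = 0;
    const int d6x[6] = {1, -1, 0, 0, 0, 0};
    const int d6y[6] = {0, 0, 1, -1, 0, 0};
    const int d6z[6] = {0, 0, 0, 0, 1, -1};
    for (int s0 = 0; s0 < 6; ++s0) {
      int s = cubeIndex(d6x[s0], d6y[s0], d6z[s0]);
      if (nb[s] || seen[s]) continue; // want background seeds
      ++ncomp;
      if (ncomp > 1) return false;
      int stack[27], top = 0;
      stack[top++] = s;
      seen[s] = true;
      while (top > 0) {
        int c = stack[--top];
        int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
        for (int m = 0; m < 6; ++m) {
          int x = cx + d6x[m], y = cy + d6y[m], z = cz + d6z[m];
          if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
          if (std::abs(x) + std::abs(y) + std::abs(z) > 2) continue; // N18 only
          int t = cubeIndex(x, y, z);
          if (t == 13 || nb[t] || seen[t]) continue;
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

// Directional (6-subcycle) homotopic thinning: repeatedly sweep the six
// border directions, deleting simple non-endpoint voxels whose face in the
// sweep direction was open at the start of the sweep. Borders erode
// symmetrically, so a band that is two voxels wide from lattice parity is
// reduced to a one-voxel curve with at most a couple of voxels lost at the
// ends (endpoint preservation then locks the curve).
// [[Rcpp::export]]
LogicalVector thin3d_directional_cpp(LogicalVector occ, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = occ[i] ? 1 : 0;

  auto inb = [&](int x, int y, int z) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };
  auto at = [&](int x, int y, int z) -> R_xlen_t {
    return x + (R_xlen_t)nx * y + nxny * z;
  };
  auto fillNb = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          nb[cubeIndex(dx, dy, dz)] =
              inb(xx, yy, zz) ? (fg[at(xx, yy, zz)] != 0) : false;
        }
  };
  const int dirs[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  bool nb[27];
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d6 = 0; d6 < 6; ++d6) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t i = at(x, y, z);
            if (!fg[i]) continue;
            int xx = x + dirs[d6][0], yy = y + dirs[d6][1],
                zz = z + dirs[d6][2];
            bool open = !inb(xx, yy, zz) || !fg[at(xx, yy, zz)];
            if (open) cand.push_back(i);
          }
      for (R_xlen_t i : cand) {
        if (!fg[i]) continue;
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxny);
        // only erode where the object is >= 2 voxels thick along the sweep
        // axis: a one-voxel-thick wall is all border and would otherwise be
        // consumed lengthwise within a single sweep
        int ox = x - dirs[d6][0], oy = y - dirs[d6][1], oz = z - dirs[d6][2];
        if (!inb(ox, oy, oz) || !fg[at(ox, oy, oz)]) continue;
        fillNb(x, y, z, nb);
        int nn = 0;
        for (int s = 0; s < 27; ++s)
          if (s != 13 && nb[s]) ++nn;
        if (nn <= 1) continue;
        if (!isSimple(nb)) continue;
        fg[i] = 0;
        changed = true;
      }
    }
    // rim erosion: diagonal one-voxel-thick ribbons are immune to the six
    // axis sweeps (no axis along which they are two voxels thick), so peel
    // their rims -- voxels with few foreground neighbours at phase start --
    // one layer per iteration. Candidacy is frozen at phase start, so the
    // peel cannot cascade into the ribbon interior; a residual curve is
    // safe because its interior voxels are non-simple and its endpoints
    // are protected.
    cand.clear();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = at(x, y, z);
          if (!fg[i]) continue;
          fillNb(x, y, z, nb);
          int nn = 0;
          for (int s = 0; s < 27; ++s)
            if (s != 13 && nb[s]) ++nn;
          if (nn >= 2 && nn <= 4) cand.push_back(i);
        }
    for (R_xlen_t i : cand) {
      if (!fg[i]) continue;
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxny);
      fillNb(x, y, z, nb);
      int nn = 0;
      for (int s = 0; s < 27; ++s)
        if (s != 13 && nb[s]) ++nn;
      if (nn <= 1) continue;
      if (!isSimple(nb)) continue;
      fg[i] = 0;
      changed = true;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}

// Label the largest 26-connected foreground component.
// [[Rcpp::export]]
LogicalVector largest_component_cpp(LogicalVector occ, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  std::vector<int> label(n, 0);
  int nlab = 0;
  R_xlen_t bestSize = 0;
  int bestLab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || label[s]) continue;
    ++nlab;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = nlab;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      ++size;
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / nxny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            R_xlen_t j = xx + (R_xlen_t)nx * yy + nxny * zz;
            if (occ[j] && !label[j]) {
              label[j] = nlab;
              stack.push_back(j);
            }
          }
    }
    if (size > bestSize) {
      bestSize = size;
      bestLab = nlab;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = label[i] == bestLab;
  return out;
}
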