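#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// Column-major 3D indexing helper (x fastest, as in R arrays).
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// The 13 unique positive directions of 3D 26-connectivity: every offset
// (dx,dy,dz) in {-1,0,1}^3 \ {0} whose first non-zero component is positive.
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline double dir_len(const int* d) {
  return std::sqrt((double)(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]));
}

// ---------------------------------------------------------------------------
// Interpolation (trilinear / tricubic Keys a = -0.5), clamped borders.
// ux/uy/uz are 0-based fractional voxel indices of the output sample points.
// ---------------------------------------------------------------------------

static inline double keys(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector arr, IntegerVector dims,
                          NumericVector ux, NumericVector uy, NumericVector uz,
                          int method) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = ux.size(), my = uy.size(), mz = uz.size();
  NumericVector out(mx * (double)my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);

  const int half = (method == 1) ? 2 : 1;  // support radius in voxels
  std::vector<double> wx(2 * half), wy(2 * half), wz(2 * half);

  for (int kz = 0; kz < mz; ++kz) {
    const double z = uz[kz];
    const int z0 = (int)std::floor(z);
    for (int j = 0; j < 2 * half; ++j)
      wz[j] = (method == 1) ? keys(z - (z0 - half + 1 + j))
                            : ((j == 0) ? 1.0 - (z - z0) : (z - z0));
    for (int ky = 0; ky < my; ++ky) {
      const double y = uy[ky];
      const int y0 = (int)std::floor(y);
      for (int j = 0; j < 2 * half; ++j)
        wy[j] = (method == 1) ? keys(y - (y0 - half + 1 + j))
                              : ((j == 0) ? 1.0 - (y - y0) : (y - y0));
      for (int kx = 0; kx < mx; ++kx) {
        const double x = ux[kx];
        const int x0 = (int)std::floor(x);
        for (int j = 0; j < 2 * half; ++j)
          wx[j] = (method == 1) ? keys(x - (x0 - half + 1 + j))
                                : ((j == 0) ? 1.0 - (x - x0) : (x - x0));
        double acc = 0.0;
        for (int c = 0; c < 2 * half; ++c) {
          if (wz[c] == 0.0) continue;
          const int zc = clampi(z0 - half + 1 + c, 0, nz - 1);
          for (int b = 0; b < 2 * half; ++b) {
            if (wy[b] == 0.0) continue;
            const int yc = clampi(y0 - half + 1 + b, 0, ny - 1);
            const double wzy = wz[c] * wy[b];
            for (int a = 0; a < 2 * half; ++a) {
              if (wx[a] == 0.0) continue;
              const int xc = clampi(x0 - half + 1 + a, 0, nx - 1);
              acc += wzy * wx[a] * arr[idx3(xc, yc, zc, nx, ny)];
            }
          }
        }
        out[idx3(kx, ky, kz, mx, my)] = acc;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Texture matrices. `levels` holds 0 outside the ROI and 1..ngray inside.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int ngray,
                       double w_face, double w_edge, double w_corner) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix m(ngray, ngray);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int g1 = levels[idx3(x, y, z, nx, ny)];
        if (g1 == 0) continue;
        for (int d = 0; d < 13; ++d) {
          const int x2 = x + DIR13[d][0], y2 = y + DIR13[d][1], z2 = z + DIR13[d][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          const int g2 = levels[idx3(x2, y2, z2, nx, ny)];
          if (g2 == 0) continue;
          const int step = std::abs(DIR13[d][0]) + std::abs(DIR13[d][1]) + std::abs(DIR13[d][2]);
          const double w = (step == 1) ? w_face : (step == 2 ? w_edge : w_corner);
          m(g1 - 1, g2 - 1) += w;
          m(g2 - 1, g1 - 1) += w;
        }
      }
  return m;  // unnormalized symmetric weighted counts
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int ngray,
                        bool step_length) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxdim = std::max(nx, std::max(ny, nz));
  const int maxcol = (int)std::lround(1.0 + (maxdim - 1) * std::sqrt(3.0)) + 1;
  NumericMatrix m(ngray, maxcol);

  for (int d = 0; d < 13; ++d) {
    const int ox = DIR13[d][0], oy = DIR13[d][1], oz = DIR13[d][2];
    const double step = step_length ? dir_len(DIR13[d]) : 1.0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // only voxels starting a grid line in this direction
          const int xp = x - ox, yp = y - oy, zp = z - oz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            continue;
          int cx = x, cy = y, cz = z;
          int cur = 0, count = 0;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            const int g = levels[idx3(cx, cy, cz, nx, ny)];
            if (g == cur && g != 0) {
              ++count;
            } else {
              if (cur != 0) {
                const int col = (int)std::lround(1.0 + (count - 1) * step);
                m(cur - 1, std::min(col, maxcol) - 1) += 1.0;
              }
              cur = g;
              count = (g != 0) ? 1 : 0;
            }
            cx += ox; cy += oy; cz += oz;
          }
          if (cur != 0) {
            const int col = (int)std::lround(1.0 + (count - 1) * step);
            m(cur - 1, std::min(col, maxcol) - 1) += 1.0;
          }
        }
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ngray) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  std::vector<int> stack;
  int maxsize = 1;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i0 = idx3(x, y, z, nx, ny);
        const int g = levels[i0];
        if (g == 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          ++size;
          const int vx = i % nx, vy = (i / nx) % ny, vz = i / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int x2 = vx + dx, y2 = vy + dy, z2 = vz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                  continue;
                const int i2 = idx3(x2, y2, z2, nx, ny);
                if (!seen[i2] && levels[i2] == g) {
                  seen[i2] = 1;
                  stack.push_back(i2);
                }
              }
        }
        zones.push_back(std::make_pair(g, size));
        if (size > maxsize) maxsize = size;
      }

  NumericMatrix m(ngray, maxsize);
  for (size_t k = 0; k < zones.size(); ++k)
    m(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return m;
}

// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ngray,
               double w_face, double w_edge, double w_corner) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector s(ngray), nvox(ngray);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int g = levels[idx3(x, y, z, nx, ny)];
        if (g == 0) continue;
        double wsum = 0.0, acc = 0.0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              const int g2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (g2 == 0) continue;
              const int step = std::abs(dx) + std::abs(dy) + std::abs(dz);
              const double w = (step == 1) ? w_face : (step == 2 ? w_edge : w_corner);
              wsum += w;
              acc += w * g2;
            }
        if (wsum <= 0.0) continue;  // isolated voxel: contributes nothing
        s[g - 1] += std::fabs((double)g - acc / wsum);
        nvox[g - 1] += 1.0;
      }
  return List::create(_["s"] = s, _["n"] = nvox);
}

// ---------------------------------------------------------------------------
// Convex hull (incremental) for solidity; max pairwise distance for size.
// ---------------------------------------------------------------------------

struct Face { int a, b, c; double nx, ny, nz, off; bool alive; };

static void face_plane(Face& f, const std::vector<std::array<double, 3> >& P) {
  const std::array<double, 3>&A = P[f.a], &B = P[f.b], &C = P[f.c];
  const double ux = B[0] - A[0], uy = B[1] - A[1], uz = B[2] - A[2];
  const double vx = C[0] - A[0], vy = C[1] - A[1], vz = C[2] - A[2];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * A[0] + f.ny * A[1] + f.nz * A[2];
}

static inline double face_dist(const Face& f, const std::array<double, 3>& p) {
  return f.nx * p[0] + f.ny * p[1] + f.nz * p[2] - f.off;
}

// Builds the hull of `pts`; returns faces as plane list. Empty if rank < 3.
static std::vector<Face> build_hull(const std::vector<std::array<double, 3> >& P,
                                    double eps) {
  std::vector<Face> faces;
  const int n = (int)P.size();
  if (n < 4) return faces;

  // initial simplex: extremes
  int i1 = 0;
  for (int i = 1; i < n; ++i)
    if (P[i][0] < P[i1][0]) i1 = i;
  int i2 = (i1 == 0) ? 1 : 0;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double d = std::pow(P[i][0] - P[i1][0], 2) + std::pow(P[i][1] - P[i1][1], 2) +
                     std::pow(P[i][2] - P[i1][2], 2);
    if (i != i1 && d > best) { best = d; i2 = i; }
  }
  if (best <= eps * eps) return faces;
  // farthest from line i1-i2
  int i3 = -1; best = eps;
  const double lx = P[i2][0] - P[i1][0], ly = P[i2][1] - P[i1][1], lz = P[i2][2] - P[i1][2];
  const double ll = std::sqrt(lx * lx + ly * ly + lz * lz);
  for (int i = 0; i < n; ++i) {
    const double ax = P[i][0] - P[i1][0], ay = P[i][1] - P[i1][1], az = P[i][2] - P[i1][2];
    const double cx = ay * lz - az * ly, cy = az * lx - ax * lz, cz = ax * ly - ay * lx;
    const double d = std::sqrt(cx * cx + cy * cy + cz * cz) / ll;
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return faces;
  // farthest from plane i1-i2-i3
  Face f0; f0.a = i1; f0.b = i2; f0.c = i3; f0.alive = true;
  face_plane(f0, P);
  const double nn = std::sqrt(f0.nx * f0.nx + f0.ny * f0.ny + f0.nz * f0.nz);
  int i4 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    const double d = std::fabs(face_dist(f0, P[i])) / nn;
    if (d > best) { best = d; i4 = i; }
  }
  if (i4 < 0) return faces;  // coplanar point set

  // orient initial tetrahedron faces outward
  const int T[4][3] = {{i1, i2, i3}, {i1, i2, i4}, {i1, i3, i4}, {i2, i3, i4}};
  const int opp[4] = {i4, i3, i2, i1};
  for (int k = 0; k < 4; ++k) {
    Face f; f.a = T[k][0]; f.b = T[k][1]; f.c = T[k][2]; f.alive = true;
    face_plane(f, P);
    if (face_dist(f, P[opp[k]]) > 0) { std::swap(f.b, f.c); face_plane(f, P); }
    faces.push_back(f);
  }

  for (int i = 0; i < n; ++i) {
    if (i == i1 || i == i2 || i == i3 || i == i4) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t k = 0; k < faces.size(); ++k) {
      if (!faces[k].alive) continue;
      const double nn2 = std::sqrt(faces[k].nx * faces[k].nx + faces[k].ny * faces[k].ny +
                                   faces[k].nz * faces[k].nz);
      if (face_dist(faces[k], P[i]) > eps * nn2) vis.push_back((int)k);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (size_t v = 0; v < vis.size(); ++v) {
      const Face& f = faces[vis[v]];
      const int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) edges.push_back(std::make_pair(e[j][0], e[j][1]));
    }
    for (size_t v = 0; v < vis.size(); ++v) faces[vis[v]].alive = false;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool horizon = true;
      for (size_t e2 = 0; e2 < edges.size(); ++e2)
        if (edges[e2].first == edges[e].second && edges[e2].second == edges[e].first) {
          horizon = false;
          break;
        }
      if (!horizon) continue;
      Face f; f.a = edges[e].first; f.b = edges[e].second; f.c = i; f.alive = true;
      face_plane(f, P);
      faces.push_back(f);
    }
  }
  std::vector<Face> out;
  for (size_t k = 0; k < faces.size(); ++k)
    if (faces[k].alive) out.push_back(faces[k]);
  return out;
}

static std::vector<std::array<double, 3> > as_points(NumericMatrix pts) {
  std::vector<std::array<double, 3> > P(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    P[i][0] = pts(i, 0); P[i][1] = pts(i, 1); P[i][2] = pts(i, 2);
  }
  return P;
}

// Counts query points inside (or on, within tol) the convex hull of `pts`.
// Returns -1 when the point set is degenerate (rank < 3).
// [[Rcpp::export]]
int cpp_hull_count_inside(NumericMatrix pts, NumericMatrix query, double tol) {
  std::vector<std::array<double, 3> > P = as_points(pts);
  std::vector<Face> faces = build_hull(P, 1e-9);
  if (faces.empty()) return -1;
  int cnt = 0;
  for (int i = 0; i < query.nrow(); ++i) {
    std::array<double, 3> q = {{query(i, 0), query(i, 1), query(i, 2)}};
    bool inside = true;
    for (size_t k = 0; k < faces.size(); ++k) {
      const double nn = std::sqrt(faces[k].nx * faces[k].nx + faces[k].ny * faces[k].ny +
                                  faces[k].nz * faces[k].nz);
      if (face_dist(faces[k], q) > tol * nn) { inside = false; break; }
    }
    if (inside) ++cnt;
  }
  return cnt;
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  double best = 0.0;
  for (int i = 0; i < pts.nrow(); ++i)
    for (int j = i + 1; j < pts.nrow(); ++j) {
      const double d = std::pow(pts(i, 0) - pts(j, 0), 2) +
                       std::pow(pts(i, 1) - pts(j, 1), 2) +
                       std::pow(pts(i, 2) - pts(j, 2), 2);
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
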