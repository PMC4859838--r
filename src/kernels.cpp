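// Low-level numerical kernels: trilinear slab resampling, Perona-Malik
// diffusion, separable Gaussian blur, connected components, chamfer
// distance transform, banded median inpainting and 2D warping.
//
// Array layout follows R: a[i,j,k] with i (x) fastest, 0-based here.
// Physical coordinates are voxel-center based: x_phys = i * spacing.

#include <Rcpp.h>
#include <limits>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample at voxel-unit coordinates (x,y,z); coordinates within
// half a voxel of the border replicate the edge; beyond that -> outside.
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double outside) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return outside;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = iclamp(x0 + 1, 0, nx - 1), y1 = iclamp(y0 + 1, 0, ny - 1),
      z1 = iclamp(z0 + 1, 0, nz - 1);
  x0 = iclamp(x0, 0, nx - 1); y0 = iclamp(y0, 0, ny - 1); z0 = iclamp(z0, 0, nz - 1);
  const size_t sxy = (size_t)nx * ny;
  const double* p00 = v + (size_t)z0 * sxy;
  const double* p01 = v + (size_t)z1 * sxy;
  double c000 = p00[x0 + (size_t)nx * y0], c100 = p00[x1 + (size_t)nx * y0];
  double c010 = p00[x0 + (size_t)nx * y1], c110 = p00[x1 + (size_t)nx * y1];
  double c001 = p01[x0 + (size_t)nx * y0], c101 = p01[x1 + (size_t)nx * y0];
  double c011 = p01[x0 + (size_t)nx * y1], c111 = p01[x1 + (size_t)nx * y1];
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

static inline double nn_sample(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, double outside) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return outside;
  int xi = iclamp((int)std::lround(x), 0, nx - 1);
  int yi = iclamp((int)std::lround(y), 0, ny - 1);
  int zi = iclamp((int)std::lround(z), 0, nz - 1);
  return v[xi + (size_t)nx * yi + (size_t)nx * ny * zi];
}

// Resample an oblique slab from a volume.  Output pixel (i,j) has section
// coordinates u = (i - (nu-1)/2)*su, v = (j - (nv-1)/2)*sv (micrometres,
// section centre at the origin).  For plane offset w the physical sample
// point is origin + R %*% (u, v, w), converted to voxel units by spacing.
// interp: 0 = trilinear, 1 = nearest.  If reduce_mean, the planes are
// averaged; otherwise an nu x nv x nplanes array is returned.
// [[Rcpp::export]]
SEXP slab_resample_cpp(NumericVector vol, IntegerVector dim,
                       NumericVector spacing, NumericMatrix rot,
                       NumericVector origin, int nu, int nv,
                       double su, double sv, NumericVector woff,
                       int interp, double outside, int reduce_mode) {
  // reduce_mode: 0 = mean over planes, 1 = stack, 2 = max over planes
  const bool reduce = reduce_mode != 1;
  const bool take_max = reduce_mode == 2;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  const int np = woff.size();
  const double r00 = rot(0,0), r01 = rot(0,1), r02 = rot(0,2);
  const double r10 = rot(1,0), r11 = rot(1,1), r12 = rot(1,2);
  const double r20 = rot(2,0), r21 = rot(2,1), r22 = rot(2,2);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double isx = 1.0 / spacing[0], isy = 1.0 / spacing[1], isz = 1.0 / spacing[2];
  const double uc = (nu - 1) / 2.0, vc = (nv - 1) / 2.0;

  NumericVector out(reduce ? (R_xlen_t)nu * nv : (R_xlen_t)nu * nv * np);
  double* o = REAL(out);
  if (reduce) std::fill(o, o + (size_t)nu * nv,
                        take_max ? -std::numeric_limits<double>::infinity() : 0.0);

  for (int p = 0; p < np; ++p) {
    const double w = woff[p];
    // base point for this plane at (u,v) = (0,0)
    const double bx = ox + r02 * w, by = oy + r12 * w, bz = oz + r22 * w;
    double* op = reduce ? o : o + (size_t)p * nu * nv;
    for (int j = 0; j < nv; ++j) {
      const double vv = (j - vc) * sv;
      double px = bx + r01 * vv, py = by + r11 * vv, pz = bz + r21 * vv;
      // start of row at i = 0
      double x = px + r00 * (0 - uc) * su;
      double y = py + r10 * (0 - uc) * su;
      double z = pz + r20 * (0 - uc) * su;
      const double dx = r00 * su, dy = r10 * su, dz = r20 * su;
      double* orow = op + (size_t)j * nu;
      if (interp == 0) {
        for (int i = 0; i < nu; ++i, x += dx, y += dy, z += dz) {
          double s = tri_sample(v, nx, ny, nz, x * isx, y * isy, z * isz, outside);
          if (!reduce) orow[i] = s;
          else if (take_max) { if (s > orow[i]) orow[i] = s; }
          else orow[i] += s;
        }
      } else {
        for (int i = 0; i < nu; ++i, x += dx, y += dy, z += dz) {
          double s = nn_sample(v, nx, ny, nz, x * isx, y * isy, z * isz, outside);
          if (!reduce) orow[i] = s;
          else if (take_max) { if (s > orow[i]) orow[i] = s; }
          else orow[i] += s;
        }
      }
    }
  }
  if (reduce) {
    if (!take_max) {
      const double inv = 1.0 / np;
      for (size_t k = 0; k < (size_t)nu * nv; ++k) o[k] *= inv;
    }
    out.attr("dim") = IntegerVector::create(nu, nv);
  } else {
    out.attr("dim") = IntegerVector::create(nu, nv, np);
  }
  return out;
}

// Perona-Malik diffusion, explicit conservative scheme.  Per-voxel
// conductance g = exp(-(|grad I|/kappa)^2) from central differences;
// face conductance is the mean of the two adjacent voxel conductances,
// no flux across the boundary (Neumann), so the intensity sum is conserved.
// [[Rcpp::export]]
NumericVector pm_diffusion_cpp(NumericVector vol, IntegerVector dim,
                               int iterations, double kappa, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  NumericVector cur = clone(vol);
  std::vector<float> g(n);      // conductance precision is uncritical
  std::vector<double> nxt(n);
  const double ik2 = 1.0 / (kappa * kappa);
  for (int it = 0; it < iterations; ++it) {
    double* c = REAL(cur);
    // conductance from central-difference gradient magnitude
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        size_t base = (size_t)j * nx + (size_t)k * sxy;
        for (int i = 0; i < nx; ++i) {
          size_t id = base + i;
          double gx = (c[base + iclamp(i + 1, 0, nx - 1)] -
                       c[base + iclamp(i - 1, 0, nx - 1)]) * 0.5;
          double gy = (c[id + (size_t)(iclamp(j + 1, 0, ny - 1) - j) * nx] -
                       c[id + (size_t)(iclamp(j - 1, 0, ny - 1) - j) * nx]) * 0.5;
          double gz = (c[id + (size_t)(iclamp(k + 1, 0, nz - 1) - k) * sxy] -
                       c[id + (size_t)(iclamp(k - 1, 0, nz - 1) - k) * sxy]) * 0.5;
          g[id] = std::exp(-(float)((gx * gx + gy * gy + gz * gz) * ik2));
        }
      }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        size_t base = (size_t)j * nx + (size_t)k * sxy;
        for (int i = 0; i < nx; ++i) {
          size_t id = base + i;
          double acc = 0.0, cp = c[id], gp = g[id];
          if (i > 0)      acc += 0.5 * (gp + g[id - 1])   * (c[id - 1]   - cp);
          if (i < nx - 1) acc += 0.5 * (gp + g[id + 1])   * (c[id + 1]   - cp);
          if (j > 0)      acc += 0.5 * (gp + g[id - nx])  * (c[id - nx]  - cp);
          if (j < ny - 1) acc += 0.5 * (gp + g[id + nx])  * (c[id + nx]  - cp);
          if (k > 0)      acc += 0.5 * (gp + g[id - sxy]) * (c[id - sxy] - cp);
          if (k < nz - 1) acc += 0.5 * (gp + g[id + sxy]) * (c[id + sxy] - cp);
          nxt[id] = cp + step * acc;
        }
      }
    std::copy(nxt.begin(), nxt.end(), REAL(cur));
  }
  cur.attr("dim") = dim;
  return cur;
}

// Separable Gaussian blur with edge replication; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector vol, IntegerVector dim,
                             NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  NumericVector out = clone(vol);
  std::vector<double> tmp(n);
  const int nd[3] = { nx, ny, nz };
  const size_t stride[3] = { 1, (size_t)nx, sxy };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || nd[ax] == 1) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += kern[t + rad];
    }
    for (auto& kv : kern) kv /= tot;
    double* src = REAL(out);
    const int len = nd[ax];
    const size_t st = stride[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx3[3] = { i, j, k };
          if (idx3[ax] != 0) continue;  // only start of each line
          size_t base = (size_t)i + (size_t)j * nx + (size_t)k * sxy;
          for (int t = 0; t < len; ++t) {
            double acc = 0;
            for (int q = -rad; q <= rad; ++q) {
              int tq = iclamp(t + q, 0, len - 1);
              acc += kern[q + rad] * src[base + (size_t)tq * st];
            }
            tmp[base + (size_t)t * st] = acc;
          }
        }
    std::copy(tmp.begin(), tmp.end(), REAL(out));
  }
  out.attr("dim") = dim;
  return out;
}

// Connected components of a binary mask, face connectivity (6 in 3D,
// 4 in 2D when nz == 1).  Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  IntegerVector lab(n);
  const int* m = INTEGER(mask);
  int* L = INTEGER(lab);
  std::fill(L, L + n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || L[s]) continue;
    ++next;
    L[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t id = stack.back(); stack.pop_back();
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / sxy);
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        size_t nid = (size_t)ii + (size_t)jj * nx + (size_t)kk * sxy;
        if (m[nid] && !L[nid]) { L[nid] = next; stack.push_back(nid); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Two-pass 26-neighbour chamfer distance (micrometres) to a mask.
// Exact for face/edge/corner neighbours, approximate further out.
// [[Rcpp::export]]
NumericVector chamfer_distance_cpp(IntegerVector mask, IntegerVector dim,
                                   NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  const double INF = 1e30;
  NumericVector dist(n);
  double* d = REAL(dist);
  const int* m = INTEGER(mask);
  for (size_t s = 0; s < n; ++s) d[s] = m[s] ? 0.0 : INF;
  // neighbour offsets with negative lexicographic order (forward pass)
  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 0; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
        offs.push_back({di, dj, dk});
      }
  std::vector<double> w(offs.size());
  for (size_t q = 0; q < offs.size(); ++q) {
    double a = offs[q][0] * spacing[0], b = offs[q][1] * spacing[1],
           c = offs[q][2] * spacing[2];
    w[q] = std::sqrt(a * a + b * b + c * c);
  }
  // forward
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)j * nx + (size_t)k * sxy;
        double dv = d[id];
        if (dv == 0) continue;
        for (size_t q = 0; q < offs.size(); ++q) {
          int ii = i + offs[q][0], jj = j + offs[q][1], kk = k + offs[q][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          double cand = d[(size_t)ii + (size_t)jj * nx + (size_t)kk * sxy] + w[q];
          if (cand < dv) dv = cand;
        }
        d[id] = dv;
      }
  // backward
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        size_t id = (size_t)i + (size_t)j * nx + (size_t)k * sxy;
        double dv = d[id];
        if (dv == 0) continue;
        for (size_t q = 0; q < offs.size(); ++q) {
          int ii = i - offs[q][0], jj = j - offs[q][1], kk = k - offs[q][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          double cand = d[(size_t)ii + (size_t)jj * nx + (size_t)kk * sxy] + w[q];
          if (cand < dv) dv = cand;
        }
        d[id] = dv;
      }
  dist.attr("dim") = dim;
  return dist;
}

// One sweep of banded median replacement: every voxel flagged in `band`
// takes the median of `allowed` voxels within a cube window of radius w.
// Voxels with no allowed neighbour in the window keep their value.
// [[Rcpp::export]]
NumericVector median_band_cpp(NumericVector vol, IntegerVector dim,
                              IntegerVector band, IntegerVector allowed,
                              int w) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sxy = (size_t)nx * ny;
  NumericVector out = clone(vol);
  const double* v = REAL(vol);
  double* o = REAL(out);
  const int* b = INTEGER(band);
  const int* a = INTEGER(allowed);
  std::vector<double> vals;
  vals.reserve((2 * w + 1) * (2 * w + 1) * (2 * w + 1));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)j * nx + (size_t)k * sxy;
        if (!b[id]) continue;
        vals.clear();
        for (int kk = std::max(0, k - w); kk <= std::min(nz - 1, k + w); ++kk)
          for (int jj = std::max(0, j - w); jj <= std::min(ny - 1, j + w); ++jj)
            for (int ii = std::max(0, i - w); ii <= std::min(nx - 1, i + w); ++ii) {
              size_t nid = (size_t)ii + (size_t)jj * nx + (size_t)kk * sxy;
              if (a[nid]) vals.push_back(v[nid]);
            }
        if (vals.empty()) continue;
        size_t mid = vals.size() / 2;
        std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
        double med = vals[mid];
        if (vals.size() % 2 == 0) {
          double lo = *std::max_element(vals.begin(), vals.begin() + mid);
          med = 0.5 * (med + lo);
        }
        o[id] = med;
      }
  out.attr("dim") = dim;
  return out;
}

// 2D warp: out[i,j] = img sampled at (mapx[i,j], mapy[i,j]) (0-based pixel
// units).  interp: 0 = bilinear, 1 = nearest.
// [[Rcpp::export]]
NumericMatrix warp2d_cpp(NumericMatrix img, NumericMatrix mapx,
                         NumericMatrix mapy, int interp, double outside) {
  const int nx = img.nrow(), ny = img.ncol();
  const int ou = mapx.nrow(), ov = mapx.ncol();
  NumericMatrix out(ou, ov);
  const double* v = REAL(img);
  for (int j = 0; j < ov; ++j)
    for (int i = 0; i < ou; ++i) {
      double x = mapx(i, j), y = mapy(i, j);
      out(i, j) = (interp == 0)
        ? tri_sample(v, nx, ny, 1, x, y, 0.0, outside)
        : nn_sample(v, nx, ny, 1, x, y, 0.0, outside);
    }
  return out;
}

// One 6-neighbour (face) binary dilation step.
// [[Rcpp::export]]
IntegerVector dilate6_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sxy = (size_t)nx * ny;
  IntegerVector out = clone(mask);
  const int* m = INTEGER(mask);
  int* o = INTEGER(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)j * nx + (size_t)k * sxy;
      for (int i = 0; i < nx; ++i) {
        size_t id = base + i;
        if (m[id]) continue;
        if ((i > 0 && m[id - 1]) || (i < nx - 1 && m[id + 1]) ||
            (j > 0 && m[id - nx]) || (j < ny - 1 && m[id + nx]) ||
            (k > 0 && m[id - sxy]) || (k < nz - 1 && m[id + sxy]))
          o[id] = 1;
      }
    }
  out.attr("dim") = dim;
  return out;
}

// Correlation coefficient between a fixed section image and single-plane
// resamples of `vol` at a fixed rotation over many plane offsets along
// the volume z axis (translation (0,0,off)).  Returns one C per offset;
// NA where the resampled plane is constant.
// [[Rcpp::export]]
NumericVector offset_scan_cpp(NumericVector vol, IntegerVector dim,
                              NumericVector spacing, NumericMatrix rot,
                              NumericVector center, NumericVector offsets_um,
                              NumericMatrix section, double su) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  const int nu = section.nrow(), nv = section.ncol();
  const size_t npx = (size_t)nu * nv;
  // section statistics
  double smean = 0;
  for (size_t t = 0; t < npx; ++t) smean += section[t];
  smean /= npx;
  std::vector<double> sdev(npx);
  double sss = 0;
  for (size_t t = 0; t < npx; ++t) {
    sdev[t] = section[t] - smean;
    sss += sdev[t] * sdev[t];
  }
  const double r00 = rot(0,0), r01 = rot(0,1);
  const double r10 = rot(1,0), r11 = rot(1,1);
  const double r20 = rot(2,0), r21 = rot(2,1);
  const double isx = 1.0 / spacing[0], isy = 1.0 / spacing[1],
               isz = 1.0 / spacing[2];
  const double uc = (nu - 1) / 2.0, vc = (nv - 1) / 2.0;
  NumericVector out(offsets_um.size());
  std::vector<double> slab(npx);
  for (int q = 0; q < offsets_um.size(); ++q) {
    const double ox = center[0], oy = center[1], oz = center[2] + offsets_um[q];
    size_t t = 0;
    double msum = 0;
    for (int j = 0; j < nv; ++j) {
      const double vv = (j - vc) * su;
      double x = ox + r01 * vv + r00 * (0 - uc) * su;
      double y = oy + r11 * vv + r10 * (0 - uc) * su;
      double z = oz + r21 * vv + r20 * (0 - uc) * su;
      const double dx = r00 * su, dy = r10 * su, dz = r20 * su;
      for (int i = 0; i < nu; ++i, x += dx, y += dy, z += dz, ++t) {
        double s = tri_sample(v, nx, ny, nz, x * isx, y * isy, z * isz, 0.0);
        slab[t] = s;
        msum += s;
      }
    }
    msum /= npx;
    double num = 0, den = 0;
    for (t = 0; t < npx; ++t) {
      double d2 = slab[t] - msum;
      num += sdev[t] * d2;
      den += d2 * d2;
    }
    out[q] = (den <= 0 || sss <= 0) ? NA_REAL : num / std::sqrt(sss * den);
  }
  return out;
}

// Scaffold-surface and bone-contact counts in one pass: a surface element
// is a titanium voxel inside the ROI with a face neighbour that is
// non-titanium and inside the ROI; it is covered when a face neighbour
// carries the bone label.  Returns (surface, covered).
// [[Rcpp::export]]
NumericVector contact_counts_cpp(IntegerVector labels, IntegerVector roi,
                                 IntegerVector dim, int ti, int bone) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sxy = (size_t)nx * ny;
  const int* L = INTEGER(labels);
  const int* Rm = INTEGER(roi);
  double nsurf = 0, ncov = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)j * nx + (size_t)k * sxy;
      for (int i = 0; i < nx; ++i) {
        size_t id = base + i;
        if (L[id] != ti || !Rm[id]) continue;
        bool surface = false, covered = false;
        const long nb[6] = { i > 0 ? (long)id - 1 : -1,
                             i < nx - 1 ? (long)id + 1 : -1,
                             j > 0 ? (long)(id - nx) : -1,
                             j < ny - 1 ? (long)(id + nx) : -1,
                             k > 0 ? (long)(id - sxy) : -1,
                             k < nz - 1 ? (long)(id + sxy) : -1 };
        for (int q = 0; q < 6; ++q) {
          if (nb[q] < 0) continue;   // volume boundary: no surface element
          int lv = L[nb[q]];
          if (lv != ti && Rm[nb[q]]) surface = true;
          if (lv == bone) covered = true;
        }
        if (surface) { nsurf += 1; if (covered) ncov += 1; }
      }
    }
  return NumericVector::create(nsurf, ncov);
}

// Sum of random plane-wave cosines evaluated at voxel coordinates:
// sum_m cos(2*pi/lam[m] * (dir[0,m]*ix + dir[1,m]*iy + dir[2,m]*iz) + ph[m])
// scaled by 1/sqrt(n_waves/2) so the field has approximately unit SD.
// [[Rcpp::export]]
NumericVector plane_waves_cpp(NumericVector ix, NumericVector iy,
                              NumericVector iz, NumericMatrix dir,
                              NumericVector lam, NumericVector phase) {
  const R_xlen_t n = ix.size();
  const int m = lam.size();
  NumericVector out(n);
  for (int w = 0; w < m; ++w) {
    const double kx = 2 * M_PI / lam[w] * dir(0, w);
    const double ky = 2 * M_PI / lam[w] * dir(1, w);
    const double kz = 2 * M_PI / lam[w] * dir(2, w);
    const double ph = phase[w];
    for (R_xlen_t t = 0; t < n; ++t)
      out[t] += std::cos(kx * ix[t] + ky * iy[t] + kz * iz[t] + ph);
  }
  const double sc = 1.0 / std::sqrt(m / 2.0);
  for (R_xlen_t t = 0; t < n; ++t) out[t] *= sc;
  return out;
}

// 1-based linear indices where roi != 0 and labels != excluded.
// [[Rcpp::export]]
IntegerVector masked_which_cpp(IntegerVector roi, IntegerVector labels,
                               int excluded) {
  const R_xlen_t n = roi.size();
  const int* r = INTEGER(roi);
  const int* L = INTEGER(labels);
  R_xlen_t cnt = 0;
  for (R_xlen_t t = 0; t < n; ++t) if (r[t] && L[t] != excluded) ++cnt;
  IntegerVector out(cnt);
  R_xlen_t q = 0;
  for (R_xlen_t t = 0; t < n; ++t)
    if (r[t] && L[t] != excluded) out[q++] = (int)(t + 1);
  return out;
}
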