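#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D connected-component labeling by breadth-first flood fill.
// mask is a logical vector in R array (column-major) order, dims = (nx, ny, nz).
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int noff = (int)dxs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int current = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    queue.clear();
    queue.push_back(start);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t idx = queue[head++];
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int k = 0; k < noff; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = current;
          queue.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Paint spheres into a voxel grid: voxels whose centre lies inside any sphere
// receive `intensity`, all others `background`. Coordinates and radii in the
// same physical units as `voxel` (dx, dy, dz). Voxel centre of index i (0-based)
// along x is (i + 0.5) * dx.
// [[Rcpp::export]]
NumericVector cpp_render_spheres(IntegerVector dims, NumericVector voxel,
                                 NumericVector cx, NumericVector cy, NumericVector cz,
                                 NumericVector r, double intensity, double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector vol(n, background);
  const int ns = (int)cx.size();
  for (int s = 0; s < ns; ++s) {
    const double rs = r[s];
    if (!(rs > 0)) continue;
    const double r2 = rs * rs;
    int ix0 = std::max(0, (int)std::floor((cx[s] - rs) / dx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((cx[s] + rs) / dx - 0.5));
    int iy0 = std::max(0, (int)std::floor((cy[s] - rs) / dy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((cy[s] + rs) / dy - 0.5));
    int iz0 = std::max(0, (int)std::floor((cz[s] - rs) / dz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((cz[s] + rs) / dz - 0.5));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double zz = (iz + 0.5) * dz - cz[s];
      double zz2 = zz * zz;
      if (zz2 > r2) continue;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double yy = (iy + 0.5) * dy - cy[s];
        double yz2 = zz2 + yy * yy;
        if (yz2 > r2) continue;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          double xx = (ix + 0.5) * dx - cx[s];
          if (xx * xx + yz2 <= r2) vol[base + ix] = intensity;
        }
      }
    }
  }
  return vol;
}

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * rad + 1);
  for (int k = -rad; k <= rad; ++k)
    kern[k + rad] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < n; ++i) {
    int pos;
    if (axis == 0) pos = (int)(i % nx);
    else if (axis == 1) pos = (int)((i / nx) % ny);
    else pos = (int)(i / ((R_xlen_t)nx * ny));
    double acc = 0.0, wsum = 0.0;
    int k0 = std::max(-rad, -pos), k1 = std::min(rad, len - 1 - pos);
    for (int k = k0; k <= k1; ++k) {
      double w = kern[k + rad];
      acc += w * src[i + (R_xlen_t)k * stride];
      wsum += w;
    }
    dst[i] = acc / wsum;
  }
}

// Separable anisotropic Gaussian blur; sigma given in voxel units per axis.
// Kernels are renormalised at the grid boundary (constant fields are preserved).
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dims, NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  blur_axis(a, b, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(b, a, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(a, b, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(b.begin(), b.end());
}
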