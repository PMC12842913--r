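#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 3D connected-component labelling of a logical array by iterative flood
// fill. Components are numbered in raster-scan order of their seed voxel,
// so the component containing the smallest linear index receives label 1;
// this makes the equal-size tie-break in largest_component() deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector &mask,
                                   const IntegerVector &dim,
                                   const int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 &&
            (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = static_cast<int>(dxs.size());

  std::vector<R_xlen_t> stack;
  int label = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++label;
    labels[seed] = label;
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = static_cast<int>(cur % nx);
      const int y = static_cast<int>((cur / nx) % ny);
      const int z = static_cast<int>(cur / (static_cast<R_xlen_t>(nx) * ny));
      for (int k = 0; k < nn; ++k) {
        const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t idx =
            xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = label;
          stack.push_back(idx);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Slice-wise binary erosion: `iterations` passes of a full 3x3 in-plane
// structuring element, applied independently to every z slice (no coupling
// along the cranio-caudal axis). Voxels on the slice border are eroded.
// [[Rcpp::export]]
LogicalVector erode_inplane_cpp(const LogicalVector &mask,
                                const IntegerVector &dim,
                                const int iterations) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;

  for (int it = 0; it < iterations; ++it) {
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t base = static_cast<R_xlen_t>(z) * nx * ny;
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t idx = base + y * static_cast<R_xlen_t>(nx) + x;
          char keep = cur[idx];
          if (keep) {
            if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1) {
              keep = 0;
            } else {
              for (int dy = -1; dy <= 1 && keep; ++dy)
                for (int dx = -1; dx <= 1 && keep; ++dx)
                  if (!cur[idx + dy * static_cast<R_xlen_t>(nx) + dx]) keep = 0;
            }
          }
          nxt[idx] = keep;
        }
      }
    }
    cur.swap(nxt);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dim;
  return out;
}
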