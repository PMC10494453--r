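// Geometric helpers: trilinear / nearest-neighbour resampling through a
// voxel-space affine (plus optional dense displacement field, used for the
// elastic augmentation), and 26-connected component labelling.
#include <Rcpp.h>
using namespace Rcpp;

static inline long vidx(int x, int y, int z, int D0, int D1) {
  return x + (long)D0 * (y + (long)D1 * z);
}

// A is 3x4: source = A[,1:3] %*% out_coord + A[,4], all in 0-based voxel units.
// disp, if non-empty, is an (Nout x 3) matrix of additional source offsets.
// clamp = TRUE replicates the border voxel for out-of-volume samples (used
// for grid resampling, where interpolation must preserve constants); FALSE
// substitutes the fill value (used for augmentation warps).
// [[Rcpp::export(name = ".warp_resample")]]
NumericVector warp_resample(NumericVector vol, IntegerVector dims_in,
                            IntegerVector dims_out, NumericMatrix A,
                            NumericMatrix disp, bool nearest, double fill,
                            bool clamp) {
  const int D0 = dims_in[0], D1 = dims_in[1], D2 = dims_in[2];
  const int E0 = dims_out[0], E1 = dims_out[1], E2 = dims_out[2];
  const bool has_disp = disp.nrow() > 0;
  NumericVector out((long)E0 * E1 * E2);
  long o = 0;
  for (int z = 0; z < E2; ++z)
    for (int y = 0; y < E1; ++y)
      for (int x = 0; x < E0; ++x, ++o) {
        double sx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + A(0, 3);
        double sy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + A(1, 3);
        double sz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + A(2, 3);
        if (has_disp) { sx += disp(o, 0); sy += disp(o, 1); sz += disp(o, 2); }
        if (nearest) {
          int ix = (int)std::lround(sx), iy = (int)std::lround(sy),
              iz = (int)std::lround(sz);
          if (clamp) {
            ix = std::min(std::max(ix, 0), D0 - 1);
            iy = std::min(std::max(iy, 0), D1 - 1);
            iz = std::min(std::max(iz, 0), D2 - 1);
            out[o] = vol[vidx(ix, iy, iz, D0, D1)];
          } else {
            out[o] = (ix < 0 || iy < 0 || iz < 0 || ix >= D0 || iy >= D1 ||
                      iz >= D2) ? fill : vol[vidx(ix, iy, iz, D0, D1)];
          }
        } else {
          const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
                    fz = (int)std::floor(sz);
          const double tx = sx - fx, ty = sy - fy, tz = sz - fz;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int ix = fx + dx, iy = fy + dy, iz = fz + dz;
                const double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                                 (dz ? tz : 1 - tz);
                double v;
                if (clamp) {
                  ix = std::min(std::max(ix, 0), D0 - 1);
                  iy = std::min(std::max(iy, 0), D1 - 1);
                  iz = std::min(std::max(iz, 0), D2 - 1);
                  v = vol[vidx(ix, iy, iz, D0, D1)];
                } else {
                  v = (ix < 0 || iy < 0 || iz < 0 || ix >= D0 || iy >= D1 ||
                       iz >= D2) ? fill : vol[vidx(ix, iy, iz, D0, D1)];
                }
                acc += w * v;
              }
          out[o] = acc;
        }
      }
  return out;
}

// 26-connected component labelling of a binary volume; labels 1..K in
// discovery order, 0 = background.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dims) {
  const int D0 = dims[0], D1 = dims[1], D2 = dims[2];
  const long N = (long)D0 * D1 * D2;
  IntegerVector lab(N, 0);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < N; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int x = (int)(v % D0), y = (int)((v / D0) % D1),
                z = (int)(v / ((long)D0 * D1));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || ny < 0 || nz < 0 || nx >= D0 || ny >= D1 || nz >= D2)
              continue;
            const long u = vidx(nx, ny, nz, D0, D1);
            if (mask[u] != 0 && lab[u] == 0) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
    }
  }
  return lab;
}
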