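// Trilinear resampling kernels for cubic volumes.
//
// The rotation loop visits every output voxel, pulls the source coordinate
// through the inverse rotation about the fixed centre voxel and interpolates
// trilinearly; voxels mapped from outside the cube receive `fill`. This is
// the one pixel-loop hot spot of the package, hence compiled.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".rotate_trilinear")]]
NumericVector rotate_trilinear(NumericVector vol, int L,
                               NumericMatrix Rinv, double centre,
                               double fill) {
  NumericVector out(L * L * L);
  const double r11 = Rinv(0, 0), r12 = Rinv(0, 1), r13 = Rinv(0, 2);
  const double r21 = Rinv(1, 0), r22 = Rinv(1, 1), r23 = Rinv(1, 2);
  const double r31 = Rinv(2, 0), r32 = Rinv(2, 1), r33 = Rinv(2, 2);
  const double *v = vol.begin();
  double *o = out.begin();
  const int LL = L * L;
  R_xlen_t p = 0;
  for (int z = 0; z < L; ++z) {
    const double dz = z - centre;
    for (int y = 0; y < L; ++y) {
      const double dy = y - centre;
      for (int x = 0; x < L; ++x, ++p) {
        const double dx = x - centre;
        const double sx = r11 * dx + r12 * dy + r13 * dz + centre;
        const double sy = r21 * dx + r22 * dy + r23 * dz + centre;
        const double sz = r31 * dx + r32 * dy + r33 * dz + centre;
        const double fx = std::floor(sx), fy = std::floor(sy),
                     fz = std::floor(sz);
        const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
        if (x0 < 0 || y0 < 0 || z0 < 0 ||
            x0 > L - 2 || y0 > L - 2 || z0 > L - 2) {
          // Partially outside: blend in-range corners with the fill value.
          const double wx1 = sx - fx, wy1 = sy - fy, wz1 = sz - fz;
          double acc = 0.0;
          for (int cz = 0; cz <= 1; ++cz) {
            const int zz = z0 + cz;
            const double wz = cz ? wz1 : 1.0 - wz1;
            if (wz == 0.0) continue;
            for (int cy = 0; cy <= 1; ++cy) {
              const int yy = y0 + cy;
              const double wy = cy ? wy1 : 1.0 - wy1;
              if (wy == 0.0) continue;
              for (int cx = 0; cx <= 1; ++cx) {
                const int xx = x0 + cx;
                const double w = wz * wy * (cx ? wx1 : 1.0 - wx1);
                if (w == 0.0) continue;
                const bool in = xx >= 0 && xx < L && yy >= 0 && yy < L &&
                                zz >= 0 && zz < L;
                acc += w * (in ? v[xx + L * yy + LL * zz] : fill);
              }
            }
          }
          o[p] = acc;
        } else {
          const double wx = sx - fx, wy = sy - fy, wz = sz - fz;
          const double *b = v + x0 + L * y0 + LL * z0;
          const double c00 = b[0] + wx * (b[1] - b[0]);
          const double c10 = b[L] + wx * (b[L + 1] - b[L]);
          const double c01 = b[LL] + wx * (b[LL + 1] - b[LL]);
          const double c11 = b[LL + L] + wx * (b[LL + L + 1] - b[LL + L]);
          const double c0 = c00 + wy * (c10 - c00);
          const double c1 = c01 + wy * (c11 - c01);
          o[p] = c0 + wz * (c1 - c0);
        }
      }
    }
  }
  return out;
}
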