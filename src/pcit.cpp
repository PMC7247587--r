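#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Partial-correlation-and-information-theory edge elimination.
//
// For every unordered trio {x, y, z} the three first-order partial
// correlations are computed,
//   r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
// and the trio tolerance
//   eps = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3.
// The pair (x, y) is eliminated by z iff
//   |r_xy| < |eps * r_xz|  AND  |r_xy| < |eps * r_yz|   (strict <).
// An edge survives iff no third locus eliminates it. A direct correlation
// with |r| < 1e-12 contributes ratio term 0 (division guard); |r| is
// clipped to 1 - 1e-12 before partials to keep the square roots real.
//
// [[Rcpp::export(name = ".pcit_keep_cpp")]]
LogicalMatrix pcit_keep_cpp(NumericMatrix r) {
  const int n = r.nrow();
  const double guard = 1e-12;
  const double clip = 1.0 - 1e-12;
  LogicalMatrix keep(n, n);
  // start from all pairs kept
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) keep(i, j) = true;
  if (n < 3) return keep;

  // clipped working copy
  NumericMatrix rc(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = r(i, j);
      if (v > clip) v = clip;
      if (v < -clip) v = -clip;
      rc(i, j) = v;
    }

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = rc(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = rc(x, z);
        const double ryz = rc(y, z);
        const double pxy = (rxy - rxz * ryz) /
          std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        const double pxz = (rxz - rxy * ryz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        const double pyz = (ryz - rxy * rxz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
        double eps = 0.0;
        if (std::fabs(rxy) >= guard) eps += pxy / rxy;
        if (std::fabs(rxz) >= guard) eps += pxz / rxz;
        if (std::fabs(ryz) >= guard) eps += pyz / ryz;
        eps /= 3.0;
        const double axy = std::fabs(rxy);
        const double axz = std::fabs(rxz);
        const double ayz = std::fabs(ryz);
        const double ae = std::fabs(eps);
        // pair (x, y) vs third locus z
        if (axy < ae * axz && axy < ae * ayz) {
          keep(x, y) = false; keep(y, x) = false;
        }
        // pair (x, z) vs third locus y
        if (axz < ae * axy && axz < ae * ayz) {
          keep(x, z) = false; keep(z, x) = false;
        }
        // pair (y, z) vs third locus x
        if (ayz < ae * axy && ayz < ae * axz) {
          keep(y, z) = false; keep(z, y) = false;
        }
      }
    }
  }
  return keep;
}
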