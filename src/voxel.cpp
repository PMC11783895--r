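#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Distance-based Gaussian density accumulation on a regular lattice.
// Each atom contributes w * exp(-d^2 / (2 sigma^2)) to every voxel center
// within the cutoff; contributions are additive and atom-type agnostic.
// [[Rcpp::export(name = ".voxelize_cpp")]]
NumericVector voxelize_cpp(NumericMatrix coords, int dim, NumericVector origin,
                           double spacing, double sigma, double cutoff,
                           double weight) {
  const int na = coords.nrow();
  NumericVector out(dim * dim * dim);
  const double cut2 = cutoff * cutoff;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // voxel centers: origin + (i + 0.5) * spacing
  std::vector<double> cx(dim);
  for (int i = 0; i < dim; ++i) cx[i] = (i + 0.5) * spacing;
  for (int a = 0; a < na; ++a) {
    const double ax = coords(a, 0) - origin[0];
    const double ay = coords(a, 1) - origin[1];
    const double az = coords(a, 2) - origin[2];
    int idx = 0;
    for (int z = 0; z < dim; ++z) {
      const double dz = cx[z] - az, dz2 = dz * dz;
      for (int y = 0; y < dim; ++y) {
        const double dy = cx[y] - ay, dyz2 = dy * dy + dz2;
        for (int x = 0; x < dim; ++x, ++idx) {
          const double dx = cx[x] - ax;
          const double d2 = dx * dx + dyz2;
          if (d2 <= cut2) out[idx] += weight * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  // layout: x fastest, then y, then z (matches R array dim c(dim,dim,dim))
  return out;
}
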