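#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model-derived density: each atom contributes an isotropic Gaussian of
// integral `weight` (atomic number), real-space sigma in Angstrom, truncated
// at a per-axis box of +/- trunc*sigma.  Grid layout matches an R array of
// dim (nx, ny, nz): linear index ix + nx*(iy + ny*iz), voxel (0,0,0) center
// at `origin`.

static inline void atom_box(double pos, double origin, double spacing,
                            int n, double reach, int &lo, int &hi) {
  lo = (int)std::ceil((pos - reach - origin) / spacing);
  hi = (int)std::floor((pos + reach - origin) / spacing);
  if (lo < 0) lo = 0;
  if (hi > n - 1) hi = n - 1;
}

// [[Rcpp::export(name = ".simulate_density_cpp")]]
NumericVector simulate_density_cpp(NumericMatrix xyz, NumericVector weight,
                                   IntegerVector dims, NumericVector origin,
                                   NumericVector spacing, double sigma,
                                   double trunc_sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector rho((R_xlen_t)nx * ny * nz);
  const double reach = trunc_sigma * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double amp = weight[a] * norm;
    int x0, x1, y0, y1, z0, z1;
    atom_box(ax, origin[0], spacing[0], nx, reach, x0, x1);
    atom_box(ay, origin[1], spacing[1], ny, reach, y0, y1);
    atom_box(az, origin[2], spacing[2], nz, reach, z0, z1);
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = origin[2] + iz * spacing[2] - az;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = origin[1] + iy * spacing[1] - ay;
        const double eyz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = origin[0] + ix * spacing[0] - ax;
          rho[base + ix] += amp * std::exp(-(dx * dx + eyz) * inv2s2);
        }
      }
    }
  }
  return rho;
}

// Pearson correlation between `em` and the model density of `xyz`, plus the
// gradient of that correlation with respect to the atom coordinates.
// Returns list(ccc, grad [n x 3], rho).
// [[Rcpp::export(name = ".density_ccc_grad_cpp")]]
List density_ccc_grad_cpp(NumericMatrix xyz, NumericVector weight,
                          NumericVector em, IntegerVector dims,
                          NumericVector origin, NumericVector spacing,
                          double sigma, double trunc_sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector rho = simulate_density_cpp(xyz, weight, dims, origin, spacing,
                                           sigma, trunc_sigma);
  double mean_a = 0.0, mean_b = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) { mean_a += em[i]; mean_b += rho[i]; }
  mean_a /= nvox; mean_b /= nvox;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    const double da = em[i] - mean_a, db = rho[i] - mean_b;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0)
    stop("zero variance in one of the maps: cannot correlate");
  const double denom = std::sqrt(saa * sbb);
  const double ccc = sab / denom;
  // dC/drho_i = (em_i - mean_a)/denom - ccc*(rho_i - mean_b)/sbb
  // accumulated over each atom's truncation box through the Gaussian kernel.
  const double reach = trunc_sigma * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  NumericMatrix grad(xyz.nrow(), 3);
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double amp = weight[a] * norm;
    int x0, x1, y0, y1, z0, z1;
    atom_box(ax, origin[0], spacing[0], nx, reach, x0, x1);
    atom_box(ay, origin[1], spacing[1], ny, reach, y0, y1);
    atom_box(az, origin[2], spacing[2], nz, reach, z0, z1);
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = origin[2] + iz * spacing[2] - az;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = origin[1] + iy * spacing[1] - ay;
        const double eyz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = origin[0] + ix * spacing[0] - ax;
          const double g = amp * std::exp(-(dx * dx + eyz) * inv2s2);
          const double dC = (em[base + ix] - mean_a) / denom -
            ccc * (rho[base + ix] - mean_b) / sbb;
          // drho_i/datom = g * (r_i - r_atom)/sigma^2
          const double f = dC * g * invs2;
          gx += f * dx; gy += f * dy; gz += f * dz;
        }
      }
    }
    grad(a, 0) = gx; grad(a, 1) = gy; grad(a, 2) = gz;
  }
  return List::create(_["ccc"] = ccc, _["grad"] = grad, _["rho"] = rho);
}
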