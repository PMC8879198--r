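#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian kernel g(r) = exp(-(3/(2*sigma^2)) * |r - r_n|^2), i.e. an
// isotropic Gaussian with per-axis standard deviation s = sigma / sqrt(3).
// Voxel values are the exact triple integral of g over the voxel, which
// factorises into a product of three 1-D integrals:
//   I(a, b) = s * sqrt(pi/2) * (erf((b-mu)/(s*sqrt2)) - erf((a-mu)/(s*sqrt2)))
// Contributions are truncated to the rectangular box |axis - mu| <= trunc*sigma.

static inline double seg_integral(double a, double b, double mu, double s) {
    const double inv = 1.0 / (s * M_SQRT2);
    return s * std::sqrt(M_PI / 2.0) * (std::erf((b - mu) * inv) - std::erf((a - mu) * inv));
}

static inline void axis_range(double mu, double origin, double spacing, int dim,
                              double cut, int &lo, int &hi) {
    // voxel i center = origin + i*spacing; keep centers within cut of mu
    lo = (int)std::ceil((mu - cut - origin) / spacing);
    hi = (int)std::floor((mu + cut - origin) / spacing);
    if (lo < 0) lo = 0;
    if (hi > dim - 1) hi = dim - 1;
}

// [[Rcpp::export(name = ".cppSimDensity")]]
NumericVector cppSimDensity(NumericMatrix coords, NumericVector origin,
                            NumericVector spacing, IntegerVector dims,
                            double sigma, double trunc) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double s = sigma / std::sqrt(3.0);
    const double cut = trunc * sigma;
    NumericVector out((R_xlen_t)nx * ny * nz);
    const int natom = coords.nrow();
    std::vector<double> ix(nx), iy(ny), iz(nz);
    for (int n = 0; n < natom; ++n) {
        const double x = coords(n, 0), y = coords(n, 1), z = coords(n, 2);
        int x0, x1, y0, y1, z0, z1;
        axis_range(x, origin[0], spacing[0], nx, cut, x0, x1);
        axis_range(y, origin[1], spacing[1], ny, cut, y0, y1);
        axis_range(z, origin[2], spacing[2], nz, cut, z0, z1);
        if (x0 > x1 || y0 > y1 || z0 > z1) continue;
        for (int i = x0; i <= x1; ++i) {
            double c = origin[0] + i * spacing[0];
            ix[i] = seg_integral(c - 0.5 * spacing[0], c + 0.5 * spacing[0], x, s);
        }
        for (int j = y0; j <= y1; ++j) {
            double c = origin[1] + j * spacing[1];
            iy[j] = seg_integral(c - 0.5 * spacing[1], c + 0.5 * spacing[1], y, s);
        }
        for (int k = z0; k <= z1; ++k) {
            double c = origin[2] + k * spacing[2];
            iz[k] = seg_integral(c - 0.5 * spacing[2], c + 0.5 * spacing[2], z, s);
        }
        for (int k = z0; k <= z1; ++k) {
            const R_xlen_t offk = (R_xlen_t)k * nx * ny;
            for (int j = y0; j <= y1; ++j) {
                const double w = iy[j] * iz[k];
                const R_xlen_t off = offk + (R_xlen_t)j * nx;
                for (int i = x0; i <= x1; ++i) out[off + i] += ix[i] * w;
            }
        }
    }
    return out;
}

// Accumulates, for each atom, sum_v weights[v] * d rho_v / d r_n.
// d/dmu of the 1-D segment integral I(a,b;mu) is g(a;mu) - g(b;mu) with
// g(t;mu) = exp(-(t-mu)^2/(2 s^2)) (difference of face Gaussians).
// [[Rcpp::export(name = ".cppDensityGradDot")]]
NumericMatrix cppDensityGradDot(NumericMatrix coords, NumericVector origin,
                                NumericVector spacing, IntegerVector dims,
                                double sigma, double trunc, NumericVector weights) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double s = sigma / std::sqrt(3.0);
    const double s2 = 2.0 * s * s;
    const double cut = trunc * sigma;
    const int natom = coords.nrow();
    NumericMatrix grad(natom, 3);
    std::vector<double> ix(nx), iy(ny), iz(nz), dx(nx), dy(ny), dz(nz);
    for (int n = 0; n < natom; ++n) {
        const double x = coords(n, 0), y = coords(n, 1), z = coords(n, 2);
        int x0, x1, y0, y1, z0, z1;
        axis_range(x, origin[0], spacing[0], nx, cut, x0, x1);
        axis_range(y, origin[1], spacing[1], ny, cut, y0, y1);
        axis_range(z, origin[2], spacing[2], nz, cut, z0, z1);
        if (x0 > x1 || y0 > y1 || z0 > z1) continue;
        for (int i = x0; i <= x1; ++i) {
            double c = origin[0] + i * spacing[0];
            double a = c - 0.5 * spacing[0], b = c + 0.5 * spacing[0];
            ix[i] = seg_integral(a, b, x, s);
            dx[i] = std::exp(-(a - x) * (a - x) / s2) - std::exp(-(b - x) * (b - x) / s2);
        }
        for (int j = y0; j <= y1; ++j) {
            double c = origin[1] + j * spacing[1];
            double a = c - 0.5 * spacing[1], b = c + 0.5 * spacing[1];
            iy[j] = seg_integral(a, b, y, s);
            dy[j] = std::exp(-(a - y) * (a - y) / s2) - std::exp(-(b - y) * (b - y) / s2);
        }
        for (int k = z0; k <= z1; ++k) {
            double c = origin[2] + k * spacing[2];
            double a = c - 0.5 * spacing[2], b = c + 0.5 * spacing[2];
            iz[k] = seg_integral(a, b, z, s);
            dz[k] = std::exp(-(a - z) * (a - z) / s2) - std::exp(-(b - z) * (b - z) / s2);
        }
        double gx = 0.0, gy = 0.0, gz = 0.0;
        for (int k = z0; k <= z1; ++k) {
            const R_xlen_t offk = (R_xlen_t)k * nx * ny;
            for (int j = y0; j <= y1; ++j) {
                const R_xlen_t off = offk + (R_xlen_t)j * nx;
                for (int i = x0; i <= x1; ++i) {
                    const double w = weights[off + i];
                    if (w == 0.0) continue;
                    gx += w * dx[i] * iy[j] * iz[k];
                    gy += w * ix[i] * dy[j] * iz[k];
                    gz += w * ix[i] * iy[j] * dz[k];
                }
            }
        }
        grad(n, 0) = gx;
        grad(n, 1) = gy;
        grad(n, 2) = gz;
    }
    return grad;
}

// Marks voxels whose center lies within `radius` of any atom.
// [[Rcpp::export(name = ".cppAtomMask")]]
LogicalVector cppAtomMask(NumericMatrix coords, NumericVector origin,
                          NumericVector spacing, IntegerVector dims,
                          double radius) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    LogicalVector out((R_xlen_t)nx * ny * nz);
    const double r2 = radius * radius;
    const int natom = coords.nrow();
    for (int n = 0; n < natom; ++n) {
        const double x = coords(n, 0), y = coords(n, 1), z = coords(n, 2);
        int x0, x1, y0, y1, z0, z1;
        axis_range(x, origin[0], spacing[0], nx, radius, x0, x1);
        axis_range(y, origin[1], spacing[1], ny, radius, y0, y1);
        axis_range(z, origin[2], spacing[2], nz, radius, z0, z1);
        for (int k = z0; k <= z1; ++k) {
            double pz = origin[2] + k * spacing[2] - z;
            for (int j = y0; j <= y1; ++j) {
                double py = origin[1] + j * spacing[1] - y;
                for (int i = x0; i <= x1; ++i) {
                    double px = origin[0] + i * spacing[0] - x;
                    if (px * px + py * py + pz * pz <= r2)
                        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
                }
            }
        }
    }
    return out;
}
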