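#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact Euclidean distance transform on a regular 3-D grid with
// anisotropic spacing, via the separable lower-envelope (parabola)
// algorithm. Input: feature-voxel occupancy; output: distance (mm) from
// every voxel center to the nearest feature voxel center.

static const double INF = 1e20;

// 1-D squared-distance transform along a line of n samples with spacing h.
// f: input squared distances; d: output; v/z: work buffers (size n, n+1).
static void dt1d(const double *f, double *d, int n, double h,
                 int *v, double *z) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    const double h2 = h * h;
    for (int q = 1; q < n; ++q) {
        double s;
        for (;;) {
            int p = v[k];
            s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) /
                (2.0 * h2 * (q - p));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dx = (q - v[k]) * h;
        d[q] = dx * dx + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d")]]
Rcpp::NumericVector edt3d(Rcpp::LogicalVector occ, Rcpp::IntegerVector dim,
                          Rcpp::NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (occ.size() != n)
        Rcpp::stop("occupancy length does not match dimensions");
    Rcpp::NumericVector out(n);
    double *D = REAL(out);
    for (R_xlen_t i = 0; i < n; ++i)
        D[i] = occ[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass 1: along x
    for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy) {
            double *line = D + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            dt1d(line, d.data(), nx, spacing[0], v.data(), z.data());
            std::copy(d.begin(), d.begin() + nx, line);
        }
    // pass 2: along y
    for (int zz = 0; zz < nz; ++zz)
        for (int xx = 0; xx < nx; ++xx) {
            R_xlen_t base = xx + (R_xlen_t)nx * ny * zz;
            for (int yy = 0; yy < ny; ++yy)
                f[yy] = D[base + (R_xlen_t)nx * yy];
            dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
            for (int yy = 0; yy < ny; ++yy)
                D[base + (R_xlen_t)nx * yy] = d[yy];
        }
    // pass 3: along z
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
            R_xlen_t base = xx + (R_xlen_t)nx * yy;
            for (int zz = 0; zz < nz; ++zz)
                f[zz] = D[base + stride * zz];
            dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
            for (int zz = 0; zz < nz; ++zz)
                D[base + stride * zz] = d[zz];
        }

    for (R_xlen_t i = 0; i < n; ++i)
        D[i] = std::sqrt(D[i]);
    return out;
}
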