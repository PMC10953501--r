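#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid, computed by the
// separable lower-envelope (parabola) algorithm applied axis by axis on
// squared distances. Input is a logical/numeric feature mask; output is the
// distance in physical units (mm) from each voxel to the nearest feature
// voxel. Arrays are in R column-major order with dim = (n1, n2, n3); spacing
// gives the physical step along each dimension.

static const double INF = std::numeric_limits<double>::infinity();

// One 1D pass: f holds squared distances sampled at positions i*s; overwrite
// with the lower envelope min_q ((i-q)^2 s^2 + f[q]).
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
    const int n = (int)f.size();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    const double s2 = s * s;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[k]] == INF) { // no finite site yet
            v[k] = q;
            z[k] = -INF;
            z[k + 1] = INF;
            continue;
        }
        double sct;
        while (true) {
            sct = ((f[q] + (double)q * q * s2) - (f[v[k]] + (double)v[k] * v[k] * s2)) /
                  (2.0 * s2 * (q - v[k]));
            if (sct <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = sct;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        if (f[v[0]] == INF) { d[q] = INF; continue; }
        while (z[k + 1] < (double)q) ++k;
        double dq = (double)(q - v[k]) * s;
        d[q] = dq * dq + f[v[k]];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
    if (dim.size() != 3 || spacing.size() != 3)
        stop("dim and spacing must have length 3");
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    if (feature.size() != n) stop("feature length does not match dim");

    std::vector<double> g((size_t)n);
    for (R_xlen_t i = 0; i < n; ++i) g[(size_t)i] = feature[i] ? 0.0 : INF;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> line((size_t)nmax), d((size_t)nmax), z((size_t)nmax + 1);
    std::vector<int> v((size_t)nmax);

    // pass along dim 1 (fastest-varying)
    for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
            line.assign(g.begin() + base, g.begin() + base + n1);
            line.resize((size_t)n1);
            dt1d(line, spacing[0], d, v, z);
            for (int i = 0; i < n1; ++i) g[(size_t)(base + i)] = line[(size_t)i];
        }
    // pass along dim 2
    for (int k = 0; k < n3; ++k)
        for (int i = 0; i < n1; ++i) {
            line.resize((size_t)n2);
            for (int j = 0; j < n2; ++j)
                line[(size_t)j] = g[(size_t)k * n1 * n2 + (R_xlen_t)j * n1 + i];
            dt1d(line, spacing[1], d, v, z);
            for (int j = 0; j < n2; ++j)
                g[(size_t)((R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1 + i)] = line[(size_t)j];
        }
    // pass along dim 3
    if (n3 > 1)
        for (int j = 0; j < n2; ++j)
            for (int i = 0; i < n1; ++i) {
                line.resize((size_t)n3);
                for (int k = 0; k < n3; ++k)
                    line[(size_t)k] = g[(size_t)k * n1 * n2 + (R_xlen_t)j * n1 + i];
                dt1d(line, spacing[2], d, v, z);
                for (int k = 0; k < n3; ++k)
                    g[(size_t)((R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1 + i)] = line[(size_t)k];
            }

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        double gv = g[(size_t)i];
        out[i] = (gv == INF) ? R_PosInf : std::sqrt(gv);
    }
    out.attr("dim") = dim;
    return out;
}
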