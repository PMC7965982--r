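#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// neighbour offsets for 6- or 26-connectivity on a 3D grid
static void neighbour_offsets(int connectivity,
                              std::vector<std::array<int, 3>>& offs) {
    offs.clear();
    if (connectivity == 6) {
        offs = {{{1,0,0}}, {{-1,0,0}}, {{0,1,0}},
                {{0,-1,0}}, {{0,0,1}}, {{0,0,-1}}};
    } else if (connectivity == 26) {
        for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dz = -1; dz <= 1; ++dz)
                    if (dx || dy || dz)
                        offs.push_back({{dx, dy, dz}});
    } else {
        stop("connectivity must be 6 or 26");
    }
}

// Label connected components of a binary mask; labels start at 1, 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 6) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    std::vector<std::array<int, 3>> offs;
    neighbour_offsets(connectivity, offs);

    IntegerVector labels(n, 0);
    std::vector<R_xlen_t> queue;
    int next_label = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || labels[s]) continue;
        ++next_label;
        labels[s] = next_label;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            R_xlen_t v = queue.back();
            queue.pop_back();
            int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
            for (const auto& o : offs) {
                int xx = x + o[0], yy = y + o[1], zz = z + o[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[w] && !labels[w]) {
                    labels[w] = next_label;
                    queue.push_back(w);
                }
            }
        }
    }
    return labels;
}

// Threshold-free cluster enhancement:
//   TFCE(v) = sum over h = dh, 2dh, ... <= stat(v) of e(h, v)^E * h^H * dh
// where e(h, v) is the voxel count of the connected component containing v
// in the supra-threshold set {stat >= h}. Negative values contribute 0.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (stat.size() != n) stop("stat length does not match dims");
    if (dh <= 0) stop("dh must be > 0");

    NumericVector out(n, 0.0);
    double mx = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!R_finite(stat[i])) stop("stat map contains non-finite values");
        if (stat[i] > mx) mx = stat[i];
    }
    if (mx <= 0) return out;

    LogicalVector mask(n);
    // small tolerance so a voxel exactly at k*dh is included at that step
    const double eps = 1e-12 * std::max(1.0, mx);
    for (double h = dh; h <= mx + eps; h += dh) {
        for (R_xlen_t i = 0; i < n; ++i) mask[i] = stat[i] >= h - eps;
        IntegerVector labels = label_components_cpp(mask, dims, connectivity);
        int nlab = 0;
        for (R_xlen_t i = 0; i < n; ++i)
            if (labels[i] > nlab) nlab = labels[i];
        if (nlab == 0) break;
        std::vector<double> counts(nlab + 1, 0.0);
        for (R_xlen_t i = 0; i < n; ++i)
            if (labels[i]) counts[labels[i]] += 1.0;
        const double hterm = std::pow(h, H) * dh;
        for (R_xlen_t i = 0; i < n; ++i)
            if (labels[i]) out[i] += std::pow(counts[labels[i]], E) * hterm;
    }
    return out;
}
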