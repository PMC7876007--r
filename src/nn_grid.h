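#pragma once
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

// Uniform-grid spatial index over a fixed point set.  Supports single
// nearest-neighbour queries (ties broken by lowest point index) and
// fixed-radius neighbour collection.
class PointGrid {
public:
    const arma::mat& P;      // n x 3, row-major points (mm)
    double h;                // cell edge
    arma::vec::fixed<3> lo;
    int nx, ny, nz;
    std::unordered_map<int64_t, std::vector<int>> cells;

    explicit PointGrid(const arma::mat& pts, double cell_hint = -1.0) : P(pts) {
        const int n = (int)P.n_rows;
        arma::rowvec mn = arma::min(P, 0), mx = arma::max(P, 0);
        double ext = std::max({mx[0] - mn[0], mx[1] - mn[1], mx[2] - mn[2]});
        if (!(ext > 0)) ext = 1.0;
        double target = ext / std::max(1.0, std::cbrt((double)n / 2.0));
        h = (cell_hint > 0) ? cell_hint : target;
        if (!(h > 0)) h = 1.0;
        for (int k = 0; k < 3; ++k) lo[k] = mn[k] - 0.5 * h;
        nx = (int)std::floor((mx[0] - lo[0]) / h) + 1;
        ny = (int)std::floor((mx[1] - lo[1]) / h) + 1;
        nz = (int)std::floor((mx[2] - lo[2]) / h) + 1;
        cells.reserve((size_t)n);
        for (int i = 0; i < n; ++i)
            cells[key(cx(P(i, 0)), cy(P(i, 1)), cz(P(i, 2)))].push_back(i);
    }

    int cx(double x) const { return clampi((int)std::floor((x - lo[0]) / h), 0, nx - 1); }
    int cy(double y) const { return clampi((int)std::floor((y - lo[1]) / h), 0, ny - 1); }
    int cz(double z) const { return clampi((int)std::floor((z - lo[2]) / h), 0, nz - 1); }
    static int clampi(int v, int a, int b) { return v < a ? a : (v > b ? b : v); }
    int64_t key(int i, int j, int k) const {
        return ((int64_t)i * (int64_t)ny + j) * (int64_t)nz + k;
    }

    // Nearest point index (0-based) and squared distance.
    int nearest(const arma::vec::fixed<3>& q, double& best_d2) const {
        int best = -1;
        best_d2 = std::numeric_limits<double>::infinity();
        int ci = cx(q[0]), cj = cy(q[1]), ck = cz(q[2]);
        int max_ring = std::max({nx, ny, nz});
        for (int r = 0; r <= max_ring; ++r) {
            if (best >= 0) {
                // smallest possible distance for ring r (cells at Chebyshev
                // distance r from the query's cell)
                double dmin = (r - 1) * h;
                if (dmin > 0 && dmin * dmin > best_d2) break;
            }
            scan_ring(q, ci, cj, ck, r, best, best_d2);
        }
        return best;
    }

    void scan_cell(const arma::vec::fixed<3>& q, int i, int j, int k,
                   int& best, double& best_d2) const {
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return;
        auto it = cells.find(key(i, j, k));
        if (it == cells.end()) return;
        for (int idx : it->second) {
            double dx = P(idx, 0) - q[0], dy = P(idx, 1) - q[1], dz = P(idx, 2) - q[2];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best_d2 || (d2 == best_d2 && idx < best)) {
                best_d2 = d2;
                best = idx;
            }
        }
    }

    void scan_ring(const arma::vec::fixed<3>& q, int ci, int cj, int ck, int r,
                   int& best, double& best_d2) const {
        if (r == 0) { scan_cell(q, ci, cj, ck, best, best_d2); return; }
        for (int i = ci - r; i <= ci + r; ++i)
            for (int j = cj - r; j <= cj + r; ++j)
                for (int k = ck - r; k <= ck + r; ++k) {
                    int ch = std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)});
                    if (ch != r) continue;
                    scan_cell(q, i, j, k, best, best_d2);
                }
    }

    // All point indices within radius rad of q.
    void radius(const arma::vec::fixed<3>& q, double rad, std::vector<int>& out) const {
        out.clear();
        double r2 = rad * rad;
        int i0 = cx(q[0] - rad), i1 = cx(q[0] + rad);
        int j0 = cy(q[1] - rad), j1 = cy(q[1] + rad);
        int k0 = cz(q[2] - rad), k1 = cz(q[2] + rad);
        for (int i = i0; i <= i1; ++i)
            for (int j = j0; j <= j1; ++j)
                for (int k = k0; k <= k1; ++k) {
                    auto it = cells.find(key(i, j, k));
                    if (it == cells.end()) continue;
                    for (int idx : it->second) {
                        double dx = P(idx, 0) - q[0], dy = P(idx, 1) - q[1], dz = P(idx, 2) - q[2];
                        if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(idx);
                    }
                }
    }
};
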