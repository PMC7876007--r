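// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include "tri_dist.h"
using namespace Rcpp;

static inline arma::vec::fixed<3> vrow(const arma::mat& M, int i) {
    arma::vec::fixed<3> v;
    v[0] = M(i, 0); v[1] = M(i, 1); v[2] = M(i, 2);
    return v;
}

// Closest surface point on a triangle mesh for each query point.
// F is 1-based (R convention).  Returns distances, closest points,
// triangle indices (1-based) and barycentric coordinates.
// [[Rcpp::export]]
List cpp_closest_point_mesh(const arma::mat& queries, const arma::mat& V,
                            const arma::imat& F) {
    const int m = (int)queries.n_rows, nf = (int)F.n_rows;
    if (nf == 0) stop("mesh has no faces");
    // per-triangle bounding boxes for quick rejection
    arma::mat blo(nf, 3), bhi(nf, 3);
    for (int t = 0; t < nf; ++t) {
        for (int c = 0; c < 3; ++c) {
            double a = V(F(t, 0) - 1, c), b = V(F(t, 1) - 1, c), d = V(F(t, 2) - 1, c);
            blo(t, c) = std::min({a, b, d});
            bhi(t, c) = std::max({a, b, d});
        }
    }
    NumericVector dist(m);
    NumericMatrix closest(m, 3), bary(m, 3);
    IntegerVector tri(m);
    for (int i = 0; i < m; ++i) {
        arma::vec::fixed<3> q = vrow(queries, i);
        double best_d2 = std::numeric_limits<double>::infinity();
        arma::vec::fixed<3> best_p;
        double best_b[3] = {0, 0, 0};
        int best_t = -1;
        for (int t = 0; t < nf; ++t) {
            double d2lo = 0.0;
            for (int c = 0; c < 3; ++c) {
                double d = (q[c] < blo(t, c)) ? blo(t, c) - q[c]
                         : (q[c] > bhi(t, c)) ? q[c] - bhi(t, c) : 0.0;
                d2lo += d * d;
            }
            if (d2lo >= best_d2) continue;
            double b[3];
            arma::vec::fixed<3> p = closest_point_triangle(
                q, vrow(V, F(t, 0) - 1), vrow(V, F(t, 1) - 1), vrow(V, F(t, 2) - 1), b);
            double d2 = arma::dot(q - p, q - p);
            if (d2 < best_d2) {
                best_d2 = d2; best_p = p; best_t = t;
                best_b[0] = b[0]; best_b[1] = b[1]; best_b[2] = b[2];
            }
        }
        dist[i] = std::sqrt(best_d2);
        tri[i] = best_t + 1;
        for (int c = 0; c < 3; ++c) {
            closest(i, c) = best_p[c];
            bary(i, c) = best_b[c];
        }
    }
    return List::create(_["distance"] = dist, _["point"] = closest,
                        _["triangle"] = tri, _["bary"] = bary);
}

// Signed distance of every voxel centre to a closed triangle mesh.
// Exact (unsigned) distance is computed within +/- exact_band of the
// surface; beyond that, distances are propagated by a 26-neighbour chamfer
// transform up to +/- band and clamped there.  Sign is negative inside,
// determined by x-ray crossing parity.  World = origin + index * spacing
// (zero-based voxel indices, voxel-centre convention).
// [[Rcpp::export]]
NumericVector cpp_signed_distance_grid(const arma::mat& V, const arma::imat& F,
                                       IntegerVector dim, NumericVector origin,
                                       double spacing, double band,
                                       double exact_band = -1.0) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int nf = (int)F.n_rows;
    const size_t ntot = (size_t)nx * ny * nz;
    if (exact_band < 0 || exact_band > band) exact_band = band;
    std::vector<double> dist(ntot, band);
    auto lin = [&](int i, int j, int k) -> size_t {
        return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
    };
    // pass 1: exact distance within exact_band, splatting per triangle
    for (int t = 0; t < nf; ++t) {
        arma::vec::fixed<3> a = vrow(V, F(t, 0) - 1), b = vrow(V, F(t, 1) - 1),
                            c = vrow(V, F(t, 2) - 1);
        const double eb = exact_band;
        int i0 = std::max(0, (int)std::floor((std::min({a[0], b[0], c[0]}) - eb - origin[0]) / spacing));
        int i1 = std::min(nx - 1, (int)std::ceil((std::max({a[0], b[0], c[0]}) + eb - origin[0]) / spacing));
        int j0 = std::max(0, (int)std::floor((std::min({a[1], b[1], c[1]}) - eb - origin[1]) / spacing));
        int j1 = std::min(ny - 1, (int)std::ceil((std::max({a[1], b[1], c[1]}) + eb - origin[1]) / spacing));
        int k0 = std::max(0, (int)std::floor((std::min({a[2], b[2], c[2]}) - eb - origin[2]) / spacing));
        int k1 = std::min(nz - 1, (int)std::ceil((std::max({a[2], b[2], c[2]}) + eb - origin[2]) / spacing));
        for (int k = k0; k <= k1; ++k)
            for (int j = j0; j <= j1; ++j)
                for (int i = i0; i <= i1; ++i) {
                    arma::vec::fixed<3> q;
                    q[0] = origin[0] + i * spacing;
                    q[1] = origin[1] + j * spacing;
                    q[2] = origin[2] + k * spacing;
                    arma::vec::fixed<3> p = closest_point_triangle(q, a, b, c);
                    double d = arma::norm(q - p);
                    size_t l = lin(i, j, k);
                    if (d < dist[l]) dist[l] = d;
                }
    }
    // pass 1b: chamfer propagation of the narrowband distances out to the
    // full band (two sweeps over the 26-neighbourhood)
    if (exact_band < band) {
        const double w1 = spacing, w2 = spacing * std::sqrt(2.0),
                     w3 = spacing * std::sqrt(3.0);
        auto sweep = [&](bool forward) {
            int kb = forward ? 0 : nz - 1, ke = forward ? nz : -1, ks = forward ? 1 : -1;
            for (int k = kb; k != ke; k += ks)
                for (int j = forward ? 0 : ny - 1; forward ? j < ny : j >= 0; j += ks)
                    for (int i = forward ? 0 : nx - 1; forward ? i < nx : i >= 0; i += ks) {
                        double best = dist[lin(i, j, k)];
                        for (int dk = -1; dk <= 1; ++dk)
                            for (int dj = -1; dj <= 1; ++dj)
                                for (int di = -1; di <= 1; ++di) {
                                    if (di == 0 && dj == 0 && dk == 0) continue;
                                    // only neighbours already visited this sweep
                                    int order = dk * ks * 9 + dj * ks * 3 + di * ks;
                                    if (order >= 0) continue;
                                    int ii = i + di, jj = j + dj, kk = k + dk;
                                    if (ii < 0 || jj < 0 || kk < 0 ||
                                        ii >= nx || jj >= ny || kk >= nz) continue;
                                    int m = std::abs(di) + std::abs(dj) + std::abs(dk);
                                    double w = m == 1 ? w1 : (m == 2 ? w2 : w3);
                                    double cand = dist[lin(ii, jj, kk)] + w;
                                    if (cand < best) best = cand;
                                }
                        if (best < dist[lin(i, j, k)]) dist[lin(i, j, k)] = best;
                    }
        };
        // seed: voxels outside the exact band start at +band (already set),
        // narrowband voxels carry exact values
        sweep(true);
        sweep(false);
        for (size_t l = 0; l < ntot; ++l)
            if (dist[l] > band) dist[l] = band;
    }
    // pass 2: inside/outside by ray parity along +x; triangles binned on (y,z)
    std::vector<std::vector<int>> bins((size_t)ny * nz);
    for (int t = 0; t < nf; ++t) {
        double ylo = std::min({V(F(t, 0) - 1, 1), V(F(t, 1) - 1, 1), V(F(t, 2) - 1, 1)});
        double yhi = std::max({V(F(t, 0) - 1, 1), V(F(t, 1) - 1, 1), V(F(t, 2) - 1, 1)});
        double zlo = std::min({V(F(t, 0) - 1, 2), V(F(t, 1) - 1, 2), V(F(t, 2) - 1, 2)});
        double zhi = std::max({V(F(t, 0) - 1, 2), V(F(t, 1) - 1, 2), V(F(t, 2) - 1, 2)});
        int j0 = std::max(0, (int)std::floor((ylo - origin[1]) / spacing) - 1);
        int j1 = std::min(ny - 1, (int)std::ceil((yhi - origin[1]) / spacing) + 1);
        int k0 = std::max(0, (int)std::floor((zlo - origin[2]) / spacing) - 1);
        int k1 = std::min(nz - 1, (int)std::ceil((zhi - origin[2]) / spacing) + 1);
        for (int k = k0; k <= k1; ++k)
            for (int j = j0; j <= j1; ++j)
                bins[(size_t)j + (size_t)ny * k].push_back(t);
    }
    // deterministic sub-voxel jitter avoids rays through vertices/edges
    const double ey = 0.137731 * spacing * 1e-3, ez = 0.271828 * spacing * 1e-3;
    NumericVector out(ntot);
    std::vector<double> xs;
    for (int k = 0; k < nz; ++k) {
        double rz = origin[2] + k * spacing + ez;
        for (int j = 0; j < ny; ++j) {
            double ry = origin[1] + j * spacing + ey;
            xs.clear();
            for (int t : bins[(size_t)j + (size_t)ny * k]) {
                arma::vec::fixed<3> a = vrow(V, F(t, 0) - 1), b = vrow(V, F(t, 1) - 1),
                                    c = vrow(V, F(t, 2) - 1);
                double d1y = b[1] - a[1], d1z = b[2] - a[2];
                double d2y = c[1] - a[1], d2z = c[2] - a[2];
                double den = d1y * d2z - d2y * d1z;
                if (std::abs(den) < 1e-14) continue;  // edge-on in (y,z)
                double py = ry - a[1], pz = rz - a[2];
                double u = (py * d2z - d2y * pz) / den;
                double v = (d1y * pz - py * d1z) / den;
                if (u < 0 || v < 0 || u + v > 1) continue;
                xs.push_back(a[0] + u * (b[0] - a[0]) + v * (c[0] - a[0]));
            }
            std::sort(xs.begin(), xs.end());
            for (int i = 0; i < nx; ++i) {
                double x = origin[0] + i * spacing;
                size_t ncross = xs.size() -
                    (std::upper_bound(xs.begin(), xs.end(), x) - xs.begin());
                bool inside = (ncross % 2) == 1;
                size_t l = lin(i, j, k);
                out[l] = inside ? -dist[l] : dist[l];
            }
        }
    }
    out.attr("dim") = dim;
    return out;
}
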