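// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "nn_grid.h"
using namespace Rcpp;

// Locally affine deformation (LAD) refinement.  V0: pre-aligned template
// vertices; cloud: target points.  Each iteration pairs every vertex with
// its nearest cloud point (pairs beyond trim_factor x median distance are
// dropped), fits a rigid transform over each vertex's distance-d
// neighbourhood, and moves each vertex to the proximity-weighted average of
// its images under the neighbourhood transforms (truncated Gaussian weights,
// sigma = d/2).  Neighbourhoods are recomputed in the current configuration.
// [[Rcpp::export]]
List cpp_lad_fit(const arma::mat& V0, const arma::mat& cloud, double d,
                 int iters, double trim_factor, double tol) {
    const int n = (int)V0.n_rows;
    if (cloud.n_rows == 0) stop("empty cloud");
    arma::mat V = V0;
    PointGrid cgrid(cloud);
    const double sig2 = (d / 2.0) * (d / 2.0);
    int fallback_total = 0, used_iters = 0;
    std::vector<double> obj;
    // best-objective snapshot: the blended update is not a strict descent
    // step, so the iteration can drift after convergence; the fit keeps and
    // returns the best pairing objective seen
    arma::mat bestV = V0;
    double best_obj = std::numeric_limits<double>::infinity();
    int since_best = 0;
    arma::mat targets(n, 3);
    arma::vec dists(n);
    std::vector<char> keep(n);
    std::vector<arma::mat33> Rk(n);
    std::vector<arma::vec3> tk(n);
    std::vector<char> valid(n);
    std::vector<std::vector<int>> nbr(n);

    for (int it = 0; it < iters; ++it) {
        used_iters = it + 1;
        // (a) pair with nearest cloud point
        for (int i = 0; i < n; ++i) {
            arma::vec::fixed<3> q = V.row(i).t();
            double d2;
            int j = cgrid.nearest(q, d2);
            targets.row(i) = cloud.row(j);
            dists[i] = std::sqrt(d2);
        }
        double cur = arma::mean(dists);
        obj.push_back(cur);
        if (cur < best_obj - 1e-9) {
            best_obj = cur;
            bestV = V;
            since_best = 0;
        } else if (++since_best >= 8) {
            break;  // converged: no objective improvement for 8 iterations
        }
        double med = arma::median(dists);
        double cutoff = (med > 0) ? trim_factor * med
                                  : std::numeric_limits<double>::infinity();
        for (int i = 0; i < n; ++i) keep[i] = dists[i] <= cutoff;
        // (b) neighbourhoods in the current configuration
        PointGrid vgrid(V, d);
        for (int k = 0; k < n; ++k) {
            arma::vec::fixed<3> q = V.row(k).t();
            vgrid.radius(q, d, nbr[k]);
        }
        // per-vertex rigid fits over kept neighbour pairs (accumulated
        // in one pass; no per-vertex matrix allocations)
        int fell = 0;
        for (int k = 0; k < n; ++k) {
            valid[k] = 0;
            int cnt = 0;
            arma::vec3 sv = arma::zeros(3), sy = arma::zeros(3);
            arma::mat33 M = arma::zeros(3, 3);
            for (int j : nbr[k]) {
                if (!keep[j]) continue;
                ++cnt;
                const double vx = V(j, 0), vy = V(j, 1), vz = V(j, 2);
                const double yx = targets(j, 0), yy = targets(j, 1), yz = targets(j, 2);
                sv[0] += vx; sv[1] += vy; sv[2] += vz;
                sy[0] += yx; sy[1] += yy; sy[2] += yz;
                M(0, 0) += vx * yx; M(0, 1) += vx * yy; M(0, 2) += vx * yz;
                M(1, 0) += vy * yx; M(1, 1) += vy * yy; M(1, 2) += vy * yz;
                M(2, 0) += vz * yx; M(2, 1) += vz * yy; M(2, 2) += vz * yz;
            }
            if (cnt >= 3) {
                arma::mat33 H = M - sv * sy.t() / (double)cnt;
                arma::mat U, W;
                arma::vec s;
                if (arma::svd(U, s, W, H)) {
                    arma::mat33 D = arma::eye(3, 3);
                    D(2, 2) = arma::det(W * U.t()) < 0 ? -1.0 : 1.0;
                    Rk[k] = W * D * U.t();
                    tk[k] = sy / cnt - Rk[k] * (sv / cnt);
                    valid[k] = 1;
                }
            }
        }
        // fallback: nearest valid vertex's transform
        for (int k = 0; k < n; ++k) {
            if (valid[k]) continue;
            ++fell;
            double best = std::numeric_limits<double>::infinity();
            int pick = -1;
            for (int j : nbr[k]) {
                if (!valid[j]) continue;
                double d2 = arma::dot(V.row(j) - V.row(k), V.row(j) - V.row(k));
                if (d2 < best) { best = d2; pick = j; }
            }
            if (pick < 0)
                for (int j = 0; j < n; ++j) {
                    if (!valid[j]) continue;
                    double d2 = arma::dot(V.row(j) - V.row(k), V.row(j) - V.row(k));
                    if (d2 < best) { best = d2; pick = j; }
                }
            if (pick < 0) stop("no valid local transform anywhere on the mesh");
            Rk[k] = Rk[pick];
            tk[k] = tk[pick];
        }
        fallback_total += fell;
        // (c) proximity-weighted blend of neighbour transforms
        arma::mat Vnew(n, 3);
        for (int k = 0; k < n; ++k) {
            const double vx = V(k, 0), vy = V(k, 1), vz = V(k, 2);
            double ax = 0, ay = 0, az = 0, wsum = 0;
            for (int j : nbr[k]) {
                const double dx = V(j, 0) - vx, dy = V(j, 1) - vy, dz = V(j, 2) - vz;
                const double w = std::exp(-(dx * dx + dy * dy + dz * dz) / sig2);
                const arma::mat33& R = Rk[j];
                const arma::vec3& t = tk[j];
                ax += w * (R(0, 0) * vx + R(0, 1) * vy + R(0, 2) * vz + t[0]);
                ay += w * (R(1, 0) * vx + R(1, 1) * vy + R(1, 2) * vz + t[1]);
                az += w * (R(2, 0) * vx + R(2, 1) * vy + R(2, 2) * vz + t[2]);
                wsum += w;
            }
            Vnew(k, 0) = ax / wsum;
            Vnew(k, 1) = ay / wsum;
            Vnew(k, 2) = az / wsum;
        }
        double step = arma::mean(arma::sqrt(arma::sum(arma::square(Vnew - V), 1)));
        V = Vnew;
        if (step < tol) break;
    }
    // score the final iterate too
    {
        double acc = 0;
        for (int i = 0; i < n; ++i) {
            arma::vec::fixed<3> q = V.row(i).t();
            double d2;
            cgrid.nearest(q, d2);
            acc += std::sqrt(d2);
        }
        if (acc / n < best_obj) bestV = V;
    }
    return List::create(_["vertices"] = bestV, _["iterations"] = used_iters,
                        _["fallbacks"] = fallback_total,
                        _["mean_pair_distance"] = NumericVector(obj.begin(), obj.end()));
}
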