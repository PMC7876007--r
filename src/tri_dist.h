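#pragma once
#include <RcppArmadillo.h>

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, sec. 5.1.5).  Returns the closest point; bary (optional) gets
// the barycentric coordinates (w_a, w_b, w_c).
inline arma::vec::fixed<3> closest_point_triangle(const arma::vec::fixed<3>& p,
                                                  const arma::vec::fixed<3>& a,
                                                  const arma::vec::fixed<3>& b,
                                                  const arma::vec::fixed<3>& c,
                                                  double* bary = nullptr) {
    arma::vec::fixed<3> ab = b - a, ac = c - a, ap = p - a;
    double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) {
        if (bary) { bary[0] = 1; bary[1] = 0; bary[2] = 0; }
        return a;
    }
    arma::vec::fixed<3> bp = p - b;
    double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {
        if (bary) { bary[0] = 0; bary[1] = 1; bary[2] = 0; }
        return b;
    }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        if (bary) { bary[0] = 1 - v; bary[1] = v; bary[2] = 0; }
        return a + v * ab;
    }
    arma::vec::fixed<3> cp = p - c;
    double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) {
        if (bary) { bary[0] = 0; bary[1] = 0; bary[2] = 1; }
        return c;
    }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        if (bary) { bary[0] = 1 - w; bary[1] = 0; bary[2] = w; }
        return a + w * ac;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        if (bary) { bary[0] = 0; bary[1] = 1 - w; bary[2] = w; }
        return b + w * (c - b);
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    if (bary) { bary[0] = 1 - v - w; bary[1] = v; bary[2] = w; }
    return a + ab * v + ac * w;
}
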