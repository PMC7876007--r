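// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double bilinear(const arma::mat& img, double x, double y) {
    const int n0 = (int)img.n_rows, n1 = (int)img.n_cols;
    if (x < 0 || y < 0 || x > n0 - 1 || y > n1 - 1) return 0.0;
    int i = (int)std::floor(x), j = (int)std::floor(y);
    if (i >= n0 - 1) i = n0 - 2;
    if (j >= n1 - 1) j = n1 - 2;
    if (i < 0) i = 0;
    if (j < 0) j = 0;
    double fx = x - i, fy = y - j;
    return img(i, j) * (1 - fx) * (1 - fy) + img(i + 1, j) * fx * (1 - fy) +
           img(i, j + 1) * (1 - fx) * fy + img(i + 1, j + 1) * fx * fy;
}

// Parallel-beam Radon transform of a square image.  Rows of the result are
// detector bins (pitch = pixel spacing / oversample, centred), columns are
// angles (radians).  Line integrals are in intensity x mm; the integration
// step equals the detector pitch.
// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& angles,
                    double spacing, int oversample = 1) {
    const int n = (int)img.n_rows;
    if ((int)img.n_cols != n) stop("slice must be square");
    const int nd = (2 * (int)std::floor(n * std::sqrt(2.0) / 2.0) + 3) * oversample;
    const double step = 1.0 / oversample;
    const double c = (n - 1) / 2.0, uc = (nd - 1) / 2.0;
    arma::mat sino(nd, angles.n_elem, arma::fill::zeros);
    for (arma::uword a = 0; a < angles.n_elem; ++a) {
        double co = std::cos(angles[a]), si = std::sin(angles[a]);
        for (int ui = 0; ui < nd; ++ui) {
            double u = (ui - uc) * step, acc = 0.0;
            for (int ti = 0; ti < nd; ++ti) {
                double t = (ti - uc) * step;
                acc += bilinear(img, c + u * co - t * si, c + u * si + t * co);
            }
            sino(ui, a) = acc * spacing * step;
        }
    }
    return sino;
}

// Backprojection of a (ramp-filtered) sinogram onto an n x n grid,
// scaled by pi / n_angles.  bins_per_pixel is the detector oversampling
// (detector pitch = pixel spacing / bins_per_pixel).
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fsino, const arma::vec& angles,
                          int n, double bins_per_pixel = 1.0) {
    const int nd = (int)fsino.n_rows;
    const double c = (n - 1) / 2.0, uc = (nd - 1) / 2.0;
    arma::mat out(n, n, arma::fill::zeros);
    for (arma::uword a = 0; a < angles.n_elem; ++a) {
        double co = std::cos(angles[a]), si = std::sin(angles[a]);
        for (int j = 0; j < n; ++j) {
            double y = j - c;
            for (int i = 0; i < n; ++i) {
                double x = i - c;
                double u = (x * co + y * si) * bins_per_pixel + uc;
                if (u < 0 || u > nd - 1) continue;
                int u0 = (int)std::floor(u);
                if (u0 >= nd - 1) u0 = nd - 2;
                double fu = u - u0;
                out(i, j) += fsino(u0, a) * (1 - fu) + fsino(u0 + 1, a) * fu;
            }
        }
    }
    return out * (M_PI / (double)angles.n_elem);
}
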