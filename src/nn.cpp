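// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "nn_grid.h"
using namespace Rcpp;

//' @name cpp_nn
//' @noRd
// [[Rcpp::export]]
List cpp_nn(const arma::mat& points, const arma::mat& queries) {
    if (points.n_rows == 0) stop("empty point set");
    PointGrid grid(points);
    const int m = (int)queries.n_rows;
    IntegerVector idx(m);
    NumericVector dist(m);
    for (int i = 0; i < m; ++i) {
        arma::vec::fixed<3> q;
        q[0] = queries(i, 0); q[1] = queries(i, 1); q[2] = queries(i, 2);
        double d2;
        int j = grid.nearest(q, d2);
        idx[i] = j + 1;  // 1-based for R
        dist[i] = std::sqrt(d2);
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}
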