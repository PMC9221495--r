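#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Dynamic time warping by the standard O(n*m) recurrence
//   D(i,j) = cost(x_i, y_j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))
// with D(0,0) = 0 as virtual start, boundary-anchored at (n,m).
// window < 0 disables the Sakoe-Chiba band |i-j| <= window.
// [[Rcpp::export]]
double dtw_dp(NumericVector x, NumericVector y, bool squared, int window) {
    const int n = x.size(), m = y.size();
    const double INF = R_PosInf;
    std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
    prev[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        std::fill(cur.begin(), cur.end(), INF);
        int jlo = 1, jhi = m;
        if (window >= 0) {
            jlo = std::max(1, i - window);
            jhi = std::min(m, i + window);
        }
        for (int j = jlo; j <= jhi; ++j) {
            double d = x[i - 1] - y[j - 1];
            double c = squared ? d * d : std::fabs(d);
            double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
            cur[j] = c + best;
        }
        std::swap(prev, cur);
    }
    return prev[m];
}
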