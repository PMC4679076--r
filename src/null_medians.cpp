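#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of the first k elements of buf (buf is scratch, reordered)
static double median_k(std::vector<double>& buf, int k) {
    int mid = k / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + k);
    double hi = buf[mid];
    if (k % 2 == 1) return hi;
    double lo = *std::max_element(buf.begin(), buf.begin() + mid);
    return (lo + hi) / 2.0;
}

// B medians of subsets of size k sampled uniformly without replacement
// from values, using R's RNG (partial Fisher-Yates); reproducible under
// set.seed().
// [[Rcpp::export]]
NumericVector null_pp_medians(NumericVector values, int k, int B) {
    int n = values.size();
    if (k < 1 || k > n) stop("k must be in [1, length(values)]");
    if (B < 1) stop("B must be >= 1");
    std::vector<double> pool(values.begin(), values.end());
    std::vector<double> buf(k);
    NumericVector out(B);
    for (int b = 0; b < B; ++b) {
        for (int i = 0; i < k; ++i) {
            int j = i + (int)(unif_rand() * (n - i));
            if (j >= n) j = n - 1;  // guard against unif_rand() == 1.0
            std::swap(pool[i], pool[j]);
            buf[i] = pool[i];
        }
        out[b] = median_k(buf, k);
    }
    return out;
}
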