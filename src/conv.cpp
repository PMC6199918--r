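#include <Rcpp.h>
using namespace Rcpp;

// Causal FIR convolution along time (columns), applied independently to each
// trial (row), with implicit zero padding in front:
//   out(i, t) = sum_{k=0}^{K-1} taps[k] * x(i, t - k),  x(i, s) = 0 for s < 0.
// Output has the same length as the input, and out(., t) depends only on
// x(., s <= t). Column-major layout makes the inner trial loop contiguous.
// [[Rcpp::export]]
NumericMatrix conv_causal_mat(const NumericMatrix& x, const NumericVector& taps) {
    const int n = x.nrow(), T = x.ncol(), K = taps.size();
    if (K > T) stop("kernel length (%d) exceeds trial length (%d)", K, T);
    NumericMatrix out(n, T);
    const double* xp = x.begin();
    const double* w = taps.begin();
    double* op = out.begin();
    for (int t = 0; t < T; ++t) {
        const int kmax = std::min(K - 1, t);
        double* ot = op + (size_t)t * n;
        for (int k = 0; k <= kmax; ++k) {
            const double wk = w[k];
            if (wk == 0.0) continue;
            const double* xs = xp + (size_t)(t - k) * n;
            for (int i = 0; i < n; ++i) ot[i] += wk * xs[i];
        }
    }
    return out;
}

// Adjoint of conv_causal_mat with respect to its input:
//   dx(i, t) = sum_{k=0}^{K-1} taps[k] * g(i, t + k)   (anti-causal correlation)
// [[Rcpp::export]]
NumericMatrix conv_causal_adj(const NumericMatrix& g, const NumericVector& taps) {
    const int n = g.nrow(), T = g.ncol(), K = taps.size();
    NumericMatrix out(n, T);
    const double* gp = g.begin();
    const double* w = taps.begin();
    double* op = out.begin();
    for (int t = 0; t < T; ++t) {
        const int kmax = std::min(K - 1, T - 1 - t);
        double* ot = op + (size_t)t * n;
        for (int k = 0; k <= kmax; ++k) {
            const double wk = w[k];
            if (wk == 0.0) continue;
            const double* gs = gp + (size_t)(t + k) * n;
            for (int i = 0; i < n; ++i) ot[i] += wk * gs[i];
        }
    }
    return out;
}

// Gradient of sum_{i,t} g(i,t) * conv(x, taps)(i,t) with respect to the taps:
//   dtaps[k] = sum_{i, t >= k} x(i, t - k) * g(i, t)
// [[Rcpp::export]]
NumericVector conv_tap_grad(const NumericMatrix& x, const NumericMatrix& g, int K) {
    const int n = x.nrow(), T = x.ncol();
    NumericVector out(K);
    const double* xp = x.begin();
    const double* gp = g.begin();
    for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int t = k; t < T; ++t) {
            const double* xs = xp + (size_t)(t - k) * n;
            const double* gs = gp + (size_t)t * n;
            for (int i = 0; i < n; ++i) acc += xs[i] * gs[i];
        }
        out[k] = acc;
    }
    return out;
}
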