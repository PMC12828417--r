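#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Online SOM training loop. All randomness (initial weights, presentation
// orders) is generated in R and passed in, so the loop itself is fully
// deterministic. Weight update for the presented sample x:
//   w_i <- w_i + eta(t) * h(BMU, i, t) * (x - w_i)
// with a Gaussian neighborhood h over the lattice distance between neuron i
// and the best matching unit, truncated at 3 sigma for speed.
//
// X:      n x J data matrix (standardized)
// W:      m x J initial weights (modified in place on a copy)
// gr, gc: length-m lattice row/column of each neuron (0-based)
// orders: E x n matrix of 0-based presentation orders, one row per epoch
// etas, radii: length-E learning rate and neighborhood radius schedules
// rows, cols: lattice dimensions; toroidal: wrap lattice distances
// [[Rcpp::export]]
List esom_train_cpp(NumericMatrix X, NumericMatrix W_init,
                    IntegerVector gr, IntegerVector gc,
                    IntegerMatrix orders,
                    NumericVector etas, NumericVector radii,
                    int rows, int cols, bool toroidal) {
  const int n = X.nrow(), J = X.ncol(), m = W_init.nrow();
  const int E = orders.nrow();
  NumericMatrix W = clone(W_init);

  for (int e = 0; e < E; ++e) {
    const double eta = etas[e];
    const double sigma = radii[e];
    const double cutoff2 = 9.0 * sigma * sigma; // 3-sigma truncation
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int t = 0; t < n; ++t) {
      const int idx = orders(e, t);
      // best matching unit (ties -> lowest neuron index)
      int bmu = 0;
      double best = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        double d2 = 0.0;
        for (int j = 0; j < J; ++j) {
          const double diff = X(idx, j) - W(i, j);
          d2 += diff * diff;
        }
        if (d2 < best) { best = d2; bmu = i; }
      }
      const int br = gr[bmu], bc = gc[bmu];
      for (int i = 0; i < m; ++i) {
        double dr = std::abs(gr[i] - br);
        double dc = std::abs(gc[i] - bc);
        if (toroidal) {
          if (dr > rows - dr) dr = rows - dr;
          if (dc > cols - dc) dc = cols - dc;
        }
        const double ld2 = dr * dr + dc * dc;
        if (ld2 > cutoff2) continue;
        const double h = eta * std::exp(-ld2 * inv2s2);
        for (int j = 0; j < J; ++j) {
          W(i, j) += h * (X(idx, j) - W(i, j));
        }
      }
    }
  }

  // final BMU assignment
  IntegerVector bmu_out(n);
  for (int t = 0; t < n; ++t) {
    int bmu = 0;
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < m; ++i) {
      double d2 = 0.0;
      for (int j = 0; j < J; ++j) {
        const double diff = X(t, j) - W(i, j);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bmu = i; }
    }
    bmu_out[t] = bmu + 1; // 1-based for R
  }
  return List::create(_["weights"] = W, _["bmu"] = bmu_out);
}
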