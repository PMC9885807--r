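#include <Rcpp.h>
using namespace Rcpp;

// Stochastic gradient descent for a linear SVM (hinge loss + L2 penalty).
//
// Documents arrive as the CSC slots of the transposed document-term matrix
// (features x docs), so each document's nonzero features are a contiguous
// slice. The L2 decay w <- (1 - eta*alpha) w is applied lazily through a
// scalar scale factor; the intercept is not regularized. The learning rate
// follows the Bottou "optimal" schedule eta_t = 1 / (alpha * (t0 + t)) with
// t0 chosen from the typical weight scale. Sample visit orders are drawn in
// R (seeded) and passed in as a 0-based epochs x n matrix, keeping all
// randomness under the caller's seed.
//
// [[Rcpp::export]]
List sgd_hinge_fit(IntegerVector xp, IntegerVector xi, NumericVector xx,
                   NumericVector y, int n_features,
                   double alpha, IntegerMatrix orders) {
  const int n = xp.size() - 1;
  std::vector<double> w(n_features, 0.0);
  double b = 0.0, scale = 1.0;

  const double typw = std::sqrt(1.0 / std::sqrt(alpha));
  const double eta0 = typw;               // hinge dloss at -typw is 1
  const double t0 = 1.0 / (eta0 * alpha);
  double t = 0.0;

  const int epochs = orders.nrow();
  for (int e = 0; e < epochs; ++e) {
    for (int k = 0; k < n; ++k) {
      const int d = orders(e, k);
      const double eta = 1.0 / (alpha * (t0 + t));
      t += 1.0;
      double margin = b;
      for (int j = xp[d]; j < xp[d + 1]; ++j)
        margin += scale * w[xi[j]] * xx[j];
      // L2 decay via the scale trick
      scale *= (1.0 - eta * alpha);
      if (scale < 1e-9) {   // renormalize to keep precision
        for (int f = 0; f < n_features; ++f) w[f] *= scale;
        scale = 1.0;
      }
      if (y[d] * margin < 1.0) {
        const double step = eta * y[d] / scale;
        for (int j = xp[d]; j < xp[d + 1]; ++j)
          w[xi[j]] += step * xx[j];
        b += eta * y[d];
      }
    }
  }
  NumericVector wout(n_features);
  for (int f = 0; f < n_features; ++f) wout[f] = scale * w[f];
  return List::create(_["weights"] = wout, _["bias"] = b);
}

// Margins w.x + b for documents in the same CSC-of-transpose layout.
// [[Rcpp::export]]
NumericVector linear_margins(IntegerVector xp, IntegerVector xi,
                             NumericVector xx, NumericVector w, double b) {
  const int n = xp.size() - 1;
  NumericVector out(n);
  for (int d = 0; d < n; ++d) {
    double m = b;
    for (int j = xp[d]; j < xp[d + 1]; ++j) m += w[xi[j]] * xx[j];
    out[d] = m;
  }
  return out;
}
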