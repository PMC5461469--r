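#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Online backpropagation for a one-hidden-layer sigmoid network with two
// sigmoid output units (one-hot targets), squared-error loss, per-instance
// weights and momentum. Instances are visited in row order each epoch, so
// training is fully deterministic given the initial weights.
//
// X: n x p standardized features; y: 0/1 class; w: instance weights.
// W1: h x p, b1: h, W2: 2 x h, b2: 2 (modified copies are returned).
// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                   NumericMatrix W1_, NumericVector b1_,
                   NumericMatrix W2_, NumericVector b2_,
                   double lr, double momentum, int epochs) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix W1(clone(W1_)), W2(clone(W2_));
  NumericVector b1(clone(b1_)), b2(clone(b2_));
  int h = W1.nrow();
  if (W2.ncol() != h || W2.nrow() != 2 || b1.size() != h || b2.size() != 2)
    stop("inconsistent network dimensions");

  std::vector<double> dW1(h * p, 0.0), db1(h, 0.0);
  std::vector<double> dW2(2 * h, 0.0), db2(2, 0.0);
  std::vector<double> hid(h), out(2), dout(2), dhid(h);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n; ++i) {
      // forward
      for (int j = 0; j < h; ++j) {
        double a = b1[j];
        for (int k = 0; k < p; ++k) a += W1(j, k) * X(i, k);
        hid[j] = sigmoid(a);
      }
      for (int c = 0; c < 2; ++c) {
        double a = b2[c];
        for (int j = 0; j < h; ++j) a += W2(c, j) * hid[j];
        out[c] = sigmoid(a);
      }
      // backward (targets one-hot; gradient scaled by the instance weight)
      double wi = w[i];
      for (int c = 0; c < 2; ++c) {
        double t = (y[i] == c) ? 1.0 : 0.0;
        dout[c] = (t - out[c]) * out[c] * (1.0 - out[c]) * wi;
      }
      for (int j = 0; j < h; ++j) {
        double s = 0.0;
        for (int c = 0; c < 2; ++c) s += W2(c, j) * dout[c];
        dhid[j] = hid[j] * (1.0 - hid[j]) * s;
      }
      // updates with momentum
      for (int c = 0; c < 2; ++c) {
        for (int j = 0; j < h; ++j) {
          double d = lr * dout[c] * hid[j] + momentum * dW2[c * h + j];
          W2(c, j) += d;
          dW2[c * h + j] = d;
        }
        double db = lr * dout[c] + momentum * db2[c];
        b2[c] += db;
        db2[c] = db;
      }
      for (int j = 0; j < h; ++j) {
        for (int k = 0; k < p; ++k) {
          double d = lr * dhid[j] * X(i, k) + momentum * dW1[j * p + k];
          W1(j, k) += d;
          dW1[j * p + k] = d;
        }
        double db = lr * dhid[j] + momentum * db1[j];
        b1[j] += db;
        db1[j] = db;
      }
    }
  }
  return List::create(_["W1"] = W1, _["b1"] = b1,
                      _["W2"] = W2, _["b2"] = b2);
}
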