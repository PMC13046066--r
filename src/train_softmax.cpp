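#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Softmax forward pass for one sample: z_i = W[i,0]*x1 + W[i,2]*x2 + b_i,
// w_hat = softmax(z) with max-subtraction for overflow safety.
static inline void forward_one(const double* W, const double* b, int K,
                               double x1, double x2, double* what) {
  double zmax = -1e300;
  for (int i = 0; i < K; ++i) {
    double z = W[i] * x1 + W[i + K] * x2 + b[i];
    what[i] = z;
    if (z > zmax) zmax = z;
  }
  double s = 0.0;
  for (int i = 0; i < K; ++i) {
    what[i] = std::exp(what[i] - zmax);
    s += what[i];
  }
  for (int i = 0; i < K; ++i) what[i] /= s;
}

// Mini-batch Adam training of the single-layer softmax network under the
// MSE loss (mean over samples and output channels). W is stored
// column-major K x 2 as in R. perms holds one 1-based sample permutation
// per epoch (n x epochs); the last incomplete mini-batch is used.
// Returns the trained parameters and per-epoch full-pass MSE/MAE on the
// training set and (optionally) a validation set.
// [[Rcpp::export]]
List train_softmax_adam_cpp(NumericMatrix X, NumericMatrix Y,
                            NumericMatrix W0, NumericVector b0,
                            IntegerMatrix perms,
                            double lr, int batch_size,
                            double beta1, double beta2, double eps,
                            Nullable<NumericMatrix> Xval_,
                            Nullable<NumericMatrix> Yval_) {
  const int n = X.nrow();
  const int K = W0.nrow();
  const int epochs = perms.ncol();
  if (Y.ncol() != K) stop("target column count does not match K");
  if (perms.nrow() != n) stop("permutation matrix must have n rows");

  std::vector<double> W(W0.begin(), W0.end());      // K x 2, column-major
  std::vector<double> b(b0.begin(), b0.end());
  const int P = 3 * K;
  std::vector<double> m(P, 0.0), v(P, 0.0), grad(P, 0.0);
  std::vector<double> what(K), dz(K);

  bool has_val = Xval_.isNotNull();
  NumericMatrix Xval, Yval;
  if (has_val) { Xval = Xval_.get(); Yval = Yval_.get(); }

  NumericMatrix history(epochs, 4);  // train_mse, train_mae, val_mse, val_mae
  long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int start = 0; start < n; start += batch_size) {
      int bsz = std::min(batch_size, n - start);
      std::fill(grad.begin(), grad.end(), 0.0);
      double scale = 2.0 / (static_cast<double>(K) * bsz);
      for (int s = 0; s < bsz; ++s) {
        int j = perms(start + s, ep) - 1;
        double x1 = X(j, 0), x2 = X(j, 1);
        forward_one(W.data(), b.data(), K, x1, x2, what.data());
        // dL/dz_i = what_i * (g_i - sum_k g_k what_k), g = 2 (what - y) / (K B)
        double gdot = 0.0;
        for (int i = 0; i < K; ++i) {
          dz[i] = scale * (what[i] - Y(j, i));
          gdot += dz[i] * what[i];
        }
        for (int i = 0; i < K; ++i) {
          double d = what[i] * (dz[i] - gdot);
          grad[i] += d * x1;        // dW[, 1]
          grad[i + K] += d * x2;    // dW[, 2]
          grad[i + 2 * K] += d;     // db
        }
      }
      ++t;
      double c1 = 1.0 - std::pow(beta1, static_cast<double>(t));
      double c2 = 1.0 - std::pow(beta2, static_cast<double>(t));
      for (int p = 0; p < P; ++p) {
        m[p] = beta1 * m[p] + (1.0 - beta1) * grad[p];
        v[p] = beta2 * v[p] + (1.0 - beta2) * grad[p] * grad[p];
        double update = lr * (m[p] / c1) / (std::sqrt(v[p] / c2) + eps);
        if (p < 2 * K) W[p] -= update; else b[p - 2 * K] -= update;
      }
    }

    // full-pass monitoring metrics
    double mse = 0.0, mae = 0.0;
    for (int j = 0; j < n; ++j) {
      forward_one(W.data(), b.data(), K, X(j, 0), X(j, 1), what.data());
      for (int i = 0; i < K; ++i) {
        double r = what[i] - Y(j, i);
        mse += r * r;
        mae += std::fabs(r);
      }
    }
    history(ep, 0) = mse / (static_cast<double>(n) * K);
    history(ep, 1) = mae / (static_cast<double>(n) * K);
    if (!std::isfinite(history(ep, 0))) {
      stop("non-finite training loss at epoch %d", ep + 1);
    }
    if (has_val) {
      int nv = Xval.nrow();
      double vmse = 0.0, vmae = 0.0;
      for (int j = 0; j < nv; ++j) {
        forward_one(W.data(), b.data(), K, Xval(j, 0), Xval(j, 1), what.data());
        for (int i = 0; i < K; ++i) {
          double r = what[i] - Yval(j, i);
          vmse += r * r;
          vmae += std::fabs(r);
        }
      }
      history(ep, 2) = vmse / (static_cast<double>(nv) * K);
      history(ep, 3) = vmae / (static_cast<double>(nv) * K);
    } else {
      history(ep, 2) = NA_REAL;
      history(ep, 3) = NA_REAL;
    }
  }

  NumericMatrix Wout(K, 2);
  std::copy(W.begin(), W.end(), Wout.begin());
  NumericVector bout(b.begin(), b.end());
  return List::create(_["W"] = Wout, _["b"] = bout, _["history"] = history);
}
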