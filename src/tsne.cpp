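// Gradient-descent inner loop of the t-SNE embedding: momentum + adaptive
// gains + early exaggeration, exactly the original optimizer.  The
// similarity matrices (P, S, Q) and the KL divergence have reference R
// implementations; only the O(N^2)-per-iteration descent lives here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_tsne_descent(NumericMatrix S_r, NumericMatrix y0, int n_iter,
                      double lr, double momentum, double exaggeration,
                      int exag_iters, int momentum_switch) {
  const arma::mat S(S_r.begin(), S_r.nrow(), S_r.ncol());
  arma::mat y(y0.begin(), y0.nrow(), y0.ncol());
  const arma::uword n = y.n_rows, d = y.n_cols;

  arma::mat inc(n, d, arma::fill::zeros);
  arma::mat gains(n, d, arma::fill::ones);
  arma::mat W(n, n, arma::fill::zeros), grad(n, d);

  std::vector<double> trace_kl;
  std::vector<int> trace_it;

  for (int it = 1; it <= n_iter; ++it) {
    const double exag = (it <= exag_iters) ? exaggeration : 1.0;

    double sumW = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      W(i, i) = 0.0;
      for (arma::uword j = i + 1; j < n; ++j) {
        double d2 = 0.0;
        for (arma::uword k = 0; k < d; ++k) {
          double diff = y(i, k) - y(j, k);
          d2 += diff * diff;
        }
        double w = 1.0 / (1.0 + d2);
        W(i, j) = w;
        W(j, i) = w;
        sumW += 2.0 * w;
      }
    }

    grad.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      for (arma::uword j = i + 1; j < n; ++j) {
        double w = W(i, j);
        double coef = 4.0 * (exag * S(i, j) - w / sumW) * w;
        for (arma::uword k = 0; k < d; ++k) {
          double g = coef * (y(i, k) - y(j, k));
          grad(i, k) += g;
          grad(j, k) -= g;
        }
      }
    }

    const double mom = (it < momentum_switch) ? momentum
                                              : std::max(momentum, 0.8);
    for (arma::uword e = 0; e < n * d; ++e) {
      double g = grad(e);
      gains(e) = ((g > 0.0) != (inc(e) > 0.0)) ? gains(e) + 0.2
                                               : gains(e) * 0.8;
      if (gains(e) < 0.01) gains(e) = 0.01;
      inc(e) = mom * inc(e) - lr * gains(e) * g;
      y(e) += inc(e);
    }
    for (arma::uword k = 0; k < d; ++k) {
      double m = arma::mean(y.col(k));
      y.col(k) -= m;
    }

    if (it % 50 == 0 || it == n_iter) {
      // KL against the unexaggerated similarities
      double sw = 0.0;
      for (arma::uword i = 0; i < n; ++i)
        for (arma::uword j = i + 1; j < n; ++j) {
          double d2 = 0.0;
          for (arma::uword k = 0; k < d; ++k) {
            double diff = y(i, k) - y(j, k);
            d2 += diff * diff;
          }
          sw += 2.0 / (1.0 + d2);
        }
      double kl = 0.0;
      for (arma::uword i = 0; i < n; ++i)
        for (arma::uword j = 0; j < n; ++j) {
          if (i == j || S(i, j) <= 0.0) continue;
          double d2 = 0.0;
          for (arma::uword k = 0; k < d; ++k) {
            double diff = y(i, k) - y(j, k);
            d2 += diff * diff;
          }
          double q = std::max(1.0 / (1.0 + d2) / sw, 1e-12);
          kl += S(i, j) * std::log(S(i, j) / q);
        }
      if (!std::isfinite(kl))
        stop("t-SNE diverged (non-finite KL) at iteration %d", it);
      trace_kl.push_back(kl);
      trace_it.push_back(it);
    }
  }

  return List::create(_["coords"] = wrap(y),
                      _["kl_trace"] = wrap(trace_kl),
                      _["trace_iter"] = wrap(trace_it));
}
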