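// Feedforward MLP (ReLU hidden layers, softmax output, inverted dropout,
// Adam or SGD, exponential learning-rate decay).  Full-batch training in
// single precision: the data sets this classifier targets are tiny (tens to
// low hundreds of rows), so one epoch equals one optimizer step, and float32
// matches the precision deep-learning frameworks train in.  All randomness
// (weight init, dropout masks) is drawn from R's RNG so that a set.seed()
// in the calling R code makes fits bit-reproducible.  Elementwise steps are
// fused in-place loops; matrix products go through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __SSE2__
#include <xmmintrin.h>
#endif

using namespace Rcpp;

// Saturated classifiers drive gradients and Adam moments into the float32
// subnormal range, where x86 arithmetic stalls badly; flush-to-zero /
// denormals-are-zero (the deep-learning-runtime default) avoids that.
// Restored on scope exit so the calling R session is unaffected.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040u); }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

static arma::fmat as_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i)
      out(i, j) = static_cast<float>(x(i, j));
  return out;
}

static NumericMatrix as_rmat(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  for (arma::uword j = 0; j < x.n_cols; ++j)
    for (arma::uword i = 0; i < x.n_rows; ++i)
      out(i, j) = x(i, j);
  return out;
}

// Glorot-uniform initial weights for layer sizes
// [input, hidden..., n_classes]; biases start at zero.
// [[Rcpp::export(rng = true)]]
List cpp_mlp_init(IntegerVector layer_sizes) {
  int L = layer_sizes.size() - 1;
  List W(L), b(L);
  for (int l = 0; l < L; ++l) {
    int fan_in = layer_sizes[l], fan_out = layer_sizes[l + 1];
    double limit = std::sqrt(6.0 / (fan_in + fan_out));
    NumericMatrix w(fan_in, fan_out);
    for (int j = 0; j < fan_out; ++j)
      for (int i = 0; i < fan_in; ++i)
        w(i, j) = (2.0 * unif_rand() - 1.0) * limit;
    W[l] = w;
    b[l] = NumericVector(fan_out);
  }
  return List::create(_["W"] = W, _["b"] = b);
}

struct Net {
  std::vector<arma::fmat> W;
  std::vector<arma::frowvec> b;
};

static Net net_from_r(List W_r, List b_r) {
  Net net;
  int L = W_r.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as_fmat(W_r[l]));
    NumericVector bv = b_r[l];
    arma::frowvec b(bv.size());
    for (int i = 0; i < bv.size(); ++i) b(i) = bv[i];
    net.b.push_back(b);
  }
  return net;
}

static void softmax_rows_inplace(arma::fmat& z) {
  for (arma::uword i = 0; i < z.n_rows; ++i) {
    float mx = z(i, 0);
    for (arma::uword j = 1; j < z.n_cols; ++j) mx = std::max(mx, z(i, j));
    float s = 0.0f;
    for (arma::uword j = 0; j < z.n_cols; ++j) {
      z(i, j) = std::exp(z(i, j) - mx);
      s += z(i, j);
    }
    for (arma::uword j = 0; j < z.n_cols; ++j) z(i, j) /= s;
  }
}

// Forward pass without dropout (inference mode).
static arma::fmat forward(const Net& net, const arma::fmat& X) {
  arma::fmat a = X;
  int L = net.W.size();
  for (int l = 0; l < L; ++l) {
    arma::fmat z = a * net.W[l];
    z.each_row() += net.b[l];
    if (l < L - 1) {
      float* p = z.memptr();
      for (arma::uword k = 0; k < z.n_elem; ++k) p[k] = std::max(0.0f, p[k]);
    }
    a = std::move(z);
  }
  softmax_rows_inplace(a);
  return a;
}

// Adam (or plain SGD) update, fused single pass over the parameter array.
static void update_param(float* w, float* m, float* v, const float* g,
                         arma::uword n, bool adam, float lr,
                         float bc1, float bc2) {
  const float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  if (adam) {
    for (arma::uword k = 0; k < n; ++k) {
      m[k] = beta1 * m[k] + (1.0f - beta1) * g[k];
      v[k] = beta2 * v[k] + (1.0f - beta2) * g[k] * g[k];
      w[k] -= lr * (m[k] / bc1) / (std::sqrt(v[k] / bc2) + eps);
    }
  } else {
    for (arma::uword k = 0; k < n; ++k) w[k] -= lr * g[k];
  }
}

// [[Rcpp::export(rng = true)]]
List cpp_mlp_train(List W_r, List b_r, NumericMatrix X_r, IntegerVector y,
                   int n_classes, double dropout, double lr0,
                   double decay_rate, int decay_steps, int epochs,
                   bool adam) {
  FlushDenormals ftz;
  Net net = net_from_r(W_r, b_r);
  const int L = net.W.size();
  const arma::fmat X = as_fmat(X_r);
  const arma::uword n = X.n_rows;
  const float keep = 1.0f - static_cast<float>(dropout);
  const float inv_keep = 1.0f / keep;
  const bool use_dropout = dropout > 0.0;

  std::vector<arma::fmat> mW(L), vW(L);
  std::vector<arma::frowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(net.W[l])); vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(arma::size(net.b[l])); vb[l].zeros(arma::size(net.b[l]));
  }

  NumericVector hist_loss(epochs), hist_acc(epochs);
  std::vector<arma::fmat> act(L + 1), mask(L);

  for (int t = 0; t < epochs; ++t) {
    // one full-batch optimizer step per epoch
    float lr = static_cast<float>(
        lr0 * std::pow(decay_rate, std::min(t, decay_steps)));
    float bc1 = 1.0f - std::pow(0.9f, static_cast<float>(t + 1));
    float bc2 = 1.0f - std::pow(0.999f, static_cast<float>(t + 1));

    act[0] = X;
    for (int l = 0; l < L; ++l) {
      arma::fmat z = act[l] * net.W[l];
      z.each_row() += net.b[l];
      if (l < L - 1) {
        float* p = z.memptr();
        if (use_dropout) {
          // fused ReLU + inverted dropout; mask stores the applied factor
          mask[l].set_size(arma::size(z));
          float* mk = mask[l].memptr();
          for (arma::uword k = 0; k < z.n_elem; ++k) {
            float f = (p[k] > 0.0f) ? ((unif_rand() < dropout) ? 0.0f : inv_keep)
                                    : 0.0f;
            mk[k] = f;
            p[k] *= f;
          }
        } else {
          mask[l].set_size(arma::size(z));
          float* mk = mask[l].memptr();
          for (arma::uword k = 0; k < z.n_elem; ++k) {
            mk[k] = (p[k] > 0.0f) ? 1.0f : 0.0f;
            p[k] = std::max(0.0f, p[k]);
          }
        }
      }
      act[l + 1] = std::move(z);
    }
    softmax_rows_inplace(act[L]);
    const arma::fmat& probs = act[L];

    double loss = 0.0;
    arma::uword correct = 0;
    for (arma::uword i = 0; i < n; ++i) {
      float py = std::max(probs(i, y[i]), 1e-12f);
      loss -= std::log(static_cast<double>(py));
      arma::uword best = 0;
      for (int c = 1; c < n_classes; ++c)
        if (probs(i, c) > probs(i, best)) best = c;
      if (best == static_cast<arma::uword>(y[i])) ++correct;
    }
    loss /= n;
    if (!std::isfinite(loss))
      stop("non-finite training loss at epoch %d", t + 1);
    hist_loss[t] = loss;
    hist_acc[t] = static_cast<double>(correct) / n;

    // backward (delta starts as dLoss/dlogits)
    arma::fmat delta = probs;
    for (arma::uword i = 0; i < n; ++i) delta(i, y[i]) -= 1.0f;
    delta /= static_cast<float>(n);
    for (int l = L - 1; l >= 0; --l) {
      arma::fmat gW = act[l].t() * delta;
      arma::frowvec gb = arma::sum(delta, 0);
      if (l > 0) {
        arma::fmat nd = delta * net.W[l].t();
        // mask already encodes both the ReLU derivative and dropout scaling
        nd %= mask[l - 1];
        delta = std::move(nd);
      }
      update_param(net.W[l].memptr(), mW[l].memptr(), vW[l].memptr(),
                   gW.memptr(), gW.n_elem, adam, lr, bc1, bc2);
      update_param(net.b[l].memptr(), mb[l].memptr(), vb[l].memptr(),
                   gb.memptr(), gb.n_elem, adam, lr, bc1, bc2);
    }
  }

  List W_out(L), b_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = as_rmat(net.W[l]);
    NumericVector bv(net.b[l].n_elem);
    for (arma::uword i = 0; i < net.b[l].n_elem; ++i) bv[i] = net.b[l](i);
    b_out[l] = bv;
  }
  return List::create(_["W"] = W_out, _["b"] = b_out,
                      _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}

// [[Rcpp::export]]
NumericMatrix cpp_mlp_predict(List W_r, List b_r, NumericMatrix X_r) {
  Net net = net_from_r(W_r, b_r);
  return as_rmat(forward(net, as_fmat(X_r)));
}
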