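// Minimal feed-forward classifier used as the reward environment.
// Architecture: input -> hidden layers (ReLU) -> softmax output.
// Trained from scratch on every call with mini-batch Adam; this is the
// per-episode retraining at the core of the wrapper selection loop, so it
// lives in C++.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::mat;
using arma::rowvec;
using arma::uvec;

namespace {

struct AdamState {
  mat mW, vW;
  rowvec mb, vb;
};

// Row-wise softmax with max-subtraction for stability.
mat softmax_rows(const mat &z) {
  mat shifted = z.each_col() - arma::max(z, 1);
  mat e = arma::exp(shifted);
  return e.each_col() / arma::sum(e, 1);
}

} // namespace

// Train the network on (Xtr, ytr) and return test-set predictions on Xte.
// ytr holds 0-based class codes; n_classes fixes the output width. All
// randomness (weight init, batch shuffling) comes from `seed` only, so a
// fixed seed gives a bit-identical fit independent of R's RNG state.
// [[Rcpp::export]]
Rcpp::IntegerVector mlp_fit_predict_cpp(const arma::mat &Xtr,
                                        const arma::ivec &ytr,
                                        const arma::mat &Xte,
                                        int n_classes,
                                        const arma::ivec &hidden,
                                        double lr,
                                        int epochs,
                                        int batch_size,
                                        int seed) {
  const arma::uword n = Xtr.n_rows, d = Xtr.n_cols;
  const int C = n_classes;

  std::vector<arma::uword> dims;
  dims.push_back(d);
  for (arma::uword l = 0; l < hidden.n_elem; ++l)
    dims.push_back(static_cast<arma::uword>(hidden[l]));
  dims.push_back(static_cast<arma::uword>(C));
  const size_t L = dims.size() - 1; // number of weight layers

  std::mt19937 gen(static_cast<unsigned int>(seed));

  // Glorot-uniform weights. Hidden biases start slightly positive: with
  // very narrow layers (2 units) a zero-bias ReLU init can leave the whole
  // layer inactive for every sample, freezing the net at the majority
  // class; 0.1 is the standard guard against dead units. Output bias 0.
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    double r = std::sqrt(6.0 / (dims[l] + dims[l + 1]));
    std::uniform_real_distribution<double> unif(-r, r);
    W[l].set_size(dims[l], dims[l + 1]);
    for (arma::uword j = 0; j < W[l].n_cols; ++j)
      for (arma::uword i = 0; i < W[l].n_rows; ++i)
        W[l](i, j) = unif(gen);
    b[l] = rowvec(dims[l + 1],
                  (l + 1 < L) ? arma::fill::value(0.1) : arma::fill::value(0.0));
  }

  std::vector<AdamState> adam(L);
  for (size_t l = 0; l < L; ++l) {
    adam[l].mW = mat(dims[l], dims[l + 1], arma::fill::zeros);
    adam[l].vW = mat(dims[l], dims[l + 1], arma::fill::zeros);
    adam[l].mb = rowvec(dims[l + 1], arma::fill::zeros);
    adam[l].vb = rowvec(dims[l + 1], arma::fill::zeros);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;

  // One-hot targets.
  mat Y(n, C, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) Y(i, ytr[i]) = 1.0;

  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  const arma::uword bs = std::max<arma::uword>(
      1, std::min<arma::uword>(static_cast<arma::uword>(batch_size), n));

  std::vector<mat> A(L + 1), Z(L);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    for (arma::uword start = 0; start < n; start += bs) {
      arma::uword stop = std::min(start + bs, n);
      uvec idx(stop - start);
      for (arma::uword i = start; i < stop; ++i) idx[i - start] = order[i];
      const double nb = static_cast<double>(idx.n_elem);

      // Forward pass.
      A[0] = Xtr.rows(idx);
      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l + 1 < L) ? arma::clamp(Z[l], 0.0, arma::datum::inf)
                               : softmax_rows(Z[l]);
      }

      // Backward pass: softmax + cross-entropy gives (P - Y)/nb at the top.
      mat delta = (A[L] - Y.rows(idx)) / nb;
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, step);
      const double bc2 = 1.0 - std::pow(beta2, step);
      for (size_t l = L; l-- > 0;) {
        mat dW = A[l].t() * delta;
        rowvec db = arma::sum(delta, 0);
        if (l > 0)
          delta = (delta * W[l].t()) % arma::conv_to<mat>::from(Z[l - 1] > 0.0);

        adam[l].mW = beta1 * adam[l].mW + (1.0 - beta1) * dW;
        adam[l].vW = beta2 * adam[l].vW + (1.0 - beta2) * arma::square(dW);
        adam[l].mb = beta1 * adam[l].mb + (1.0 - beta1) * db;
        adam[l].vb = beta2 * adam[l].vb + (1.0 - beta2) * arma::square(db);
        W[l] -= lr * (adam[l].mW / bc1) /
                (arma::sqrt(adam[l].vW / bc2) + eps);
        b[l] -= lr * (adam[l].mb / bc1) /
                (arma::sqrt(adam[l].vb / bc2) + eps);
      }
    }
  }

  // Predict.
  mat H = Xte;
  for (size_t l = 0; l < L; ++l) {
    mat Zl = H * W[l];
    Zl.each_row() += b[l];
    H = (l + 1 < L) ? arma::clamp(Zl, 0.0, arma::datum::inf) : Zl;
  }
  arma::uvec pred = arma::index_max(H, 1);
  Rcpp::IntegerVector out(pred.n_elem);
  for (arma::uword i = 0; i < pred.n_elem; ++i)
    out[i] = static_cast<int>(pred[i]);
  return out;
}
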