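// Minibatch Adam training of a shallow tanh autoencoder
//   n -> width (tanh) -> k (linear code) -> width (tanh) -> n (linear)
// on the mean squared reconstruction error. All randomness (initial weights,
// batch order) is supplied by the caller so training is fully deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct AdamState {
  mat m, v;
  explicit AdamState(const mat& w) : m(size(w), fill::zeros), v(size(w), fill::zeros) {}
};

inline void adam_update(mat& w, const mat& g, AdamState& s, double lr,
                        double b1, double b2, double eps, double t) {
  s.m = b1 * s.m + (1.0 - b1) * g;
  s.v = b2 * s.v + (1.0 - b2) * square(g);
  const mat mhat = s.m / (1.0 - std::pow(b1, t));
  const mat vhat = s.v / (1.0 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

} // namespace

// X: n x N data (columns = cells). init: list of W1,b1,W2,b2,W3,b3,W4,b4.
// batch_order: N x epochs matrix of 1-based column indices (one shuffled
// permutation per epoch). Returns trained weights, per-epoch mean minibatch
// loss, the full-data reconstruction Y and code C.
// [[Rcpp::export(name = ".ae_train_cpp")]]
Rcpp::List ae_train_cpp(const arma::mat& X, Rcpp::List init,
                        const arma::imat& batch_order, int batch_size,
                        double lr) {
  const uword n = X.n_rows, N = X.n_cols;
  const int epochs = batch_order.n_cols;
  if (batch_order.n_rows != N) Rcpp::stop("batch_order rows must equal N");
  if (!X.is_finite()) Rcpp::stop("non-finite input");

  mat W1 = Rcpp::as<mat>(init["W1"]); vec b1 = Rcpp::as<vec>(init["b1"]);
  mat W2 = Rcpp::as<mat>(init["W2"]); vec b2 = Rcpp::as<vec>(init["b2"]);
  mat W3 = Rcpp::as<mat>(init["W3"]); vec b3 = Rcpp::as<vec>(init["b3"]);
  mat W4 = Rcpp::as<mat>(init["W4"]); vec b4 = Rcpp::as<vec>(init["b4"]);

  AdamState sW1(W1), sW2(W2), sW3(W3), sW4(W4);
  AdamState sb1(b1), sb2(b2), sb3(b3), sb4(b4);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  vec epoch_loss(epochs, fill::zeros);
  double step = 0.0;

  for (int e = 0; e < epochs; ++e) {
    double acc = 0.0;
    int nb = 0;
    for (uword start = 0; start < N; start += batch_size) {
      const uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec idx(stop - start + 1);
      for (uword i = 0; i < idx.n_elem; ++i)
        idx(i) = static_cast<uword>(batch_order(start + i, e)) - 1;
      const mat Xb = X.cols(idx);
      const double b = static_cast<double>(Xb.n_cols);

      // forward
      const mat H1 = tanh(W1 * Xb + repmat(b1, 1, Xb.n_cols));
      const mat C  = W2 * H1 + repmat(b2, 1, Xb.n_cols);
      const mat H2 = tanh(W3 * C + repmat(b3, 1, Xb.n_cols));
      const mat Y  = W4 * H2 + repmat(b4, 1, Xb.n_cols);

      const mat R = Y - Xb;
      const double loss = accu(square(R)) / (b * n);
      if (!std::isfinite(loss)) Rcpp::stop("divergent training: non-finite loss");
      acc += loss; ++nb;

      // backward (d loss / d Y = 2R / (b*n))
      const mat dY  = (2.0 / (b * n)) * R;
      const mat gW4 = dY * H2.t();
      const vec gb4 = sum(dY, 1);
      const mat dH2 = (W4.t() * dY) % (1.0 - square(H2));
      const mat gW3 = dH2 * C.t();
      const vec gb3 = sum(dH2, 1);
      const mat dC  = W3.t() * dH2;
      const mat gW2 = dC * H1.t();
      const vec gb2 = sum(dC, 1);
      const mat dH1 = (W2.t() * dC) % (1.0 - square(H1));
      const mat gW1 = dH1 * Xb.t();
      const vec gb1 = sum(dH1, 1);

      step += 1.0;
      adam_update(W1, gW1, sW1, lr, beta1, beta2, eps, step);
      adam_update(b1, gb1, sb1, lr, beta1, beta2, eps, step);
      adam_update(W2, gW2, sW2, lr, beta1, beta2, eps, step);
      adam_update(b2, gb2, sb2, lr, beta1, beta2, eps, step);
      adam_update(W3, gW3, sW3, lr, beta1, beta2, eps, step);
      adam_update(b3, gb3, sb3, lr, beta1, beta2, eps, step);
      adam_update(W4, gW4, sW4, lr, beta1, beta2, eps, step);
      adam_update(b4, gb4, sb4, lr, beta1, beta2, eps, step);
    }
    epoch_loss(e) = acc / nb;
  }

  // full-data forward pass with the trained weights
  const mat H1 = tanh(W1 * X + repmat(b1, 1, N));
  const mat C  = W2 * H1 + repmat(b2, 1, N);
  const mat H2 = tanh(W3 * C + repmat(b3, 1, N));
  const mat Y  = W4 * H2 + repmat(b4, 1, N);

  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
    Rcpp::Named("W3") = W3, Rcpp::Named("b3") = b3,
    Rcpp::Named("W4") = W4, Rcpp::Named("b4") = b4,
    Rcpp::Named("epoch_loss") = epoch_loss,
    Rcpp::Named("Y") = Y, Rcpp::Named("code") = C);
}
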