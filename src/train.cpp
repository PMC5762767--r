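// Per-instance SGD inner loops for the denoising autoencoder and the
// BP-MLL network. All randomness (epoch shuffles, corruption masks) is
// drawn in R and passed in, so these loops are deterministic and can be
// compared entry-for-entry against the R reference step functions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigmoid_v(const arma::vec& t) {
  return 1.0 / (1.0 + arma::exp(-t));
}
static inline arma::mat sigmoid_m(const arma::mat& t) {
  return 1.0 / (1.0 + arma::exp(-t));
}

// Mean reconstruction loss over all rows of X, clean inputs (no corruption).
static double dae_mean_loss(const arma::mat& X, const arma::mat& W,
                            const arma::vec& b, const arma::vec& bp,
                            const int loss_kind) {
  const double eps = 1e-12;
  // Y: m x dprime, Z: m x d
  arma::mat Y = sigmoid_m(X * W.t() + arma::repmat(b.t(), X.n_rows, 1));
  arma::mat Z = sigmoid_m(Y * W + arma::repmat(bp.t(), X.n_rows, 1));
  double total = 0.0;
  if (loss_kind == 0) {            // squared error
    total = arma::accu(arma::square(X - Z));
  } else {                         // cross-entropy
    arma::mat Zc = arma::clamp(Z, eps, 1.0 - eps);
    total = -arma::accu(X % arma::log(Zc) + (1.0 - X) % arma::log(1.0 - Zc));
  }
  return total / X.n_rows;
}

// [[Rcpp::export]]
List dae_train_cpp(const arma::mat& X, arma::mat W, arma::vec b, arma::vec bp,
                   const IntegerMatrix& orders, const IntegerMatrix& masks,
                   const double lr, const int loss_kind, const int epochs) {
  const int m = X.n_rows;
  const int ncorrupt = masks.nrow();
  arma::vec trace(epochs);
  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < m; ++t) {
      const int i = orders(t, e) - 1;
      arma::vec x = X.row(i).t();
      arma::vec xt = x;
      if (ncorrupt > 0) {
        const int col = e * m + t;
        for (int j = 0; j < ncorrupt; ++j) xt(masks(j, col) - 1) = 0.0;
      }
      arma::vec y = sigmoid_v(W * xt + b);
      arma::vec u = W.t() * y + bp;
      arma::vec z = sigmoid_v(u);
      arma::vec du;                          // dL/d(pre-activation of z)
      if (loss_kind == 0) {
        du = 2.0 * (z - x) % z % (1.0 - z);
      } else {
        du = z - x;                          // cross-entropy + sigmoid
      }
      arma::vec da = (W * du) % y % (1.0 - y);
      W -= lr * (da * xt.t() + y * du.t()); // tied: encoder + decoder parts
      b -= lr * da;
      bp -= lr * du;
      if (!W.is_finite()) {
        stop("non-finite parameters during DAE training (learning_rate = %f)",
             lr);
      }
    }
    trace(e) = dae_mean_loss(X, W, b, bp, loss_kind);
    if (!std::isfinite(trace(e))) {
      stop("non-finite reconstruction loss during DAE training "
           "(learning_rate = %f)", lr);
    }
  }
  return List::create(_["W"] = W, _["b"] = b, _["b_prime"] = bp,
                      _["trace"] = trace);
}

// d_j and e_s of the pairwise exponential error, via the factorisation
// sum_{l in Ybar} exp(-(c_j - c_l)) = exp(-c_j) * sum_{l in Ybar} exp(c_l).
static void bpmll_deltas(const arma::vec& c, const arma::vec& bvec,
                         const arma::uvec& rel, const arma::uvec& irr,
                         const arma::mat& W, arma::vec& d, arma::vec& e) {
  const double z = 1.0 / (double)(rel.n_elem * irr.n_elem);
  const double s_irr = arma::accu(arma::exp(c.elem(irr)));
  const double s_rel = arma::accu(arma::exp(-c.elem(rel)));
  d.zeros(c.n_elem);
  for (arma::uword a = 0; a < rel.n_elem; ++a) {
    const arma::uword j = rel(a);
    d(j) = z * std::exp(-c(j)) * s_irr * c(j) * (1.0 - c(j));
  }
  for (arma::uword a = 0; a < irr.n_elem; ++a) {
    const arma::uword j = irr(a);
    d(j) = -z * std::exp(c(j)) * s_rel * c(j) * (1.0 - c(j));
  }
  e = (W * d) % bvec % (1.0 - bvec);
}

static double bpmll_global_error_arma(const arma::mat& X, const arma::mat& V,
                                      const arma::mat& W,
                                      const arma::vec& gamma,
                                      const arma::vec& theta,
                                      const List& rel_idx,
                                      const List& irr_idx) {
  const int m = X.n_rows;
  arma::mat B = sigmoid_m(X * V + arma::repmat(gamma.t(), m, 1));
  arma::mat C = sigmoid_m(B * W + arma::repmat(theta.t(), m, 1));
  double E = 0.0;
  for (int i = 0; i < m; ++i) {
    const arma::uvec rel = as<arma::uvec>(rel_idx[i]) - 1;
    const arma::uvec irr = as<arma::uvec>(irr_idx[i]) - 1;
    const arma::rowvec c = C.row(i);
    const double s_irr = arma::accu(arma::exp(c.elem(irr).t()));
    double ei = 0.0;
    for (arma::uword a = 0; a < rel.n_elem; ++a)
      ei += std::exp(-c(rel(a))) * s_irr;
    E += ei / (double)(rel.n_elem * irr.n_elem);
  }
  return E;
}

// [[Rcpp::export]]
List bpmll_train_cpp(const arma::mat& X, arma::mat V, arma::mat W,
                     arma::vec gamma, arma::vec theta,
                     const List& rel_idx, const List& irr_idx,
                     const IntegerMatrix& orders, const double alpha,
                     const int max_epochs, const int patience,
                     const double tol) {
  const int m = X.n_rows;
  std::vector<double> trace;
  double best = R_PosInf;
  int streak = 0;
  arma::vec d, e;
  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int t = 0; t < m; ++t) {
      const int i = orders(t, ep) - 1;
      arma::vec x = X.row(i).t();
      arma::vec bvec = sigmoid_v(V.t() * x + gamma);
      arma::vec c = sigmoid_v(W.t() * bvec + theta);
      const arma::uvec rel = as<arma::uvec>(rel_idx[i]) - 1;
      const arma::uvec irr = as<arma::uvec>(irr_idx[i]) - 1;
      bpmll_deltas(c, bvec, rel, irr, W, d, e);
      W += alpha * (bvec * d.t());
      theta += alpha * d;
      V += alpha * (x * e.t());
      gamma += alpha * e;
    }
    const double E = bpmll_global_error_arma(X, V, W, gamma, theta,
                                             rel_idx, irr_idx);
    if (!std::isfinite(E)) {
      stop("non-finite global error during BP-MLL training (alpha = %f)",
           alpha);
    }
    trace.push_back(E);
    if (E < best - tol) {
      best = E;
      streak = 0;
    } else {
      ++streak;
    }
    if (streak >= patience) break;
  }
  return List::create(_["V"] = V, _["W"] = W, _["gamma"] = gamma,
                      _["theta"] = theta, _["trace"] = wrap(trace));
}
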