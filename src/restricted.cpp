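// Full-batch hinge-loss gradient descent for the restricted parallel-synapse
// neuron. One synchronous update per epoch: all gradients are evaluated at the
// pre-update parameters, summed over the margin-violation set, then applied at
// once; the slope is projected back to s >= 0 afterwards.
//
// form == 0: h = a^2 * logistic(s (x - t))      (sigmoid reporting form)
// form == 1: h = a^2 * tanh(s (x - t))          (zero-centred training form)

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec forward_current(const arma::mat& X, const arma::mat& A,
                                 const arma::mat& S, const arma::mat& T,
                                 int form) {
  const arma::uword N = A.n_rows, M = A.n_cols;
  arma::vec z(X.n_rows, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    arma::vec xi = X.col(i);
    for (arma::uword j = 0; j < M; ++j) {
      arma::vec u = S(i, j) * (xi - T(i, j));
      if (form == 1)
        z += (A(i, j) * A(i, j)) * arma::tanh(u);
      else
        z += (A(i, j) * A(i, j)) / (1.0 + arma::exp(-u));
    }
  }
  return z;
}

// Accumulate the summed hinge gradient over the violation set (rows of XO).
static void accumulate_grads(const arma::mat& XO, const arma::vec& yO,
                             const arma::mat& A, const arma::mat& S,
                             const arma::mat& T, int form,
                             arma::mat& gA, arma::mat& gS, arma::mat& gT) {
  const arma::uword N = A.n_rows, M = A.n_cols;
  for (arma::uword i = 0; i < N; ++i) {
    arma::vec xi = XO.col(i);
    for (arma::uword j = 0; j < M; ++j) {
      const double a = A(i, j), s = S(i, j), t = T(i, j);
      arma::vec d = xi - t;
      arma::vec u = s * d;
      if (form == 1) {
        arma::vec th = arma::tanh(u);
        arma::vec sech2 = 1.0 - arma::square(th);
        gA(i, j) = 2.0 * a * arma::dot(yO, th);
        gS(i, j) = a * a * arma::dot(yO, sech2 % d);
        gT(i, j) = a * a * s * arma::dot(yO, sech2);
      } else {
        arma::vec sig = 1.0 / (1.0 + arma::exp(-u));
        arma::vec h = (a * a) * sig;
        arma::vec one_minus = 1.0 - sig;
        gA(i, j) = 2.0 * a * arma::dot(yO, sig);
        gS(i, j) = arma::dot(yO, one_minus % h % d);
        gT(i, j) = s * arma::dot(yO, one_minus % h);
      }
    }
  }
}

// One draw from the edge-weighted threshold distribution: an equal mixture of
// Beta(b1, b2) and Beta(b2, b1), U-shaped on [0, 1] for b1 < 1 < b2.
static double draw_edge_threshold(double b1, double b2) {
  if (R::unif_rand() < 0.5) return R::rbeta(b1, b2);
  return R::rbeta(b2, b1);
}

// [[Rcpp::export]]
List cpp_train_restricted(const arma::mat& X, const arma::vec& y,
                          arma::mat A, arma::mat S, arma::mat T, double theta,
                          int form, double eps,
                          double eta_a, double eta_s, double eta_t,
                          double eta_theta,
                          int max_epochs, int resurrect_every,
                          double floor_amp, double beta_edge, double beta_mid,
                          int patience, bool normalize, int optimizer,
                          double lr, int lr_patience, double lr_factor,
                          double adam_beta2) {
  const arma::uword P = X.n_rows;
  arma::mat gA(arma::size(A)), gS(arma::size(A)), gT(arma::size(A));
  int epochs = 0, best_errors = P + 1, since_best = 0, n_resurrected = 0;
  bool success = false;
  double loss = 0.0;
  int errors = P;
  // adaptive-moment state (optimizer == 1)
  arma::mat mA(arma::size(A), arma::fill::zeros), vA = mA, mS = mA, vS = mA,
            mT = mA, vT = mA;
  double mth = 0.0, vth = 0.0, tadam = 0.0;
  const double b1 = 0.9, b2 = adam_beta2, adam_eps = 1e-8;

  // cache of per-synapse activations: column k = synapse (i, j), i = k % N
  const arma::uword N = A.n_rows, M = A.n_cols, NM = N * M;
  arma::mat act(P, NM);

  for (int e = 0; e < max_epochs; ++e) {
    arma::vec a2 = arma::vectorise(arma::square(A));
    for (arma::uword j = 0; j < M; ++j)
      for (arma::uword i = 0; i < N; ++i) {
        arma::uword k = j * N + i;
        arma::vec u = S(i, j) * (X.col(i) - T(i, j));
        if (form == 1) act.col(k) = arma::tanh(u);
        else           act.col(k) = 1.0 / (1.0 + arma::exp(-u));
      }
    arma::vec z = act * a2;
    arma::vec margin = (z - theta) % y;
    // sign(0) counts as -1, so z - theta == 0 is an error on a +1 label
    errors = 0;
    for (arma::uword m = 0; m < P; ++m) {
      double pred = (z(m) - theta > 0.0) ? 1.0 : -1.0;
      if (pred != y(m)) ++errors;
    }
    loss = arma::accu(arma::clamp(eps - margin, 0.0, arma::datum::inf));
    if (errors == 0) { success = true; break; }
    if (errors < best_errors) { best_errors = errors; since_best = 0; }
    else {
      ++since_best;
      if (patience > 0 && since_best >= patience) break;
      // reduce-on-plateau schedule for the adaptive optimizer
      if (lr_patience > 0 && since_best % lr_patience == 0) lr *= lr_factor;
    }

    arma::uvec omega = arma::find(eps - margin > 0.0);
    if (omega.n_elem > 0) {
      arma::mat XO = X.rows(omega);
      arma::mat actO = act.rows(omega);
      arma::vec yO = y(omega);
      // per-synapse hinge gradients from the cached activations
      for (arma::uword j = 0; j < M; ++j)
        for (arma::uword i = 0; i < N; ++i) {
          arma::uword k = j * N + i;
          const double a = A(i, j), s = S(i, j), t = T(i, j);
          arma::vec d = XO.col(i) - t;
          if (form == 1) {
            arma::vec th = actO.col(k);
            arma::vec sech2 = 1.0 - arma::square(th);
            gA(i, j) = 2.0 * a * arma::dot(yO, th);
            gS(i, j) = a * a * arma::dot(yO, sech2 % d);
            gT(i, j) = a * a * s * arma::dot(yO, sech2);
          } else {
            arma::vec sig = actO.col(k);
            arma::vec hv = (a * a) * sig;
            arma::vec om = 1.0 - sig;
            gA(i, j) = 2.0 * a * arma::dot(yO, sig);
            gS(i, j) = arma::dot(yO, om % hv % d);
            gT(i, j) = s * arma::dot(yO, om % hv);
          }
        }
      const double gth = arma::accu(yO);
      if (optimizer == 1) {
        // adaptive-moment descent on the same summed hinge gradient
        // (accumulate_grads returns the descent direction, i.e. -dL/dp)
        tadam += 1.0;
        const double c1 = 1.0 - std::pow(b1, tadam),
                     c2 = 1.0 - std::pow(b2, tadam);
        auto step = [&](arma::mat& Par, arma::mat& m, arma::mat& v,
                        const arma::mat& gdesc) {
          m = b1 * m + (1.0 - b1) * gdesc;
          v = b2 * v + (1.0 - b2) * arma::square(gdesc);
          Par += lr * (m / c1) / (arma::sqrt(v / c2) + adam_eps);
        };
        step(A, mA, vA, gA);
        step(S, mS, vS, gS);
        step(T, mT, vT, -gT);
        mth = b1 * mth + (1.0 - b1) * (-gth);
        vth = b2 * vth + (1.0 - b2) * gth * gth;
        theta += lr * (mth / c1) / (std::sqrt(vth / c2) + adam_eps);
      } else {
        // literal explicit update rules; optional violation-set
        // normalization uses the mean instead of the sum, so the effective
        // per-pattern step grows as the violation set shrinks
        const double sc = normalize ? 1.0 / (double)omega.n_elem : 1.0;
        A += (eta_a * sc) * gA;
        S += (eta_s * sc) * gS;
        T -= (eta_t * sc) * gT;
        theta -= (eta_theta * sc) * gth;
      }
      S = arma::clamp(S, 0.0, arma::datum::inf);
    }
    ++epochs;

    if (resurrect_every > 0 && ((e + 1) % resurrect_every == 0)) {
      for (arma::uword k = 0; k < A.n_elem; ++k) {
        if (A(k) * A(k) < floor_amp) {
          A(k) = std::sqrt(floor_amp);
          T(k) = draw_edge_threshold(beta_edge, beta_mid);
          ++n_resurrected;
        }
      }
    }
  }

  return List::create(_["a"] = A, _["s"] = S, _["t"] = T, _["theta"] = theta,
                      _["epochs"] = epochs, _["loss"] = loss,
                      _["errors"] = errors, _["success"] = success,
                      _["n_resurrected"] = n_resurrected);
}

// A single synchronous update (no stopping test, no resurrection); used by
// gradient_step() and the finite-difference validation of the update rules.
// [[Rcpp::export]]
List cpp_gradient_step(const arma::mat& X, const arma::vec& y,
                       const arma::mat& A, const arma::mat& S,
                       const arma::mat& T, double theta, int form, double eps,
                       double eta_a, double eta_s, double eta_t,
                       double eta_theta) {
  arma::vec z = forward_current(X, A, S, T, form);
  arma::vec margin = (z - theta) % y;
  arma::uvec omega = arma::find(eps - margin > 0.0);
  arma::mat A2 = A, S2 = S, T2 = T;
  double theta2 = theta;
  if (omega.n_elem > 0) {
    arma::mat gA(arma::size(A)), gS(arma::size(A)), gT(arma::size(A));
    arma::mat XO = X.rows(omega);
    arma::vec yO = y(omega);
    accumulate_grads(XO, yO, A, S, T, form, gA, gS, gT);
    A2 += eta_a * gA;
    S2 += eta_s * gS;
    T2 -= eta_t * gT;
    theta2 -= eta_theta * arma::accu(yO);
    S2 = arma::clamp(S2, 0.0, arma::datum::inf);
  }
  return List::create(_["a"] = A2, _["s"] = S2, _["t"] = T2,
                      _["theta"] = theta2,
                      _["n_violations"] = (int)omega.n_elem);
}

// [[Rcpp::export]]
arma::vec cpp_total_current(const arma::mat& X, const arma::mat& A,
                            const arma::mat& S, const arma::mat& T, int form) {
  return forward_current(X, A, S, T, form);
}
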