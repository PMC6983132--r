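#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Per-sample loops of the reservoir machinery and the SampEn template count.
// These are the only hot loops in the package; everything else is vectorised R.

// Leaky-integrator reservoir update iterated over a 1-D input series.
// x(t) = (1-alpha) x(t-1) + alpha * tanh(Win [1; u(t)] + W x(t-1))
// Returns the N x T activation matrix (one column per time step).
// [[Rcpp::export]]
arma::mat esn_run_cpp(const arma::mat& W, const arma::mat& Win, double alpha,
                      const arma::vec& u, const arma::vec& x0) {
  const arma::uword N = W.n_rows, T = u.n_elem;
  arma::mat S(N, T);
  arma::vec x = x0;
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec z = Win.col(0) + Win.col(1) * u[t] + W * x;
    x = (1.0 - alpha) * x + alpha * arma::tanh(z);
    S.col(t) = x;
  }
  return S;
}

// Finite-time largest-Lyapunov-exponent estimate: a reference and a
// perturbed trajectory (initial separation gamma0 on neuron 1) are driven
// by the same input; the separation is renormalised to gamma0 after every
// step and the per-step log expansion is averaged over the post-washout
// steps. A collapse to exactly zero separation (e.g. the perturbed neuron
// feeds no other neuron) does not enter the average: the trajectory is
// re-perturbed on the next neuron. If every step collapses the dynamics
// forget a perturbation within one step and -Inf is returned.
// [[Rcpp::export]]
double lyapunov_cpp(const arma::mat& W, const arma::mat& Win, double alpha,
                    const arma::vec& u, int washout, double gamma0) {
  const arma::uword T = u.n_elem;
  const arma::uword N = W.n_rows;
  arma::vec xr(N, arma::fill::zeros);
  for (int t = 0; t < washout && t < (int)T; ++t) {
    arma::vec z = Win.col(0) + Win.col(1) * u[t] + W * xr;
    xr = (1.0 - alpha) * xr + alpha * arma::tanh(z);
  }
  arma::uword pn = 0;
  arma::vec xp = xr;
  xp[pn] += gamma0;
  double acc = 0.0;
  int k = 0;
  for (arma::uword t = washout; t < T; ++t) {
    arma::vec zr = Win.col(0) + Win.col(1) * u[t] + W * xr;
    xr = (1.0 - alpha) * xr + alpha * arma::tanh(zr);
    arma::vec zp = Win.col(0) + Win.col(1) * u[t] + W * xp;
    xp = (1.0 - alpha) * xp + alpha * arma::tanh(zp);
    double gamma = arma::norm(xp - xr, 2);
    if (gamma <= 0.0) {
      pn = (pn + 1) % N;
      xp = xr;
      xp[pn] += gamma0;
    } else {
      acc += std::log(gamma / gamma0);
      xp = xr + (xp - xr) * (gamma0 / gamma);
      ++k;
    }
  }
  if (k == 0) return -std::numeric_limits<double>::infinity();
  return acc / k;
}

// SampEn template counts: A = ordered distinct pairs of (m+1)-length
// templates with Chebyshev distance strictly below r, B = same for
// m-length templates. Both counts run over the N-m templates that can be
// extended, self-matches excluded.
// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts_cpp(const arma::vec& x, int m, double r) {
  const int Nt = (int)x.n_elem - m;  // templates with an (m+1)th sample
  double A = 0.0, B = 0.0;
  for (int i = 0; i < Nt - 1; ++i) {
    for (int j = i + 1; j < Nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::abs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d >= r) break;
      }
      if (d < r) {
        B += 1.0;
        double a = std::abs(x[i + m] - x[j + m]);
        if (a < r && d < r) A += 1.0;
      }
    }
  }
  // ordered distinct pairs: twice the unordered counts
  return Rcpp::NumericVector::create(2.0 * A, 2.0 * B);
}
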