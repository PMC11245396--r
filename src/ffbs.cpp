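// Forward filtering / backward sampling for the discrete syllable chain.
// Messages are normalized at each step (scaled probability space), which is
// equivalent to log-space propagation but avoids T*N*N exp() calls.
// Draws come from R's RNG stream (RNGScope via Rcpp attributes), so results
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int sampleCat(const arma::rowvec& p) {
  double u = unif_rand() * arma::accu(p);
  double c = 0.0;
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    c += p(i);
    if (u <= c) return (int)i;
  }
  return (int)p.n_elem - 1;
}

// loglik: T x N log observation densities; Pi: N x N row-stochastic
// transition matrix; segStart/segEnd: 1-based inclusive recording bounds.
// The initial state of each recording is uniform over 1..N.
// Returns a 1-based state sequence.
// [[Rcpp::export(name = ".ffbsSample")]]
IntegerVector ffbsSample(const arma::mat& loglik, const arma::mat& Pi,
                         const IntegerVector& segStart,
                         const IntegerVector& segEnd) {
  const int T = loglik.n_rows;
  const int N = loglik.n_cols;
  if ((int)Pi.n_rows != N || (int)Pi.n_cols != N)
    stop("transition matrix dimension mismatch");
  arma::mat alpha(T, N);
  IntegerVector z(T);
  for (int s = 0; s < segStart.size(); ++s) {
    const int t0 = segStart[s] - 1, t1 = segEnd[s] - 1;
    if (t0 < 0 || t1 >= T || t1 < t0) stop("invalid segment bounds");
    arma::rowvec a = arma::exp(loglik.row(t0) - loglik.row(t0).max());
    double sa = arma::accu(a);
    if (!(sa > 0) || !a.is_finite())
      stop("invalid likelihood row at frame %d", t0 + 1);
    a /= sa;
    alpha.row(t0) = a;
    for (int t = t0 + 1; t <= t1; ++t) {
      arma::rowvec pred = a * Pi;
      a = pred % arma::exp(loglik.row(t) - loglik.row(t).max());
      sa = arma::accu(a);
      if (!(sa > 0) || !a.is_finite())
        stop("all-zero forward message at frame %d", t + 1);
      a /= sa;
      alpha.row(t) = a;
    }
    int j = sampleCat(alpha.row(t1));
    z[t1] = j + 1;
    for (int t = t1 - 1; t >= t0; --t) {
      arma::rowvec p = alpha.row(t) % Pi.col(j).t();
      j = sampleCat(p);
      z[t] = j + 1;
    }
  }
  return z;
}

// HMM forward algorithm log marginal likelihood, uniform initial state,
// same segment conventions as ffbsSample.
// [[Rcpp::export(name = ".hmmLogMarginal")]]
double hmmLogMarginal(const arma::mat& loglik, const arma::mat& Pi,
                      const IntegerVector& segStart,
                      const IntegerVector& segEnd) {
  const int N = loglik.n_cols;
  double total = 0.0;
  for (int s = 0; s < segStart.size(); ++s) {
    const int t0 = segStart[s] - 1, t1 = segEnd[s] - 1;
    double m = loglik.row(t0).max();
    arma::rowvec a = arma::exp(loglik.row(t0) - m) / (double)N;
    double sa = arma::accu(a);
    total += m + std::log(sa);
    a /= sa;
    for (int t = t0 + 1; t <= t1; ++t) {
      arma::rowvec pred = a * Pi;
      m = loglik.row(t).max();
      a = pred % arma::exp(loglik.row(t) - m);
      sa = arma::accu(a);
      if (!(sa > 0)) return -arma::datum::inf;
      total += m + std::log(sa);
      a /= sa;
    }
  }
  return total;
}
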