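## Elementary samplers used throughout the Gibbs engine. All draw through
## R's RNG stream so that set.seed() makes every fit reproducible.

#' Scaled inverse chi-squared draws
#'
#' Draws from \eqn{\chi^{-2}(\nu, \tau^2)}, the distribution of
#' \eqn{\nu \tau^2 / X} with \eqn{X \sim \chi^2_\nu}. Mean is
#' \eqn{\nu \tau^2 / (\nu - 2)} for \eqn{\nu > 2}. This is the conjugate
#' family for Gaussian variances used by the per-keypoint noise levels and
#' per-frame noise scales.
#'
#' @param n Number of draws.
#' @param nu Degrees of freedom (> 0); scalar or length-n.
#' @param tausq Scale parameter (> 0); scalar or length-n.
#' @return Numeric vector of n positive draws.
#' @export
rinvchisq <- function(n, nu, tausq) {
  nu * tausq / rchisq(n, df = nu)
}

#' Von Mises draws
#'
#' Best-Fisher rejection sampler for the von Mises distribution
#' \eqn{vM(\mu, \kappa)} on the circle. `kappa = 0` gives uniform draws.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians); scalar or length-n.
#' @param kappa Concentration (>= 0); scalar or length-n.
#' @return Angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-10
  out[unif] <- runif(sum(unif), 0, 2 * pi)
  idx <- which(!unif)
  for (i in idx) {
    k <- kappa[i]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    repeat {
      u1 <- runif(1); u2 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c_ <- k * (r - f)
      if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
        u3 <- runif(1)
        out[i] <- mu[i] + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  wrapAngle(out)
}

## log von Mises density (unnormalized-safe: uses log Bessel I0)
dvonmisesLog <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) - logBesselI0(kappa)
}

## log I0(x), stable for large x
logBesselI0 <- function(x) {
  ifelse(x < 700,
         log(besselI(x, 0, expon.scaled = TRUE)) + x,
         x - 0.5 * log(2 * pi * x) + log1p(1 / (8 * x)))
}

#' Dirichlet draws
#' @param n Number of draws.
#' @param alpha Concentration vector (entries > 0).
#' @return n x length(alpha) matrix of probability vectors.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

## Inverse-Wishart draw IW(nu, S): mean S/(nu - p - 1). Sampled as the
## inverse of a Wishart(nu, S^{-1}) draw via the Bartlett decomposition.
rinvwishart <- function(nu, S) {
  p <- nrow(S)
  Sinv <- chol2inv(chol(S))
  Lc <- t(chol(Sinv))             # Sinv = Lc Lc'
  A <- matrix(0, p, p)
  diag(A) <- sqrt(rchisq(p, df = nu - seq_len(p) + 1))
  if (p > 1)
    A[lower.tri(A)] <- rnorm(p * (p - 1) / 2)
  LW <- Lc %*% A                  # W = LW LW' ~ Wishart(nu, Sinv)
  W <- tcrossprod(LW)
  chol2inv(chol(W))
}

## Matrix-normal draw MN(M, U, V): X = M + chol(U)' Z chol(V) with Z iid N(0,1)
## U is row covariance (p x p), V column covariance (q x q).
rmatrixnormal <- function(M, U, V) {
  p <- nrow(M); q <- ncol(M)
  Z <- matrix(rnorm(p * q), p, q)
  cU <- chol(U); cV <- chol(V)
  M + t(cU) %*% Z %*% cV
}

## MNIW draw: Q ~ IW(nu, S); [A|b] ~ MN(M0, Q, K) with K column covariance.
rmniw <- function(nu, S, M0, K) {
  Q <- rinvwishart(nu, S)
  Q <- (Q + t(Q)) / 2
  AB <- rmatrixnormal(M0, Q, K)
  list(AB = AB, Q = Q)
}
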