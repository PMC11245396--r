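## Autoregressive likelihoods, MNIW dynamics updates, and the sticky
## HDP-HMM weak-limit transition update.

## Regressor matrix Phi: row t = (x_{t-L}, ..., x_{t-1}, 1), zero-padded at
## recording starts ("left-padded with zeros for negative time indices").
lagRegressors <- function(x, L, recording) {
  T_ <- nrow(x); M <- ncol(x)
  Phi <- matrix(0, T_, L * M + 1L)
  Phi[, L * M + 1L] <- 1
  ri <- recordingIndex(recording)
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    n <- length(rows)
    for (l in seq_len(L)) {          # lag L - l + 1 goes in block l
      lag <- L - l + 1L
      cols <- ((l - 1L) * M + 1L):(l * M)
      src <- rows[seq_len(max(0L, n - lag))]
      dst <- rows[(lag + 1L):n][seq_len(max(0L, n - lag))]
      if (n > lag) Phi[dst, cols] <- x[src, , drop = FALSE]
    }
  }
  Phi
}

#' Per-state AR log-likelihood table
#'
#' Entry (t, i) is the log density of `x[t, ]` under state i's lag-L vector
#' autoregression, \eqn{\log N(x_t \mid A_i x_{t-L:t-1} + b_i, Q_i)}, with
#' history zero-padded at recording starts. With `maskFirst = TRUE` the
#' first L frames of each recording are instead set to 0 for every state
#' (uniform across states), so they do not inform the state sequence.
#'
#' @param x T x M pose trajectory.
#' @param ar List with `A` (N x M x LM), `b` (N x M), `Q` (N x M x M).
#' @param recording Per-frame recording labels.
#' @param maskFirst Mask the first L frames of each recording.
#' @return T x N matrix of log densities.
#' @export
arLogLikelihoods <- function(x, ar, recording = rep("rec1", nrow(x)),
                             maskFirst = FALSE) {
  T_ <- nrow(x); M <- ncol(x)
  N <- dim(ar$A)[1L]
  L <- dim(ar$A)[3L] / M
  Phi <- lagRegressors(x, L, recording)
  out <- matrix(0, T_, N)
  for (i in seq_len(N)) {
    AB <- cbind(matrix(ar$A[i, , ], nrow = M), ar$b[i, ])
    Qi <- matrix(ar$Q[i, , ], M, M)
    cQ <- tryCatch(chol(Qi), error = function(e)
      stop("Q of state ", i, " is not positive definite"))
    mu <- Phi %*% t(AB)
    resid <- x - mu
    w <- backsolve(cQ, t(resid), transpose = TRUE)   # solves t(cQ) w = resid'
    quad <- colSums(w^2)
    out[, i] <- -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(cQ))) + quad)
  }
  if (maskFirst) {
    ri <- recordingIndex(recording)
    for (r in seq_len(nrow(ri))) {
      rows <- ri$start[r]:min(ri$end[r], ri$start[r] + L - 1L)
      out[rows, ] <- 0
    }
  }
  out
}

#' Resample the syllable sequence
#'
#' Exact joint draw from the conditional of the discrete state sequence
#' given the pose trajectory and all parameters, by forward filtering /
#' backward sampling per recording (uniform initial state at each
#' recording start).
#'
#' @param loglik T x N log-likelihood table (see [arLogLikelihoods()]).
#' @param pi_ N x N row-stochastic transition matrix.
#' @param recording Per-frame recording labels.
#' @return Integer length-T state sequence in 1..N.
#' @export
resampleStates <- function(loglik, pi_, recording = rep("rec1", nrow(loglik))) {
  ri <- recordingIndex(recording)
  .ffbsSample(loglik, pi_, as.integer(ri$start), as.integer(ri$end))
}

## Transition counts n[i, j], never crossing recording boundaries.
transitionCounts <- function(z, N, recording) {
  n <- matrix(0, N, N)
  ri <- recordingIndex(recording)
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    if (length(rows) < 2L) next
    from <- z[rows[-length(rows)]]
    to <- z[rows[-1L]]
    tab <- table(factor(from, levels = seq_len(N)),
                 factor(to, levels = seq_len(N)))
    n <- n + unclass(tab)
  }
  n
}

## Chinese-restaurant table counts: m[i,j] = sum of Bernoulli(a/(a + l - 1)).
crtCounts <- function(n, a) {
  m <- matrix(0L, nrow(n), ncol(n))
  idx <- which(n > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    l <- seq_len(n[i, j])
    m[i, j] <- sum(runif(n[i, j]) < a[i, j] / (a[i, j] + l - 1))
  }
  m
}

#' Resample transition parameters (sticky HDP-HMM, weak limit)
#'
#' Samples the global state weights `beta` and the transition matrix `pi`
#' from their conditional given the state sequence, using the standard
#' auxiliary table-count scheme of the weak-limit sampler: table counts per
#' (i, j) via the Chinese-restaurant construction with concentration
#' \eqn{\alpha\beta_j + \kappa\delta_{ij}}, a binomial correction removing
#' tables attributable to the stickiness override, then
#' \eqn{\beta \sim Dir(\gamma/N + \bar m_{\cdot 1}, \ldots)} and
#' \eqn{\pi_i \sim Dir(\alpha\beta_1 + n_{i1}, \ldots, \alpha\beta_i +
#' \kappa + n_{ii}, \ldots)}.
#'
#' @param z Integer state sequence (1..N).
#' @param hyper Hyperparameter list (uses `N`, `gamma`, `alpha`, `kappa`).
#' @param recording Per-frame recording labels.
#' @param beta Current value of `beta` (used for the table counts).
#' @return List with `beta` and `pi`.
#' @export
resampleTransitions <- function(z, hyper, recording = rep("rec1", length(z)),
                                beta = NULL) {
  N <- hyper$N
  kap <- hyper$kappa
  if (is.na(kap)) stop("kappa is not set; calibrate or supply it")
  if (is.null(beta)) beta <- rep(1 / N, N)
  n <- transitionCounts(z, N, recording)
  a <- hyper$alpha * matrix(beta, N, N, byrow = TRUE) + kap * diag(N)
  m <- crtCounts(n, a)
  ## remove tables due to the stickiness override
  rho <- kap / (hyper$alpha + kap)
  mbar <- m
  if (rho > 0) {
    for (i in seq_len(N)) {
      if (m[i, i] > 0) {
        p <- rho / (rho + beta[i] * (1 - rho))
        mbar[i, i] <- m[i, i] - rbinom(1L, m[i, i], p)
      }
    }
  }
  betaNew <- as.numeric(rdirichlet(1L, hyper$gamma / N + colSums(mbar)))
  piNew <- resamplePi(betaNew, n, hyper)
  list(beta = betaNew, pi = piNew)
}

#' @rdname resampleTransitions
#' @param counts N x N transition count matrix.
#' @export
resamplePi <- function(beta, counts, hyper) {
  N <- hyper$N
  conc <- hyper$alpha * matrix(beta, N, N, byrow = TRUE) +
    hyper$kappa * diag(N) + counts
  t(apply(conc, 1L, function(a) as.numeric(rdirichlet(1L, a))))
}

#' Resample the per-state AR dynamics
#'
#' Conjugate matrix-normal inverse-Wishart posterior draw of
#' \eqn{[A_i | b_i], Q_i} for each state, given the frames currently
#' assigned to it (regressors are the zero-padded lag stacks). States with
#' no assigned frames draw from the MNIW prior.
#'
#' @param x T x M pose trajectory.
#' @param z Integer state sequence.
#' @param hyper Hyperparameter list.
#' @param recording Per-frame recording labels.
#' @return List with `A` (N x M x LM), `b` (N x M), `Q` (N x M x M).
#' @export
resampleARParams <- function(x, z, hyper, recording = rep("rec1", nrow(x))) {
  M <- hyper$M; L <- hyper$L; N <- hyper$N
  Phi <- lagRegressors(x, L, recording)
  K0inv <- chol2inv(chol(hyper$K0))
  M0 <- hyper$M0
  A <- array(0, dim = c(N, M, L * M))
  b <- matrix(0, N, M)
  Q <- array(0, dim = c(N, M, M))
  for (i in seq_len(N)) {
    rows <- which(z == i)
    n <- length(rows)
    if (n == 0L) {
      draw <- rmniw(hyper$nu0, hyper$S0, M0, hyper$K0)
    } else {
      Phii <- Phi[rows, , drop = FALSE]
      Xi <- x[rows, , drop = FALSE]
      Sxx <- K0inv + crossprod(Phii)
      cS <- tryCatch(chol(Sxx), error = function(e) {
        chol(Sxx + diag(1e-8, nrow(Sxx)))   # ridge jitter on near-singular scale
      })
      Kn <- chol2inv(cS)
      Mn <- (M0 %*% K0inv + crossprod(Xi, Phii)) %*% Kn
      Sn <- hyper$S0 + crossprod(Xi) + M0 %*% K0inv %*% t(M0) -
        Mn %*% Sxx %*% t(Mn)
      Sn <- (Sn + t(Sn)) / 2
      ev <- eigen(Sn, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10) Sn <- Sn + diag(1e-8, M)
      draw <- rmniw(hyper$nu0 + n, Sn, Mn, Kn)
    }
    A[i, , ] <- draw$AB[, seq_len(L * M), drop = FALSE]
    b[i, ] <- draw$AB[, L * M + 1L]
    Q[i, , ] <- draw$Q
  }
  list(A = A, b = b, Q = Q)
}
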