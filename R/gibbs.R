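## Gibbs conditionals of the full keypoint model.
##
## Conventions (fixed package-wide):
##  * poses are K x D matrices, one keypoint per row;
##  * vec() over a pose is keypoint-major / dimension-minor, so the
##    observation covariance diag(sigma_k^2 s_tk) (x) I_D consists of D x D
##    identity blocks per keypoint;
##  * world = ego %*% R(h) + v, with R(h) the counterclockwise rotation
##    acting on coordinate rows (see rotationMatrix);
##  * recording boundaries break the syllable Markov chain, the AR process
##    on x (zero-padded history) and the random walk on v.

## Per-keypoint loading blocks. Predicted ego coordinate of keypoint k in
## dimension d is  B[k,d,] . x + dmat[k,d]  where B[k,d,m] = sum_j
## Gamma[k,j] C[(j-1)D+d, m].
keypointLoadings <- function(C, d, Gamma, D) {
  K <- nrow(Gamma); M <- ncol(C)
  B <- array(0, dim = c(K, D, M))
  dmat <- matrix(0, K, D)
  for (dd in seq_len(D)) {
    idx <- seq.int(dd, by = D, length.out = K - 1L)
    B[, dd, ] <- Gamma %*% C[idx, , drop = FALSE]
    dmat[, dd] <- Gamma %*% d[idx]
  }
  list(B = B, dmat = dmat)
}

## Predicted ego poses for all frames: T x K x D.
predictedEgoPose <- function(x, loadings) {
  K <- dim(loadings$B)[1L]; D <- dim(loadings$B)[2L]
  T_ <- nrow(x)
  out <- array(0, dim = c(T_, K, D))
  for (dd in seq_len(D)) {
    Bd <- matrix(loadings$B[, dd, ], nrow = K)      # K x M
    out[, , dd] <- tcrossprod(x, Bd) +
      matrix(loadings$dmat[, dd], T_, K, byrow = TRUE)
  }
  out
}

## Egocentrize all frames of a coordinate array: (Y - v) R(h)^T, vectorized.
egocentrizeAll <- function(Y, v, h) {
  dm <- dim(Y); T_ <- dm[1L]; K <- dm[2L]; D <- dm[3L]
  out <- array(0, dim = dm)
  cx <- Y[, , 1L, drop = TRUE] - v[, 1L]
  cy <- Y[, , 2L, drop = TRUE] - v[, 2L]
  ch <- cos(h); sh <- sin(h)
  out[, , 1L] <- cx * ch + cy * sh
  out[, , 2L] <- -cx * sh + cy * ch
  if (D == 3L) out[, , 3L] <- Y[, , 3L, drop = TRUE] - v[, 3L]
  out
}

## Rotate ego poses into world orientation (no translation): ego R(h).
rotateToWorldAll <- function(E, h) {
  dm <- dim(E); D <- dm[3L]
  out <- array(0, dim = dm)
  ch <- cos(h); sh <- sin(h)
  ex <- E[, , 1L, drop = TRUE]; ey <- E[, , 2L, drop = TRUE]
  out[, , 1L] <- ex * ch - ey * sh
  out[, , 2L] <- ex * sh + ey * ch
  if (D == 3L) out[, , 3L] <- E[, , 3L, drop = TRUE]
  out
}

## Squared residual norms per frame/keypoint between observed ego pose and
## model prediction: T x K.
egoResidualSq <- function(ego, pred) {
  dm <- dim(ego)
  out <- matrix(0, dm[1L], dm[2L])
  for (dd in seq_len(dm[3L]))
    out <- out + (ego[, , dd, drop = TRUE] - pred[, , dd, drop = TRUE])^2
  out
}

#' Resample per-frame noise scales s
#'
#' Conditionally independent scaled-inverse-chi-squared draws
#' \eqn{s_{t,k} \sim \chi^{-2}\!\big(\nu_s + D,\; (\nu_s s_{0,t,k} +
#' \sigma_k^{-2} \|r_{t,k}\|^2)/(\nu_s + D)\big)} where \eqn{r_{t,k}} is the
#' residual between the egocentrized observation and the predicted pose.
#'
#' @param model A [KeypointSLDS-class].
#' @param series The observed [KeypointSeries-class].
#' @return T x K matrix of positive scales.
#' @export
resampleScales <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  D <- nDims(series)
  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  pred <- predictedEgoPose(lt$x, ld)
  ego <- egocentrizeAll(coords(series), lt$v, lt$h)
  sq <- egoResidualSq(ego, pred)
  nu <- hp$nu_s + D
  tau <- sweep(sq, 2L, obs$sigmasq, "/")
  tau <- (hp$nu_s * obs$s0 + tau) / nu
  matrix(rinvchisq(length(tau), nu, as.numeric(tau)), nrow(tau), ncol(tau))
}

#' Resample per-keypoint baseline variances sigma^2
#'
#' Per-keypoint scaled-inverse-chi-squared draw
#' \eqn{\sigma_k^2 \sim \chi^{-2}\!\big(\nu_\sigma + DT,\;
#' (\nu_\sigma \sigma_0^2 + S_y)(\nu_\sigma + DT)^{-1}\big)} with
#' \eqn{S_y = \sum_t \|r_{t,k}\|^2 / s_{t,k}}. With the default
#' \eqn{\nu_\sigma = 10^5} this pins \eqn{\sigma_k^2} near
#' \eqn{\sigma_0^2 = 1} by design.
#'
#' @inheritParams resampleScales
#' @return Length-K vector of variances.
#' @export
resampleSigmasq <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  D <- nDims(series)
  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  pred <- predictedEgoPose(lt$x, ld)
  ego <- egocentrizeAll(coords(series), lt$v, lt$h)
  sq <- egoResidualSq(ego, pred)
  Sy <- colSums(sq / obs$s)
  T_ <- nFrames(series)
  nu <- hp$nu_sigma + D * T_
  rinvchisq(length(Sy), nu, (hp$nu_sigma * hp$sigmasq0 + Sy) / nu)
}

#' Resample headings h
#'
#' Independent per-frame von Mises draws. The conditional is
#' \eqn{p(h_t) \propto \exp(a_t \cos h_t + b_t \sin h_t)} with
#' \eqn{a_t = \sum_k w_{tk}\, \mu_{tk} \cdot (Y_{tk} - v_t)} and
#' \eqn{b_t = \sum_k w_{tk} (\mu_{tk,1} (Y_{tk,2}-v_{t,2}) -
#' \mu_{tk,2}(Y_{tk,1}-v_{t,1}))}, where \eqn{\mu_{tk}} is the predicted ego
#' position of keypoint k and \eqn{w_{tk} = 1/(\sigma_k^2 s_{tk})}; only xy
#' components enter for D = 3. Zero concentration falls back to a uniform
#' draw.
#'
#' @inheritParams resampleScales
#' @return Length-T headings in [0, 2*pi).
#' @export
resampleHeadings <- function(model, series) {
  obs <- model@obs; lt <- model@latent
  D <- nDims(series)
  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  pred <- predictedEgoPose(lt$x, ld)
  Y <- coords(series)
  w <- 1 / sweep(obs$s, 2L, obs$sigmasq, "*")
  cx <- Y[, , 1L, drop = TRUE] - lt$v[, 1L]
  cy <- Y[, , 2L, drop = TRUE] - lt$v[, 2L]
  m1 <- pred[, , 1L, drop = TRUE]; m2 <- pred[, , 2L, drop = TRUE]
  a <- rowSums(w * (m1 * cx + m2 * cy))
  b <- rowSums(w * (m1 * cy - m2 * cx))
  kap <- sqrt(a^2 + b^2)
  theta <- atan2(b, a)
  rvonmises(length(a), theta, kap)
}

#' Resample centroids v
#'
#' Exact joint draw of the centroid trajectory per recording. Each frame
#' contributes an isotropic Gaussian observation potential with precision
#' \eqn{\sum_k w_{tk}} and mean the precision-weighted average of
#' \eqn{Y_{tk} - (\mu_{tk} R(h_t))}; frames are coupled by the Gaussian
#' random walk with variance `sigmasq_loc` (the first frame carries the
#' N(0, `sigmasq_v1`) prior). The resulting tridiagonal-precision Gaussian
#' is sampled exactly by sparse Cholesky, independently per axis.
#'
#' @inheritParams resampleScales
#' @return T x D matrix of centroids.
#' @export
resampleCentroids <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  D <- nDims(series); T_ <- nFrames(series)
  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  pred <- predictedEgoPose(lt$x, ld)
  predW <- rotateToWorldAll(pred, lt$h)
  Y <- coords(series)
  w <- 1 / sweep(obs$s, 2L, obs$sigmasq, "*")
  prec <- rowSums(w)                             # emission precision per frame
  emissMean <- matrix(0, T_, D)
  for (dd in seq_len(D))
    emissMean[, dd] <- rowSums(w * (Y[, , dd, drop = TRUE] -
                                      predW[, , dd, drop = TRUE])) / prec
  vOut <- matrix(0, T_, D)
  ri <- recordingIndex(recordings(series))
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    n <- length(rows)
    dg <- prec[rows]
    off <- rep(-1 / hp$sigmasq_loc, max(0L, n - 1L))
    dg[1L] <- dg[1L] + 1 / hp$sigmasq_v1
    if (n > 1L) {
      dg <- dg + c(1 / hp$sigmasq_loc * c(0, rep(1, n - 1L))) +
        c(rep(1 / hp$sigmasq_loc, n - 1L), 0)
      P <- Matrix::bandSparse(n, k = c(0L, 1L),
                              diagonals = list(dg, off), symmetric = TRUE)
    } else {
      P <- Matrix::Matrix(matrix(dg, 1L, 1L), sparse = TRUE)
    }
    rhs <- emissMean[rows, , drop = FALSE] * prec[rows]
    vOut[rows, ] <- samplePrecisionGaussian(P, rhs)
  }
  vOut
}

## Draw columns of X ~ N(P^{-1} R, P^{-1}) for sparse symmetric PD P and
## rhs matrix R (one column per independent sample sharing P).
samplePrecisionGaussian <- function(P, R) {
  R <- as.matrix(R)
  Ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(P), "CsparseMatrix"),
                         LDL = FALSE, perm = TRUE)
  mu <- as.matrix(Matrix::solve(Ch, R, system = "A"))
  Z <- matrix(rnorm(length(R)), nrow(R), ncol(R))
  ## x = mu + Pt' L^{-T} z  (P = Pt' L L' Pt under the fill-reducing perm)
  u <- Matrix::solve(Ch, Z, system = "Lt")
  u <- Matrix::solve(Ch, u, system = "Pt")
  mu + as.matrix(u)
}

#' Resample the latent pose trajectory x
#'
#' Exact joint draw from \eqn{P(x_{1:T} \mid z, v, h, s, \sigma, Y)}. The
#' conditional is Gaussian with block-banded precision: each frame's AR
#' factor couples the window \eqn{x_{t-L:t}} (zero-padded at recording
#' starts) and each frame's emission contributes
#' \eqn{\sum_k w_{tk} B_k^\top B_k} on the diagonal block, where
#' \eqn{B_k} is keypoint k's loading block. Sampled exactly via sparse
#' Cholesky of the assembled precision.
#'
#' @inheritParams resampleScales
#' @return T x M matrix.
#' @export
resampleLatentPose <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  D <- nDims(series); T_ <- nFrames(series)
  M <- hp$M; L <- hp$L; N <- hp$N
  K <- nKeypoints(series)
  z <- lt$z
  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  ego <- egocentrizeAll(coords(series), lt$v, lt$h)
  w <- 1 / sweep(obs$s, 2L, obs$sigmasq, "*")      # T x K precisions

  ## emission quadratic terms, vectorized over frames
  BtB <- matrix(0, K, M * M)
  Ball <- matrix(0, K * D, M)                      # rows (k-1)*D + d
  for (k in seq_len(K)) {
    Bk <- matrix(ld$B[k, , ], nrow = D)            # D x M
    BtB[k, ] <- as.numeric(crossprod(Bk))
    Ball[((k - 1L) * D + 1L):(k * D), ] <- Bk
  }
  Pem <- w %*% BtB                                 # T x M^2 (col-major blocks)
  E <- matrix(0, T_, K * D)
  for (dd in seq_len(D))
    E[, seq.int(dd, by = D, length.out = K)] <-
      ego[, , dd, drop = TRUE] - matrix(ld$dmat[, dd], T_, K, byrow = TRUE)
  wExp <- w[, rep(seq_len(K), each = D)]
  Rem <- (E * wExp) %*% Ball                       # T x M emission rhs

  ## per-state AR window blocks H_i = G_i' Q_i^{-1} G_i, g_i = G_i' Q_i^{-1} b_i
  W <- (L + 1L) * M
  Hflat <- matrix(0, W * W, N)
  gmat <- matrix(0, W, N)
  for (i in seq_len(N)) {
    G <- cbind(-matrix(model@ar$A[i, , ], nrow = M), diag(M))  # M x W
    Qi <- matrix(model@ar$Q[i, , ], M, M)
    Jinv <- chol2inv(chol(Qi))
    JG <- Jinv %*% G
    Hflat[, i] <- as.numeric(crossprod(G, JG))
    gmat[, i] <- as.numeric(crossprod(G, Jinv %*% model@ar$b[i, ]))
  }

  ri <- recordingIndex(recordings(series))
  segOf <- rep(seq_len(nrow(ri)), ri$end - ri$start + 1L)
  relT <- seq_len(T_) - ri$start[segOf] + 1L       # 1-based frame within recording

  iList <- list(); jList <- list(); xList <- list()
  rhs <- numeric(T_ * M)

  ## emission blocks (diagonal, all frames)
  tpl <- expand.grid(r = seq_len(M), c = seq_len(M))
  nb <- M * M
  base <- rep((seq_len(T_) - 1L) * M, each = nb)
  iList[[1L]] <- base + rep(tpl$r, T_)
  jList[[1L]] <- base + rep(tpl$c, T_)
  xList[[1L]] <- as.numeric(t(Pem))                # frame-major, col-major blocks
  for (m in seq_len(M))
    rhs[(seq_len(T_) - 1L) * M + m] <- rhs[(seq_len(T_) - 1L) * M + m] + Rem[, m]

  ## AR blocks: frames with a full L-window inside their recording
  full <- which(relT > L)
  if (length(full)) {
    tplW <- expand.grid(r = seq_len(W), c = seq_len(W))
    nbW <- W * W
    baseW <- rep((full - L - 1L) * M, each = nbW)
    iList[[2L]] <- baseW + rep(tplW$r, length(full))
    jList[[2L]] <- baseW + rep(tplW$c, length(full))
    xList[[2L]] <- as.numeric(Hflat[, z[full]])
    for (p in seq_len(W)) {
      idx <- (full - L - 1L) * M + p
      rhs[idx] <- rhs[idx] + gmat[p, z[full]]
    }
  }
  ## AR blocks for early frames (zero-padded history): keep only the
  ## window entries that exist; padded entries are fixed zeros.
  early <- which(relT <= L)
  for (t in early) {
    nlag <- relT[t] - 1L
    keep <- (W - (nlag + 1L) * M + 1L):W           # last nlag+1 blocks
    Hsub <- matrix(Hflat[, z[t]], W, W)[keep, keep, drop = FALSE]
    gsub <- gmat[keep, z[t]]
    gstart <- (t - nlag - 1L) * M
    nk <- length(keep)
    iList[[length(iList) + 1L]] <- gstart + rep(seq_len(nk), nk)
    jList[[length(jList) + 1L]] <- gstart + rep(seq_len(nk), each = nk)
    xList[[length(xList) + 1L]] <- as.numeric(Hsub)
    rhs[gstart + seq_len(nk)] <- rhs[gstart + seq_len(nk)] + gsub
  }

  P <- Matrix::sparseMatrix(i = unlist(iList), j = unlist(jList),
                            x = unlist(xList), dims = c(T_ * M, T_ * M))
  xNew <- samplePrecisionGaussian(P, matrix(rhs, ncol = 1L))
  matrix(xNew, T_, M, byrow = TRUE)
}

#' Resample the observation loading (C, d)
#'
#' Joint Gaussian draw of the latent-to-pose map from its conditional,
#' with prior \eqn{vec(C, d) \sim N(0, \sigma_C^2 I)}. Off by default in
#' the fitting protocol: (C, d) stay at their PCA initialization.
#'
#' @inheritParams resampleScales
#' @return List with `C` and `d`.
#' @export
resampleLoading <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  D <- nDims(series); T_ <- nFrames(series)
  K <- nKeypoints(series); M <- hp$M
  Gamma <- obs$Gamma
  ego <- egocentrizeAll(coords(series), lt$v, lt$h)
  p <- (K - 1L) * D
  dimTheta <- p * (M + 1L)
  Sxx <- diag(1 / hp$sigmasq_C, dimTheta)
  rhs <- numeric(dimTheta)
  Id <- diag(D)
  for (t in seq_len(T_)) {
    winv <- 1 / (obs$sigmasq * obs$s[t, ])
    Wred <- crossprod(Gamma, Gamma * winv)         # Gamma' S^-1 Gamma, (K-1)^2
    Wfull <- kronecker(Wred, Id)
    xt <- c(lt$x[t, ], 1)
    Sxx <- Sxx + kronecker(tcrossprod(xt), Wfull)
    q <- crossprod(Gamma, matrix(ego[t, , ], K, D) * winv)  # (K-1) x D
    rhs <- rhs + kronecker(xt, as.numeric(t(q)))
  }
  theta <- samplePrecisionGaussian(Matrix::Matrix(Sxx, sparse = TRUE),
                                   matrix(rhs, ncol = 1L))
  Ctil <- matrix(theta, p, M + 1L)
  list(C = Ctil[, seq_len(M), drop = FALSE], d = Ctil[, M + 1L])
}

## chi^-2(nu, tau2) log density
dinvchisqLog <- function(x, nu, tausq) {
  0.5 * nu * log(tausq * nu / 2) - lgamma(nu / 2) -
    (1 + nu / 2) * log(x) - nu * tausq / (2 * x)
}

dirichletLogDens <- function(p, alpha) {
  sum((alpha - 1) * log(pmax(p, 1e-300))) + lgamma(sum(alpha)) -
    sum(lgamma(alpha))
}

#' Log joint density of the model
#'
#' Sum of every prior and likelihood term of the generative model:
#' transition prior and syllable chain, MNIW prior on the dynamics, the AR
#' factors of x (zero-padded), centroid walk, uniform headings, noise-scale
#' and variance priors, and the keypoint observation term. Used to monitor
#' burn-in; errors if any term is non-finite.
#'
#' @inheritParams resampleScales
#' @return Scalar log density.
#' @export
logJoint <- function(model, series) {
  hp <- model@hyper; obs <- model@obs; lt <- model@latent
  tr <- model@trans
  D <- nDims(series); T_ <- nFrames(series)
  N <- hp$N; M <- hp$M
  terms <- c(trans = 0, z = 0, arprior = 0, x = 0, v = 0, h = 0,
             s = 0, sigma = 0, obs = 0)

  terms["trans"] <- dirichletLogDens(tr$beta, rep(hp$gamma / N, N)) +
    sum(vapply(seq_len(N), function(i)
      dirichletLogDens(tr$pi[i, ], hp$alpha * tr$beta +
                         hp$kappa * (seq_len(N) == i)), numeric(1)))

  ri <- recordingIndex(recordings(series))
  lp <- 0
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    lp <- lp - log(N)
    if (length(rows) > 1L)
      lp <- lp + sum(log(tr$pi[cbind(lt$z[rows[-length(rows)]],
                                     lt$z[rows[-1L]])]))
  }
  terms["z"] <- lp

  K0inv <- chol2inv(chol(hp$K0))
  ldK0 <- determinant(hp$K0, logarithm = TRUE)$modulus
  q <- nrow(hp$K0)
  lpAR <- 0
  for (i in seq_len(N)) {
    Qi <- matrix(model@ar$Q[i, , ], M, M)
    cQ <- chol(Qi)
    ldQ <- 2 * sum(log(diag(cQ)))
    ## inverse-Wishart(nu0, S0)
    nu0 <- hp$nu0
    lpAR <- lpAR + 0.5 * nu0 * determinant(hp$S0, TRUE)$modulus -
      0.5 * nu0 * M * log(2) - lmvgamma(nu0 / 2, M) -
      0.5 * (nu0 + M + 1) * ldQ -
      0.5 * sum(diag(hp$S0 %*% chol2inv(cQ)))
    ## matrix normal MN(M0, Q, K0)
    AB <- cbind(matrix(model@ar$A[i, , ], nrow = M), model@ar$b[i, ])
    Dev <- AB - hp$M0
    Qinv <- chol2inv(cQ)
    lpAR <- lpAR - 0.5 * (M * q * log(2 * pi) + q * ldQ + M * ldK0) -
      0.5 * sum(diag(K0inv %*% t(Dev) %*% Qinv %*% Dev))
  }
  terms["arprior"] <- lpAR

  ll <- arLogLikelihoods(lt$x, model@ar, recordings(series), maskFirst = FALSE)
  terms["x"] <- sum(ll[cbind(seq_len(T_), lt$z)])

  lpv <- 0
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    lpv <- lpv + sum(dnorm(lt$v[rows[1L], ], 0, sqrt(hp$sigmasq_v1),
                           log = TRUE))
    if (length(rows) > 1L) {
      dv <- diff(lt$v[rows, , drop = FALSE])
      lpv <- lpv + sum(dnorm(dv, 0, sqrt(hp$sigmasq_loc), log = TRUE))
    }
  }
  terms["v"] <- lpv
  terms["h"] <- -T_ * log(2 * pi)
  terms["s"] <- sum(dinvchisqLog(obs$s, hp$nu_s, obs$s0))
  terms["sigma"] <- sum(dinvchisqLog(obs$sigmasq, hp$nu_sigma, hp$sigmasq0))

  ld <- keypointLoadings(obs$C, obs$d, obs$Gamma, D)
  pred <- predictedEgoPose(lt$x, ld)
  ego <- egocentrizeAll(coords(series), lt$v, lt$h)
  sq <- egoResidualSq(ego, pred)
  varmat <- sweep(obs$s, 2L, obs$sigmasq, "*")
  terms["obs"] <- -0.5 * sum(D * log(2 * pi * varmat) + sq / varmat)

  bad <- names(terms)[!is.finite(terms)]
  if (length(bad))
    stop("non-finite log-joint term(s): ", paste(bad, collapse = ", "))
  sum(terms)
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## One full Gibbs sweep in the fixed order
## z -> (pi, beta) -> (A, b, Q) -> x -> h -> v -> s -> sigma.
## updateParams = FALSE freezes pi/beta/A/b/Q/sigma (used by applyModel);
## updateCd = TRUE additionally resamples the loading.
gibbsSweep <- function(model, series, updateParams = TRUE, updateCd = FALSE) {
  lt <- model@latent
  rec <- recordings(series)
  ll <- arLogLikelihoods(lt$x, model@ar, rec, maskFirst = FALSE)
  lt$z <- resampleStates(ll, model@trans$pi, rec)
  model@latent <- lt
  if (updateParams) {
    model@trans <- resampleTransitions(lt$z, model@hyper, rec,
                                       beta = model@trans$beta)
    model@ar <- resampleARParams(lt$x, lt$z, model@hyper, rec)
  }
  lt$x <- resampleLatentPose(model, series); model@latent <- lt
  lt$h <- resampleHeadings(model, series); model@latent <- lt
  lt$v <- resampleCentroids(model, series); model@latent <- lt
  model@obs$s <- resampleScales(model, series)
  if (updateParams)
    model@obs$sigmasq <- resampleSigmasq(model, series)
  if (updateCd) {
    cd <- resampleLoading(model, series)
    model@obs$C <- cd$C
    model@obs$d <- cd$d
  }
  model
}
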