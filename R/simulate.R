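## Generative simulators: full switching model with ground truth, the
## single-state LDS null, and the keypoint-ablation schedule.

#' SimTruth: ground-truth latents and parameters of a simulation
#'
#' @slot latent List with the true `z`, `x`, `v`, `h`, `s`.
#' @slot params List with the true `trans`, `ar`, `C`, `d`, `Gamma`,
#'   `sigmasq`, `s0`.
#' @slot hyper Hyperparameter list used to generate.
#' @export
setClass("SimTruth",
  representation(latent = "list", params = "list", hyper = "list"))

setMethod("show", "SimTruth", function(object) {
  z <- object@latent$z
  cat(sprintf("SimTruth: %d frames, %d states used\n",
              length(z), length(unique(z))))
  invisible(object)
})

## companion-form spectral radius of [A_1 ... A_L]
companionSpectralRadius <- function(A) {
  M <- nrow(A); L <- ncol(A) / M
  comp <- matrix(0, L * M, L * M)
  if (L > 1)
    comp[seq_len((L - 1) * M), (M + 1):(L * M)] <- diag((L - 1) * M)
  ## our lag blocks are ordered oldest -> newest: x_t = sum_l A[, block l] x_{t-L+l-1}
  ## companion state (x_{t-L+1}, ..., x_t): last block row is [A_1 ... A_L]
  comp[((L - 1) * M + 1):(L * M), ] <- A
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Construct well-separated stable simulation dynamics
#'
#' Builds per-state AR parameters with distinct damped-rotation dynamics
#' (state-specific angular velocity and drift), a smooth elongated base
#' pose resembling a rodent body (nose-to-tail along +x), and a loading
#' matrix of smooth spatial modes. These are the default study conditions
#' of the simulator: stable (companion spectral radius < 1), separated
#' enough that syllables are identifiable, with latent stationary scale
#' near 1 (whitened units).
#'
#' @param nStates Number of discrete states.
#' @param K Keypoints; `D` spatial dimension; `M` latent dimension;
#'   `L` AR lag order.
#' @param D,M,L See above.
#' @param poseScale Spatial magnitude (length units) of pose variation per
#'   latent unit; default 8.
#' @param bodyLength Nose-to-tail extent of the base pose; default 60.
#' @param meanDurationFrames Mean syllable duration of the sticky transition
#'   matrix, in frames; default 12 (400 ms at 30 Hz).
#' @return List with `ar` (`A`, `b`, `Q`), `C`, `d`, `Gamma`, `pi`, `beta`.
#' @export
simulationParams <- function(nStates = 4L, K = 8L, D = 2L, M = 4L, L = 3L,
                             poseScale = 8, bodyLength = 60,
                             meanDurationFrames = 12) {
  Gamma <- gammaEmbedding(K)
  ## base pose: body axis along +x, ears off-axis
  bx <- seq(bodyLength / 2, -bodyLength / 2, length.out = K)
  by <- rep(0, K)
  if (K >= 4L) { by[2L] <- 6; by[3L] <- -6 }
  base <- cbind(bx, by)
  if (D == 3L) base <- cbind(base, rep(2, K))
  base <- sweep(base, 2L, colMeans(base))
  d <- numeric((K - 1L) * D)
  for (dd in seq_len(D))
    d[seq.int(dd, by = D, length.out = K - 1L)] <- crossprod(Gamma, base[, dd])
  ## smooth orthogonal spatial modes for the loading
  p <- (K - 1L) * D
  raw <- matrix(0, p, M)
  for (m in seq_len(M)) {
    mode <- sin(outer(seq_len(K) / K, m * pi))[, 1L] + cos(m * seq_len(K))
    v <- numeric(p)
    for (dd in seq_len(D)) {
      comp <- if ((m + dd) %% 2 == 0) mode else rev(mode)
      v[seq.int(dd, by = D, length.out = K - 1L)] <-
        crossprod(Gamma, comp * (1 + 0.3 * dd))
    }
    raw[, m] <- v
  }
  C <- qr.Q(qr(raw))[, seq_len(M), drop = FALSE] * poseScale
  ## per-state damped rotation dynamics + drift
  A <- array(0, dim = c(nStates, M, L * M))
  b <- matrix(0, nStates, M)
  Q <- array(0, dim = c(nStates, M, M))
  for (i in seq_len(nStates)) {
    omega <- 0.25 + 0.45 * (i - 1) / max(1, nStates - 1)
    rho <- 0.88
    A1 <- diag(M) * rho
    for (pr in seq_len(floor(M / 2))) {
      idx <- c(2 * pr - 1, 2 * pr)
      th <- omega * (1 + 0.3 * (pr - 1)) * (if (i %% 2 == 0) 1 else -1)
      A1[idx, idx] <- rho * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    }
    A[i, , (L - 1) * M + seq_len(M)] <- A1     # newest lag block
    dir <- sin(i + seq_len(M))
    b[i, ] <- 0.35 * dir / sqrt(sum(dir^2))
    Q[i, , ] <- diag(0.2, M)
    stopifnot(companionSpectralRadius(matrix(A[i, , ], M)) < 1)
  }
  pSelf <- 1 - 1 / meanDurationFrames
  piMat <- matrix((1 - pSelf) / max(1, nStates - 1), nStates, nStates)
  diag(piMat) <- if (nStates == 1L) 1 else pSelf
  list(ar = list(A = A, b = b, Q = Q), C = C, d = d, Gamma = Gamma,
       pi = piMat, beta = rep(1 / nStates, nStates))
}

#' Draw AR parameters from the MNIW prior (stability-enforced)
#'
#' Repeatedly draws \eqn{[A_i|b_i], Q_i \sim MNIW(\nu_0, S_0, M_0, K_0)}
#' until the companion-form spectral radius is below `radius`, erroring
#' after `maxTries` rejections.
#'
#' @param hyper Hyperparameter list.
#' @param nStates Number of states to draw.
#' @param radius Stability bound; default 1.
#' @param maxTries Rejections allowed per state.
#' @return List `A`, `b`, `Q` as in [simulationParams()].
#' @export
drawPriorARParams <- function(hyper, nStates, radius = 1, maxTries = 100L) {
  M <- hyper$M; L <- hyper$L
  A <- array(0, dim = c(nStates, M, L * M))
  b <- matrix(0, nStates, M)
  Q <- array(0, dim = c(nStates, M, M))
  for (i in seq_len(nStates)) {
    ok <- FALSE
    for (tr in seq_len(maxTries)) {
      draw <- rmniw(hyper$nu0, hyper$S0, hyper$M0, hyper$K0)
      Ai <- draw$AB[, seq_len(L * M), drop = FALSE]
      if (companionSpectralRadius(Ai) < radius) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw stable AR dynamics for state ", i)
    A[i, , ] <- Ai
    b[i, ] <- draw$AB[, L * M + 1L]
    Q[i, , ] <- draw$Q
  }
  list(A = A, b = b, Q = Q)
}

## simulate a sticky Markov chain (uniform initial state)
simulateChain <- function(T_, piMat) {
  N <- nrow(piMat)
  z <- integer(T_)
  z[1L] <- sample.int(N, 1L)
  for (t in seq_len(T_)[-1L])
    z[t] <- sample.int(N, 1L, prob = piMat[z[t - 1L], ])
  z
}

## simulate the switching AR process with zero-padded history
simulateAR <- function(z, ar, M, L) {
  T_ <- length(z)
  x <- matrix(0, T_, M)
  hist <- matrix(0, L, M)        # rows: x_{t-L}..x_{t-1}
  for (t in seq_len(T_)) {
    i <- z[t]
    A <- matrix(ar$A[i, , ], M)
    mu <- A %*% as.numeric(t(hist)) + ar$b[i, ]
    cQ <- chol(matrix(ar$Q[i, , ], M, M))
    x[t, ] <- as.numeric(mu) + as.numeric(crossprod(cQ, rnorm(M)))
    if (L > 1L) hist[seq_len(L - 1L), ] <- hist[-1L, , drop = FALSE]
    hist[L, ] <- x[t, ]
  }
  x
}

#' Simulate keypoint data from the full generative model
#'
#' Samples a sticky Markov syllable sequence, per-state AR latent pose,
#' Gaussian random-walk centroid, headings, scaled-inverse-chi-squared
#' per-frame noise scales (with confidences emitted through the inverse of
#' the confidence-to-noise curve), and finally world keypoint coordinates
#' \eqn{Y_t = \tilde Y_t R(h_t) + 1_K v_t^\top} with
#' \eqn{vec(\tilde Y_t) \sim N((\Gamma \otimes I_D)(C x_t + d), S_t)}.
#'
#' @param T_ Number of frames.
#' @param K,D Keypoints and spatial dimension.
#' @param fps Frame rate in Hz.
#' @param nStates True number of syllables.
#' @param params Optional parameter list from [simulationParams()]; if
#'   `NULL`, the defaults are built (and AR parameters can instead be drawn
#'   from the prior with `fromPrior = TRUE`).
#' @param hyper Optional hyperparameter list; defaults to
#'   [defaultHyperparams()] with M = 4.
#' @param lowConfFraction Fraction of keypoint detections given low
#'   confidence (high prior noise); default 0.03.
#' @param headings `"walk"` (default) uses a wrapped random walk with a
#'   uniform start (smooth, animal-like turning; headings still cover the
#'   whole circle); `"iid"` draws independent uniform headings per frame
#'   (the model prior, but unphysical at tracker frame rates and
#'   incompatible with interpolating world coordinates across frames).
#' @param fromPrior Draw AR parameters from the MNIW prior instead of the
#'   constructed defaults.
#' @return List with `series` (a [KeypointSeries-class]) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateKeypointSLDS <- function(T_, K = 8L, D = 2L, fps = 30,
                                 nStates = 4L, params = NULL, hyper = NULL,
                                 lowConfFraction = 0.03,
                                 headings = c("walk", "iid"),
                                 fromPrior = FALSE) {
  headings <- match.arg(headings)
  if (is.null(hyper)) hyper <- defaultHyperparams(M = 4L)
  M <- hyper$M; L <- hyper$L
  if (is.null(params)) {
    params <- simulationParams(nStates, K, D, M, L)
    if (fromPrior) params$ar <- drawPriorARParams(hyper, nStates)
  }
  Gamma <- params$Gamma
  z <- simulateChain(T_, params$pi)
  x <- simulateAR(z, params$ar, M, L)
  ## centroid random walk
  v <- matrix(0, T_, D)
  v[1L, ] <- rnorm(D, 0, sqrt(hyper$sigmasq_v1))
  if (T_ > 1L)
    for (dd in seq_len(D))
      v[-1L, dd] <- v[1L, dd] + cumsum(rnorm(T_ - 1L, 0, sqrt(hyper$sigmasq_loc)))
  h <- if (headings == "iid") runif(T_, 0, 2 * pi)
       else wrapAngle(cumsum(c(runif(1, 0, 2 * pi), rnorm(T_ - 1L, 0, 0.1))))
  ## confidences -> prior noise scales -> actual scales
  conf <- matrix(rbeta(T_ * K, 18, 1), T_, K)
  low <- matrix(runif(T_ * K) < lowConfFraction, T_, K)
  conf[low] <- rbeta(sum(low), 1.5, 8)
  s0 <- s0FromConfidence(conf)
  sigmasq <- rep(hyper$sigmasq0, K)
  s <- matrix(rinvchisq(T_ * K, hyper$nu_s, as.numeric(s0)), T_, K)
  ## observations
  ld <- keypointLoadings(params$C, params$d, Gamma, D)
  pred <- predictedEgoPose(x, ld)
  noiseSd <- sqrt(sweep(s, 2L, sigmasq, "*"))
  ego <- pred
  for (dd in seq_len(D))
    ego[, , dd] <- pred[, , dd, drop = TRUE] +
      matrix(rnorm(T_ * K), T_, K) * noiseSd
  Y <- rotateToWorldAll(ego, h)
  for (dd in seq_len(D)) Y[, , dd] <- Y[, , dd, drop = TRUE] + v[, dd]
  series <- KeypointSeries(Y, conf, fps)
  truth <- new("SimTruth",
               latent = list(z = z, x = x, v = v, h = h, s = s),
               params = list(trans = list(beta = params$beta, pi = params$pi),
                             ar = params$ar, C = params$C, d = params$d,
                             Gamma = Gamma, sigmasq = sigmasq, s0 = s0),
               hyper = hyper)
  list(series = series, truth = truth)
}

#' Simulate the single-state LDS null
#'
#' Same observation pathway as the full simulator but with exactly one
#' discrete state (no syllable block structure), no centroid or heading
#' motion, and separate noise variances for each coordinate axis of each
#' keypoint. Serves as the negative control: a switching model fit to this
#' data should not find well-separated syllables.
#'
#' @param T_ Frames; `K`, `D`, `fps` as in [simulateKeypointSLDS()].
#' @param K,D,fps See above.
#' @param params Optional [simulationParams()]-style list; defaults to the
#'   standard one-state parameters with L = 1 dynamics.
#' @param axisNoiseSd Optional K x D matrix of per-keypoint per-axis noise
#'   standard deviations; default draws log-uniform in [0.5, 1.5].
#' @return List with `series` and `truth` (latent `x`; `z` all ones).
#' @export
simulateLDSNull <- function(T_, K = 8L, D = 2L, fps = 30, params = NULL,
                            axisNoiseSd = NULL) {
  hyper <- defaultHyperparams(M = 4L, L = 1L)
  if (is.null(params))
    params <- simulationParams(1L, K, D, hyper$M, hyper$L,
                               meanDurationFrames = 2)
  z <- rep(1L, T_)
  x <- simulateAR(z, params$ar, hyper$M, hyper$L)
  if (is.null(axisNoiseSd))
    axisNoiseSd <- matrix(exp(runif(K * D, log(0.5), log(1.5))), K, D)
  ld <- keypointLoadings(params$C, params$d, params$Gamma, D)
  pred <- predictedEgoPose(x, ld)
  Y <- pred
  for (dd in seq_len(D))
    Y[, , dd] <- pred[, , dd, drop = TRUE] +
      matrix(rnorm(T_ * K), T_, K) *
        matrix(axisNoiseSd[, dd], T_, K, byrow = TRUE)
  series <- KeypointSeries(Y, matrix(1, T_, K), fps)
  truth <- new("SimTruth",
               latent = list(z = z, x = x, v = matrix(0, T_, D),
                             h = rep(0, T_), s = matrix(1, T_, K)),
               params = list(ar = params$ar, C = params$C, d = params$d,
                             Gamma = params$Gamma, axisNoiseSd = axisNoiseSd),
               hyper = hyper)
  list(series = series, truth = truth)
}

#' Random keypoint-ablation schedule
#'
#' Ablation intervals start on every 10th second of the recording
#' (t = 10 s, 20 s, ...), last Uniform(33 ms, 3 s), and each affects a
#' uniformly chosen subset of 1-8 keypoints.
#'
#' @param T_ Recording length in frames.
#' @param fps Frame rate in Hz.
#' @param K Number of keypoints available.
#' @param maxKeypoints Largest subset size; default `min(8, K)`.
#' @return Data frame with `start`, `end` (1-based frames, inclusive) and a
#'   list-column `keypoints`.
#' @export
ablationSchedule <- function(T_, fps, K = 8L, maxKeypoints = min(8L, K)) {
  if (T_ < 10 * fps) stop("recording must be at least 10 s long")
  starts <- seq(10, floor((T_ - 1) / fps), by = 10)
  starts <- starts[starts * fps + 1 <= T_]
  out <- data.frame(start = integer(0), end = integer(0))
  kps <- list()
  for (i in seq_along(starts)) {
    st <- as.integer(round(starts[i] * fps)) + 1L
    durFrames <- max(1L, as.integer(round(runif(1, 0.033, 3) * fps)))
    en <- min(T_, st + durFrames - 1L)
    nk <- sample.int(maxKeypoints, 1L)
    out <- rbind(out, data.frame(start = st, end = en))
    kps[[i]] <- sort(sample.int(K, nk))
  }
  out$keypoints <- kps
  out
}

#' Apply an ablation schedule to a series
#'
#' For each interval and keypoint: erase the coordinates and fill the gap
#' by linear interpolation between the flanking unablated frames, and set
#' the confidences to 0. Untouched frames are bitwise unchanged.
#'
#' @param series A [KeypointSeries-class].
#' @param schedule From [ablationSchedule()].
#' @return An ablated `KeypointSeries`.
#' @export
applyAblation <- function(series, schedule) {
  Y <- coords(series); cf <- confidences(series)
  T_ <- nFrames(series); D <- nDims(series)
  for (i in seq_len(nrow(schedule))) {
    st <- schedule$start[i]; en <- schedule$end[i]
    if (st < 1L || en > T_) stop("ablation interval out of bounds")
    lo <- st - 1L; hi <- en + 1L
    for (k in schedule$keypoints[[i]]) {
      for (dd in seq_len(D)) {
        if (lo >= 1L && hi <= T_) {
          Y[st:en, k, dd] <- Y[lo, k, dd] +
            (Y[hi, k, dd] - Y[lo, k, dd]) * (st:en - lo) / (hi - lo)
        } else if (lo >= 1L) {
          Y[st:en, k, dd] <- Y[lo, k, dd]
        } else if (hi <= T_) {
          Y[st:en, k, dd] <- Y[hi, k, dd]
        }
      }
      cf[st:en, k] <- 0
    }
  }
  KeypointSeries(Y, cf, fps(series), recordings(series),
                 keypointNames(series))
}
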