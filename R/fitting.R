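## Two-phase fitting protocol, stickiness calibration, model application
## and ensemble ranking.

#' Median syllable duration in milliseconds
#'
#' Median over maximal same-state runs (syllable instances), computed per
#' recording, converted to ms at the given frame rate.
#'
#' @param z Integer state sequence.
#' @param fps Frame rate in Hz.
#' @param recording Per-frame recording labels.
#' @param minFrequency If > 0, instances of states whose overall frame
#'   frequency is below this fraction are excluded first.
#' @return Median duration in ms (NA if no instances remain).
#' @export
medianSyllableDurationMs <- function(z, fps, recording = rep("rec1", length(z)),
                                     minFrequency = 0) {
  inst <- extractInstances(z, recording, fps, minFrequency = minFrequency)
  d <- inst$instances$durationFrames[!inst$instances$excluded]
  if (!length(d)) return(NA_real_)
  median(d) * 1000 / fps
}

## AR-HMM log joint (transition prior + chain + AR prior + AR likelihood)
arhmmLogJoint <- function(x, z, trans, ar, hyper, recording) {
  N <- hyper$N
  lp <- dirichletLogDens(trans$beta, rep(hyper$gamma / N, N)) +
    sum(vapply(seq_len(N), function(i)
      dirichletLogDens(trans$pi[i, ], hyper$alpha * trans$beta +
                         hyper$kappa * (seq_len(N) == i)), numeric(1)))
  ri <- recordingIndex(recording)
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    lp <- lp - log(N)
    if (length(rows) > 1L)
      lp <- lp + sum(log(pmax(trans$pi[cbind(z[rows[-length(rows)]],
                                             z[rows[-1L]])], 1e-300)))
  }
  ll <- arLogLikelihoods(x, ar, recording, maskFirst = TRUE)
  lp + sum(ll[cbind(seq_along(z), z)])
}

#' Fit an AR-HMM to a fixed pose trajectory
#'
#' Phase one of the protocol: Gibbs sampling of the state sequence,
#' transition parameters and AR dynamics on a fixed (whitened PCA) pose
#' trajectory. States are initialized uniformly at random; the first L
#' frames of each recording are masked in the state likelihood.
#'
#' @param x T x M pose trajectory (whitened projections).
#' @param hyper Hyperparameter list (kappa must be set).
#' @param iters Number of Gibbs sweeps (>= 1).
#' @param recording Per-frame recording labels.
#' @param verbose Print a progress line every 10 sweeps.
#' @return List with `z`, `trans`, `ar`, `hyper`, `trace` (data frame of
#'   per-iteration log joint and median duration in frames).
#' @export
fitARHMM <- function(x, hyper, iters = 50L,
                     recording = rep("rec1", nrow(x)), verbose = FALSE) {
  if (iters < 1L) stop("iters must be >= 1")
  if (is.na(hyper$kappa)) stop("kappa is not set; calibrate or supply it")
  T_ <- nrow(x); N <- hyper$N
  z <- sample.int(N, T_, replace = TRUE)
  trans <- list(beta = rep(1 / N, N), pi = NULL)
  trans$pi <- resamplePi(trans$beta, matrix(0, N, N), hyper)
  ar <- NULL
  trace <- data.frame(iter = integer(0), logJoint = numeric(0),
                      medianDurationFrames = numeric(0))
  for (it in seq_len(iters)) {
    ar <- resampleARParams(x, z, hyper, recording)
    ll <- arLogLikelihoods(x, ar, recording, maskFirst = TRUE)
    z <- resampleStates(ll, trans$pi, recording)
    trans <- resampleTransitions(z, hyper, recording, beta = trans$beta)
    lj <- arhmmLogJoint(x, z, trans, ar, hyper, recording)
    md <- medianSyllableDurationMs(z, 1000, recording)  # in frames
    trace <- rbind(trace, data.frame(iter = it, logJoint = lj,
                                     medianDurationFrames = md))
    if (verbose && it %% 10L == 0L)
      message(sprintf("iter %d  logJoint %.1f  median duration %.1f frames",
                      it, lj, md))
  }
  list(z = z, trans = trans, ar = ar, hyper = hyper, trace = trace)
}

#' Calibrate the stickiness hyperparameter
#'
#' Bisection search on log10(kappa): short pilot AR-HMM fits are run at
#' candidate kappa values until the fitted median syllable duration lands
#' within `tol` (relative) of `targetMs`. The bracket is expanded
#' geometrically first if needed. Median duration is monotone
#' non-decreasing in kappa, which bisection relies on.
#'
#' @param x T x M pose trajectory.
#' @param hyper Hyperparameter list (kappa ignored).
#' @param targetMs Target median syllable duration in ms; default 400.
#' @param fps Frame rate of the data in Hz.
#' @param recording Per-frame recording labels.
#' @param pilotIters Sweeps per pilot fit; default 50.
#' @param tol Relative tolerance; default 0.1 (within +/- 10 percent).
#' @param maxEvals Total pilot fits allowed; default 12.
#' @param log10Range Initial search bracket for log10(kappa).
#' @param verbose Print one line per pilot fit.
#' @return List with `kappa`, `durationMs` (at the returned kappa), and
#'   `trace` (data frame of tested kappas and durations).
#' @export
calibrateKappa <- function(x, hyper, targetMs = 400, fps = 30,
                           recording = rep("rec1", nrow(x)),
                           pilotIters = 50L, tol = 0.1, maxEvals = 12L,
                           log10Range = c(2, 8), verbose = FALSE) {
  if (targetMs <= 1000 / fps)
    stop("target duration must exceed one frame period")
  evalKappa <- function(lk) {
    hp <- hyper; hp$kappa <- 10^lk
    fit <- fitARHMM(x, hp, iters = pilotIters, recording = recording)
    ## average the duration over the tail of the pilot to damp sweep-to-sweep
    ## jitter (durations move in whole-frame steps)
    tailN <- min(10L, pilotIters)
    md <- median(tail(fit$trace$medianDurationFrames, tailN)) * 1000 / fps
    if (verbose)
      message(sprintf("kappa 10^%.2f -> median %.0f ms", lk, md))
    md
  }
  trace <- data.frame(log10kappa = numeric(0), durationMs = numeric(0))
  record <- function(lk, d) trace[nrow(trace) + 1L, ] <<- c(lk, d)
  relErr <- function(d) abs(d - targetMs) / targetMs
  ## once inside the acceptance band, keep bisecting toward this tighter
  ## relative error while the evaluation budget lasts, so an independent
  ## refit stays inside the band despite whole-frame duration granularity
  refineTol <- min(tol, 0.025)
  lo <- log10Range[1L]; hi <- log10Range[2L]
  dLo <- evalKappa(lo); record(lo, dLo)
  nEval <- 1L
  dHi <- evalKappa(hi); record(hi, dHi); nEval <- nEval + 1L
  ## expand the bracket if the target is outside it
  while (dLo > targetMs && nEval < maxEvals && lo > -4) {
    lo <- lo - 2; dLo <- evalKappa(lo); record(lo, dLo); nEval <- nEval + 1L
  }
  while (dHi < targetMs && nEval < maxEvals && hi < 14) {
    hi <- hi + 2; dHi <- evalKappa(hi); record(hi, dHi); nEval <- nEval + 1L
  }
  if (dLo > targetMs || dHi < targetMs) {
    warning("target duration not bracketable; returning closest tested kappa")
    i <- which.min(abs(trace$durationMs - targetMs))
    return(list(kappa = 10^trace$log10kappa[i],
                durationMs = trace$durationMs[i], trace = trace))
  }
  best <- if (relErr(dLo) < relErr(dHi)) c(lo, dLo) else c(hi, dHi)
  while (nEval < maxEvals && relErr(best[2L]) > refineTol) {
    mid <- (lo + hi) / 2
    dMid <- evalKappa(mid); record(mid, dMid); nEval <- nEval + 1L
    if (relErr(dMid) < relErr(best[2L])) best <- c(mid, dMid)
    if (dMid < targetMs) { lo <- mid; dLo <- dMid } else { hi <- mid; dHi <- dMid }
  }
  if (relErr(best[2L]) > tol)
    warning("calibration did not reach the target tolerance")
  list(kappa = 10^best[1L], durationMs = best[2L], trace = trace)
}

#' Initialize the full model from an AR-HMM fit
#'
#' Builds a [KeypointSLDS-class] whose discrete part comes from the AR-HMM,
#' observation loading from the PCA, latents (v, h) from egocentric
#' alignment of the original series, noise-scale priors s0 from the
#' detection confidences, and s initialized at s0.
#'
#' @param series The original [KeypointSeries-class] (uninterpolated,
#'   unaugmented coordinates).
#' @param arhmm Result of [fitARHMM()].
#' @param pca Result of [fitPCAWhiten()].
#' @param aligned The [AlignedPose-class] of `series`.
#' @param seed Integer recorded on the model.
#' @return A [KeypointSLDS-class].
#' @export
initFullModel <- function(series, arhmm, pca, aligned, seed = NA_integer_) {
  hp <- arhmm$hyper
  K <- nKeypoints(series)
  s0 <- s0FromConfidence(confidences(series))
  obs <- list(C = pca$C, d = pca$d, Gamma = pca$Gamma,
              sigmasq = rep(hp$sigmasq0, K), s = s0, s0 = s0)
  latent <- list(z = arhmm$z, x = pca$x, v = aligned@v, h = aligned@h)
  newKeypointSLDS(hp, arhmm$trans, arhmm$ar, obs, latent, seed)
}

#' Fit the full keypoint model
#'
#' Phase two of the protocol: Gibbs sweeps over all latent variables and
#' parameters (syllables, transitions, AR dynamics, latent pose, heading,
#' centroid, noise scales and variances), starting from an AR-HMM
#' initialization. The loading (C, d) stays fixed at its PCA value unless
#' `updateCd = TRUE`.
#'
#' @param series The original [KeypointSeries-class].
#' @param init A [KeypointSLDS-class] from [initFullModel()].
#' @param iters Number of sweeps; the protocol default is 500.
#' @param updateCd Also resample the loading (off by default).
#' @param verbose Print a progress line every 10 sweeps.
#' @return List with `model` (final [KeypointSLDS-class]) and `report`
#'   (data frame of per-iteration log joint and median duration in ms).
#' @export
fitKeypointSLDS <- function(series, init, iters = 500L, updateCd = FALSE,
                            verbose = FALSE) {
  if (iters < 1L) stop("iters must be >= 1")
  if (length(init@latent$z) != nFrames(series))
    stop("initialization and series disagree on the number of frames")
  model <- init
  fpsHz <- fps(series)
  rec <- recordings(series)
  report <- data.frame(iter = integer(0), logJoint = numeric(0),
                       medianDurationMs = numeric(0))
  for (it in seq_len(iters)) {
    model <- gibbsSweep(model, series, updateParams = TRUE,
                        updateCd = updateCd)
    lj <- logJoint(model, series)
    md <- medianSyllableDurationMs(model@latent$z, fpsHz, rec)
    report <- rbind(report, data.frame(iter = it, logJoint = lj,
                                       medianDurationMs = md))
    if (verbose && it %% 10L == 0L)
      message(sprintf("iter %d  logJoint %.1f  median duration %.0f ms",
                      it, lj, md))
  }
  list(model = model, report = report)
}

#' Apply a fitted model to (new) data with frozen parameters
#'
#' Resamples only the latent variables (z, x, v, h, s) on the given
#' series, holding all parameters (transitions, AR dynamics, loading,
#' sigma^2) fixed. Because the parameters are shared, syllable labels are
#' directly comparable across repeated applications and across datasets
#' (e.g. ablated versions of the training data).
#'
#' @param model A fitted [KeypointSLDS-class].
#' @param series A [KeypointSeries-class] with the same keypoint set.
#' @param iters Latent-only Gibbs sweeps; default 50.
#' @param anterior,posterior Reference keypoints for the alignment
#'   initialization.
#' @return A [KeypointSLDS-class] with updated latents (parameters
#'   bit-identical to `model`).
#' @export
applyModel <- function(model, series, iters = 50L,
                       anterior = 1L, posterior = nKeypoints(series)) {
  if (ncol(model@obs$Gamma) + 1L != nKeypoints(series))
    stop("keypoint set differs from the training data")
  hp <- model@hyper
  al <- egocentricAlign(series, anterior, posterior)
  Yr <- reducedPoseMatrix(al, model@obs$Gamma)
  Yc <- sweep(Yr, 2L, model@obs$d)
  C <- model@obs$C
  x <- Yc %*% C %*% chol2inv(chol(crossprod(C)))   # least-squares projection
  s0 <- s0FromConfidence(confidences(series))
  out <- model
  out@obs$s <- s0
  out@obs$s0 <- s0
  ll <- arLogLikelihoods(x, model@ar, recordings(series), maskFirst = FALSE)
  z <- resampleStates(ll, model@trans$pi, recordings(series))
  out@latent <- list(z = z, x = x, v = al@v, h = al@h)
  for (it in seq_len(iters))
    out <- gibbsSweep(out, series, updateParams = FALSE, updateCd = FALSE)
  out
}

#' Expected marginal likelihood scores for an ensemble of fits
#'
#' Ranks an ensemble of model fits (same data, different seeds) by how well
#' each fit's AR dynamics explain the pose trajectories inferred by the
#' other fits: \eqn{Score(\theta^{(i)}) = \frac{1}{N-1} \sum_{j \ne i}
#' \log P(x^{(j)} \mid \theta^{(i)})}, the discrete states marginalized by
#' the HMM forward algorithm. Consensus-like fits score highest, outliers
#' lowest.
#'
#' @param ensemble List of fits; each element needs `x` (T x M trajectory),
#'   `ar` (AR parameter list) and `trans` (with `pi`), e.g. the output of
#'   [fitARHMM()].
#' @param recording Per-frame recording labels.
#' @return Numeric vector of scores, one per ensemble member.
#' @export
emlScores <- function(ensemble, recording = NULL) {
  nE <- length(ensemble)
  if (nE < 2L) stop("need at least 2 ensemble members")
  if (is.null(recording))
    recording <- rep("rec1", nrow(ensemble[[1L]]$x))
  ri <- recordingIndex(recording)
  scores <- numeric(nE)
  for (i in seq_len(nE)) {
    tot <- 0
    for (j in seq_len(nE)[-i]) {
      ll <- arLogLikelihoods(ensemble[[j]]$x, ensemble[[i]]$ar, recording,
                             maskFirst = FALSE)
      tot <- tot + .hmmLogMarginal(ll, ensemble[[i]]$trans$pi,
                                   as.integer(ri$start), as.integer(ri$end))
    }
    scores[i] <- tot / (nE - 1L)
  }
  scores
}

#' Run the full two-phase pipeline on a series
#'
#' Convenience wrapper: interpolation, noise augmentation, egocentric
#' alignment, whitened PCA, kappa calibration (optional), AR-HMM fit, then
#' the full model fit on the original coordinates.
#'
#' @param series A [KeypointSeries-class].
#' @param anterior,posterior Reference keypoints for alignment.
#' @param nStates Maximum number of states N.
#' @param kappa Stickiness; `NA` triggers calibration to `targetMs`.
#' @param targetMs Median-duration target for calibration.
#' @param arhmmIters,fullIters Sweep counts for the two phases.
#' @param varianceTarget PCA explained-variance target.
#' @param seed Integer seed (set at entry; recorded on the model).
#' @param verbose Progress lines.
#' @return List with `model`, `report`, `arhmm`, `pca`, `kappa`.
#' @export
fitPipeline <- function(series, anterior = 1L, posterior = nKeypoints(series),
                        nStates = 100L, kappa = NA_real_, targetMs = 400,
                        arhmmIters = 50L, fullIters = 200L,
                        varianceTarget = 0.9, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  rec <- recordings(series)
  interp <- interpolateLowConfidence(series, 0.5)
  aug <- augmentUniformNoise(interp, 0.1)
  alignedAug <- egocentricAlign(aug, anterior, posterior)
  pca <- fitPCAWhiten(alignedAug, varianceTarget)
  hyper <- defaultHyperparams(M = pca$M, N = nStates, kappa = kappa)
  if (is.na(kappa)) {
    cal <- calibrateKappa(pca$x, hyper, targetMs = targetMs,
                          fps = fps(series), recording = rec,
                          verbose = verbose)
    hyper$kappa <- cal$kappa
  } else cal <- NULL
  arhmm <- fitARHMM(pca$x, hyper, iters = arhmmIters, recording = rec,
                    verbose = verbose)
  aligned <- egocentricAlign(series, anterior, posterior)
  init <- initFullModel(series, arhmm, pca, aligned, seed)
  fit <- fitKeypointSLDS(series, init, iters = fullIters, verbose = verbose)
  list(model = fit$model, report = fit$report, arhmm = arhmm, pca = pca,
       kappa = hyper$kappa, calibration = cal)
}
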