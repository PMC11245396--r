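#' AlignedPose: egocentrically aligned keypoint series
#'
#' Result of [egocentricAlign()]: per-frame centered and oriented poses
#' together with the removed centroids and headings, so the original world
#' coordinates can be reconstructed exactly via [rigidTransform()].
#'
#' @slot ytilde Numeric array T x K x D of centered/oriented coordinates.
#' @slot v Numeric matrix T x D of centroids.
#' @slot h Length-T headings in [0, 2*pi).
#' @slot recording Per-frame recording labels.
#' @slot fps Frame rate in Hz.
#' @export
setClass("AlignedPose",
  representation(ytilde = "array", v = "matrix", h = "numeric",
                 recording = "character", fps = "numeric"))

#' Interpolate low-confidence keypoint detections
#'
#' Treats coordinates whose detection confidence falls below `threshold` as
#' missing and fills them by per-keypoint, per-axis linear interpolation
#' within each recording. Leading/trailing gaps take the nearest valid
#' value. Confidences are left untouched, so the operation is idempotent.
#'
#' @param series A [KeypointSeries-class].
#' @param threshold Confidence cutoff in [0, 1]; default 0.5.
#' @return A new `KeypointSeries` with interpolated coordinates.
#' @export
interpolateLowConfidence <- function(series, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  Y <- coords(series)
  cf <- confidences(series)
  dm <- dim(Y)
  ri <- recordingIndex(recordings(series))
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    for (k in seq_len(dm[2L])) {
      ok <- cf[rows, k] >= threshold
      if (!any(ok))
        stop(sprintf(
          "keypoint '%s' has no frames above the confidence threshold in recording '%s'",
          keypointNames(series)[k], ri$recording[r]))
      if (all(ok)) next
      tt <- seq_along(rows)
      for (d in seq_len(dm[3L])) {
        vals <- Y[rows, k, d]
        Y[rows, k, d] <- stats::approx(tt[ok], vals[ok], xout = tt,
                                       rule = 2)$y
      }
    }
  }
  KeypointSeries(Y, cf, fps(series), recordings(series),
                 keypointNames(series))
}

#' Add small uniform jitter to coordinates
#'
#' Adds i.i.d. Uniform(-halfWidth, halfWidth) noise to every coordinate.
#' Used only during the AR-HMM initialization phase to avoid degeneracy of
#' the PCA/AR fit on interpolated (locally collinear) stretches; the full
#' model is always fit to the original coordinates.
#'
#' @param series A [KeypointSeries-class].
#' @param halfWidth Half-width of the uniform interval; default 0.1 in the
#'   native coordinate units.
#' @return A new `KeypointSeries` with perturbed coordinates.
#' @export
augmentUniformNoise <- function(series, halfWidth = 0.1) {
  Y <- coords(series)
  if (halfWidth > 0)
    Y <- Y + array(runif(length(Y), -halfWidth, halfWidth), dim = dim(Y))
  KeypointSeries(Y, confidences(series), fps(series), recordings(series),
                 keypointNames(series))
}

#' Egocentric alignment along an anterior-posterior axis
#'
#' Per frame, the centroid is the unweighted mean over keypoints and the
#' heading is the angle of the (anterior - posterior) axis in the xy plane
#' (e.g. tail-to-nose). Coordinates are centered and rotated so the axis
#' points along +x: \eqn{\tilde Y = (Y - 1_K v^\top) R(h)^\top}. If the two
#' reference keypoints coincide in a frame (degenerate heading), the heading
#' is carried over from the previous frame (0 at a recording start).
#'
#' @param series A [KeypointSeries-class].
#' @param anterior,posterior Names (or indices) of the anterior and
#'   posterior reference keypoints.
#' @return An [AlignedPose-class].
#' @export
egocentricAlign <- function(series, anterior = 1L, posterior = nKeypoints(series)) {
  kn <- keypointNames(series)
  ai <- if (is.character(anterior)) match(anterior, kn) else as.integer(anterior)
  pi_ <- if (is.character(posterior)) match(posterior, kn) else as.integer(posterior)
  if (is.na(ai) || is.na(pi_)) stop("unknown reference keypoint name")
  if (ai == pi_) stop("anterior and posterior keypoints must differ")
  Y <- coords(series)
  dm <- dim(Y)
  T_ <- dm[1L]; K <- dm[2L]; D <- dm[3L]
  v <- matrix(0, T_, D)
  for (d in seq_len(D)) v[, d] <- rowMeans(Y[, , d, drop = TRUE])
  dx <- Y[, ai, 1L] - Y[, pi_, 1L]
  dy <- Y[, ai, 2L] - Y[, pi_, 2L]
  h <- atan2(dy, dx)
  degen <- sqrt(dx^2 + dy^2) < 1e-9
  if (any(degen)) {
    ri <- recordingIndex(recordings(series))
    for (r in seq_len(nrow(ri))) {
      rows <- ri$start[r]:ri$end[r]
      hr <- h[rows]; dg <- degen[rows]
      if (dg[1L]) hr[1L] <- 0
      for (t in seq_along(hr)[-1L]) if (dg[t]) hr[t] <- hr[t - 1L]
      h[rows] <- hr
    }
  }
  h <- wrapAngle(h)
  yt <- array(0, dim = dm)
  for (t in seq_len(T_))
    yt[t, , ] <- egocentrize(matrix(Y[t, , ], K, D), v[t, ], h[t])
  new("AlignedPose", ytilde = yt, v = v, h = h,
      recording = recordings(series), fps = fps(series))
}

## Flatten aligned poses into the (K-1)*D reduced coordinates Gamma' Y,
## keypoint-major / dimension-minor vec convention.
reducedPoseMatrix <- function(aligned, Gamma = NULL) {
  dm <- dim(aligned@ytilde)
  T_ <- dm[1L]; K <- dm[2L]; D <- dm[3L]
  if (is.null(Gamma)) Gamma <- gammaEmbedding(K)
  out <- matrix(0, T_, (K - 1L) * D)
  for (d in seq_len(D)) {
    proj <- aligned@ytilde[, , d, drop = TRUE] %*% Gamma   # T x (K-1)
    out[, seq.int(d, by = D, length.out = K - 1L)] <- proj
  }
  out
}

## Inverse of reducedPoseMatrix's flattening for a single frame:
## (K-1)*D vector -> K x D centered pose via Gamma.
reducedToPose <- function(yvec, Gamma) {
  K <- nrow(Gamma); D <- length(yvec) / (K - 1L)
  mat <- matrix(yvec, nrow = D)           # D x (K-1), dimension-minor
  Gamma %*% t(mat)                        # K x D
}

#' Whitened PCA of aligned poses
#'
#' Projects the \eqn{\Gamma^\top}-reduced aligned poses onto the smallest
#' number of principal components whose cumulative explained variance
#' reaches `varianceTarget`, with whitening (unit variance per component).
#' Returns the loading matrix `C` and offset `d` that map a latent pose
#' back to the reduced coordinate space: `y ~ C x + d`. These initialize
#' (and by default remain) the observation parameters of the full model.
#'
#' @param aligned An [AlignedPose-class].
#' @param varianceTarget Fraction of total variance to retain, in (0, 1];
#'   default 0.9.
#' @param maxDim Optional cap on the number of components.
#' @return List with `C` ((K-1)D x M), `d` (length (K-1)D), `M`, `x`
#'   (T x M whitened projections), `explained` (per-component variance
#'   fractions), and `Gamma`.
#' @export
fitPCAWhiten <- function(aligned, varianceTarget = 0.9, maxDim = Inf) {
  stopifnot(varianceTarget > 0, varianceTarget <= 1)
  K <- dim(aligned@ytilde)[2L]
  Gamma <- gammaEmbedding(K)
  Yr <- reducedPoseMatrix(aligned, Gamma)
  if (nrow(Yr) < 2L) stop("need at least 2 frames for PCA")
  d <- colMeans(Yr)
  Yc <- sweep(Yr, 2L, d)
  sv <- svd(Yc, nu = 0)
  ev <- sv$d^2 / (nrow(Yc) - 1L)          # component variances (sample)
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate data: zero total variance")
  frac <- ev / tot
  cum <- cumsum(frac)
  M <- which(cum >= varianceTarget - 1e-12)[1L]
  if (is.na(M)) stop("variance target unreachable")
  M <- min(M, maxDim)
  V <- sv$v[, seq_len(M), drop = FALSE]
  ## deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(M)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  lam <- ev[seq_len(M)]
  lam <- pmax(lam, 1e-300)
  C <- V %*% diag(sqrt(lam), M)
  x <- Yc %*% V %*% diag(1 / sqrt(lam), M)
  list(C = C, d = d, M = M, x = x, explained = frac, Gamma = Gamma)
}

## Gaussian kernel smoothing of columns of a matrix (sigma in frames),
## renormalized at the edges; never crosses recording boundaries (callers
## pass one recording at a time).
gaussianSmooth <- function(mat, sigma = 1) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  T_ <- nrow(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    padded <- c(rep(mat[1L, j], half), mat[, j], rep(mat[T_, j], half))
    sm <- stats::filter(padded, kern / sum(kern), sides = 2)
    out[, j] <- sm[(half + 1L):(half + T_)]
  }
  out
}

#' Keypoint change score
#'
#' Z-scored total frame-to-frame displacement of egocentrically aligned,
#' Gaussian-smoothed (sigma = 1 frame) keypoints:
#' sum over keypoints of the Euclidean step length, then z-scored over valid
#' frames. Spikes in the score mark abrupt pose changes. The first frame of
#' each recording has no predecessor and is set to 0; smoothing and
#' differencing never cross recording boundaries. Rigid whole-body motion
#' contributes nothing (it is removed by the alignment).
#'
#' @param series A [KeypointSeries-class].
#' @param anterior,posterior Reference keypoints for alignment; see
#'   [egocentricAlign()].
#' @return Numeric length-T score.
#' @export
changeScore <- function(series, anterior = 1L, posterior = nKeypoints(series)) {
  if (nFrames(series) < 3L) stop("need at least 3 frames")
  al <- egocentricAlign(series, anterior, posterior)
  dm <- dim(al@ytilde)
  T_ <- dm[1L]; K <- dm[2L]; D <- dm[3L]
  flat <- matrix(al@ytilde, T_, K * D)
  ri <- recordingIndex(al@recording)
  disp <- numeric(T_)
  first <- logical(T_)
  for (r in seq_len(nrow(ri))) {
    rows <- ri$start[r]:ri$end[r]
    sm <- gaussianSmooth(flat[rows, , drop = FALSE], sigma = 1)
    dstep <- diff(sm)                      # (n-1) x KD
    step2 <- dstep^2
    ## per-keypoint Euclidean norms, summed over keypoints
    tot <- numeric(nrow(dstep))
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * D + 1L):(k * D)
      tot <- tot + sqrt(rowSums(step2[, idx, drop = FALSE]))
    }
    disp[rows] <- c(0, tot)
    first[rows[1L]] <- TRUE
  }
  valid <- !first
  mu <- mean(disp[valid])
  sdv <- sd(disp[valid])
  if (!is.finite(sdv) || sdv < 1e-12) return(numeric(T_))
  out <- (disp - mu) / sdv
  out[first] <- 0
  out
}
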