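## Post-fit syllable analytics.

#' Extract syllable instances and state frequencies
#'
#' A syllable instance is a maximal run of consecutive frames assigned the
#' same discrete state within one recording. States whose overall frame
#' frequency falls below `minFrequency` are flagged as rare/excluded
#' (default threshold 0.5 percent).
#'
#' @param z Integer state sequence.
#' @param recording Per-frame recording labels.
#' @param fps Frame rate in Hz (for durations in ms).
#' @param minFrequency Frame-frequency exclusion threshold; default 0.005.
#' @return List with `instances` (data frame: state, start, end, recording,
#'   durationFrames, durationMs, excluded) and `frequencies` (data frame:
#'   state, frames, frequency, excluded).
#' @export
extractInstances <- function(z, recording = rep("rec1", length(z)),
                             fps = 30, minFrequency = 0.005) {
  T_ <- length(z)
  ri <- recordingIndex(recording)
  rows <- list()
  for (r in seq_len(nrow(ri))) {
    seg <- ri$start[r]:ri$end[r]
    runs <- rle(z[seg])
    en <- cumsum(runs$lengths)
    st <- en - runs$lengths + 1L
    rows[[r]] <- data.frame(state = runs$values,
                            start = seg[st], end = seg[en],
                            recording = ri$recording[r],
                            stringsAsFactors = FALSE)
  }
  inst <- do.call(rbind, rows)
  inst$durationFrames <- inst$end - inst$start + 1L
  inst$durationMs <- inst$durationFrames * 1000 / fps
  counts <- tapply(inst$durationFrames, inst$state, sum)
  freq <- data.frame(state = as.integer(names(counts)),
                     frames = as.integer(counts))
  freq$frequency <- freq$frames / T_
  freq$excluded <- freq$frequency < minFrequency
  inst$excluded <- freq$excluded[match(inst$state, freq$state)]
  list(instances = inst, frequencies = freq)
}

#' Cross-syllable likelihood matrix
#'
#' Entry (n, m) is the average, over instances of syllable n, of the ratio
#' of the instance's AR density under syllable m's dynamics to its density
#' under syllable n's own dynamics:
#' \deqn{C_{nm} = \frac{1}{|I(n)|} \sum_{(t_s..t_e) \in I(n)}
#'   \frac{P(x_{t_s..t_e} \mid A_m, b_m, Q_m)}
#'        {P(x_{t_s..t_e} \mid A_n, b_n, Q_n)}.}
#' Computed in log space per instance and exponentiated, so the diagonal is
#' exactly 1. Well-separated syllables give off-diagonal entries below 1.
#' Conditioning uses the actual preceding frames of x (zero-padded at
#' recording starts).
#'
#' @param z Integer state sequence.
#' @param x T x M latent pose trajectory.
#' @param ar AR parameter list (`A`, `b`, `Q`).
#' @param recording Per-frame recording labels.
#' @param states States to include (default: all with >= 1 instance among
#'   1..N from the AR parameter array).
#' @return N x N matrix; rows of states with zero instances are NaN.
#' @export
crossSyllableLikelihoods <- function(z, x, ar,
                                     recording = rep("rec1", length(z)),
                                     states = NULL) {
  N <- dim(ar$A)[1L]
  if (is.null(states)) states <- seq_len(N)
  ll <- arLogLikelihoods(x, ar, recording, maskFirst = FALSE)
  inst <- extractInstances(z, recording, minFrequency = 0)$instances
  C <- matrix(NaN, length(states), length(states),
              dimnames = list(states, states))
  instLogDens <- function(i0, i1) colSums(ll[i0:i1, , drop = FALSE])
  for (ni in seq_along(states)) {
    n <- states[ni]
    sub <- inst[inst$state == n, , drop = FALSE]
    if (!nrow(sub)) next
    acc <- matrix(0, nrow(sub), length(states))
    for (r in seq_len(nrow(sub))) {
      ld <- instLogDens(sub$start[r], sub$end[r])
      acc[r, ] <- exp(ld[states] - ld[n])
    }
    C[ni, ] <- colMeans(acc)
  }
  C
}

#' Onset-anchored trajectories and per-syllable summaries
#'
#' For each syllable instance with onset frame T, the trajectory is the
#' sequence of poses from T-5 to T+15 frames, all egocentrically aligned
#' by the centroid and heading *at onset*:
#' \eqn{X_T = [F(v_T, h_T; y_{T-5}), \ldots, F(v_T, h_T; y_{T+15})]}.
#' Instances whose window leaves the recording are dropped. Per syllable
#' (with more than `nNeighbors` usable instances) a representative
#' instance is chosen by a local-density criterion: minimize the ratio of
#' the mean distance to its `nNeighbors` nearest same-syllable trajectories
#' to the mean distance to its `nNeighbors` nearest trajectories overall.
#' The final trajectory is the mean over the representative's `nNeighbors`
#' nearest same-syllable neighbors, down-sampled to the 10 poses at onset
#' offsets -5, -3, ..., +13 frames (at 30 Hz: 165 ms before to 433 ms
#' after onset).
#'
#' @param series The [KeypointSeries-class].
#' @param v T x D centroids and `h` length-T headings (model latents).
#' @param h See above.
#' @param z Integer state sequence.
#' @param nNeighbors Neighborhood size; default 50.
#' @param minFrequency Rare-state exclusion threshold; default 0.005.
#' @return Named list per syllable: `representative` (instance row),
#'   `trajectory` (10 x K x D array), `nInstances`, `neighborCount`.
#' @export
syllableTrajectories <- function(series, v, h, z, nNeighbors = 50L,
                                 minFrequency = 0.005) {
  Y <- coords(series)
  K <- nKeypoints(series); D <- nDims(series)
  rec <- recordings(series)
  ex <- extractInstances(z, rec, fps(series), minFrequency)
  inst <- ex$instances
  ri <- recordingIndex(rec)
  segEnd <- ri$end[match(inst$recording, ri$recording)]
  segStart <- ri$start[match(inst$recording, ri$recording)]
  ok <- inst$start - 5L >= segStart & inst$start + 15L <= segEnd &
    !inst$excluded
  inst <- inst[ok, , drop = FALSE]
  if (!nrow(inst)) return(list())
  winLen <- 21L
  traj <- matrix(0, nrow(inst), winLen * K * D)
  for (r in seq_len(nrow(inst))) {
    Tt <- inst$start[r]
    frames <- (Tt - 5L):(Tt + 15L)
    Xr <- array(0, dim = c(winLen, K, D))
    for (w in seq_along(frames))
      Xr[w, , ] <- egocentrize(matrix(Y[frames[w], , ], K, D),
                               v[Tt, ], h[Tt])
    traj[r, ] <- as.numeric(Xr)
  }
  out <- list()
  nAll <- nrow(inst)
  dAll <- as.matrix(dist(traj))
  for (st in sort(unique(inst$state))) {
    idx <- which(inst$state == st)
    if (length(idx) <= nNeighbors) next
    kLoc <- min(nNeighbors, length(idx) - 1L)
    kGlob <- min(nNeighbors, nAll - 1L)
    ratio <- numeric(length(idx))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      dLoc <- sort(dAll[i, setdiff(idx, i)])[seq_len(kLoc)]
      dGlob <- sort(dAll[i, -i])[seq_len(kGlob)]
      ratio[ii] <- mean(dLoc) / mean(dGlob)
    }
    ## degenerate geometry (coincident trajectories): fall back to instance
    ## order, the documented tie-break
    ratio[!is.finite(ratio)] <- 1
    repI <- idx[which.min(ratio)]
    others <- setdiff(idx, repI)
    nn <- others[order(dAll[repI, others])][seq_len(kLoc)]
    finalFlat <- colMeans(traj[nn, , drop = FALSE])
    finalArr <- array(finalFlat, dim = c(winLen, K, D))
    keep <- seq(1L, winLen, by = 2L)[1:10]       # offsets -5, -3, ..., +13
    out[[as.character(st)]] <- list(
      representative = inst[repI, ],
      trajectory = finalArr[keep, , , drop = FALSE],
      nInstances = length(idx),
      neighborCount = kLoc)
  }
  out
}

#' Ensemble per-frame transition probability
#'
#' Given state sequences from several model fits of the same data, the
#' transition probability at frame t is the fraction of fits in which a
#' syllable transition occurred at t (i.e. \eqn{z_t \ne z_{t-1}}). The
#' first frame of each recording is 0 by convention.
#'
#' @param zList List of equal-length integer state sequences.
#' @param recording Per-frame recording labels.
#' @return Numeric length-T vector in [0, 1].
#' @export
ensembleTransitionProbability <- function(zList,
                                          recording = rep("rec1", length(zList[[1L]]))) {
  lens <- vapply(zList, length, integer(1L))
  if (length(unique(lens)) != 1L) stop("ragged ensemble: unequal lengths")
  T_ <- lens[1L]
  p <- numeric(T_)
  for (zi in zList) p <- p + c(FALSE, zi[-1L] != zi[-T_])
  p <- p / length(zList)
  ri <- recordingIndex(recording)
  p[ri$start] <- 0
  p
}
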