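#' Orthonormal embedding of the centered-pose subspace
#'
#' Returns the K x (K-1) matrix \eqn{\Gamma} whose columns form an orthonormal
#' basis of the subspace of centered keypoint arrangements, i.e. the span of
#' vectors summing to zero. It satisfies \eqn{\Gamma^\top \Gamma = I_{K-1}},
#' \eqn{\Gamma^\top 1_K = 0} and \eqn{\Gamma \Gamma^\top = I_K - 1_{K \times K}/K}.
#' Any D-dimensional pose with a zero mean over keypoints can be represented
#' losslessly in the (K-1)-dimensional coordinates \eqn{\Gamma^\top Y}.
#'
#' The basis is the (transposed) sub-Helmert basis, which is fully
#' deterministic: no dependence on numerical eigensolvers. Column j has
#' j leading entries equal to \eqn{1/\sqrt{j(j+1)}} followed by
#' \eqn{-j/\sqrt{j(j+1)}}; signs are fixed so the first nonzero entry of each
#' column is positive.
#'
#' @param K Number of keypoints (integer, >= 2).
#' @return A numeric K x (K-1) matrix.
#' @examples
#' G <- gammaEmbedding(5)
#' max(abs(crossprod(G) - diag(4)))           # orthonormal columns
#' max(abs(tcrossprod(G) - (diag(5) - 1/5)))  # centering projector
#' @export
gammaEmbedding <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L)
    stop("gammaEmbedding: K must be an integer >= 2")
  G <- matrix(0, K, K - 1L)
  for (j in seq_len(K - 1L)) {
    s <- 1 / sqrt(j * (j + 1))
    G[seq_len(j), j] <- s
    G[j + 1L, j] <- -j * s
  }
  G
}

#' Prior noise scale from detector confidence
#'
#' Logistic curve mapping a keypoint detection confidence in [0, 1] to the
#' prior scale \eqn{s_0} of the observation noise:
#' \deqn{s_0(c) = 1 + 100 \,(1 + e^{20(c - 0.4)})^{-1}.}
#' High-confidence detections get \eqn{s_0 \approx 1} (low-noise regime),
#' low-confidence ones approach 101 (high-noise regime); the midpoint
#' \eqn{s_0 = 51} sits at confidence 0.4.
#'
#' @param conf Numeric vector/matrix of confidences (finite).
#' @return Prior noise scales, same shape as `conf`, in (1, 101).
#' @seealso [confidenceFromS0()] for the inverse, used by the simulator.
#' @export
s0FromConfidence <- function(conf) {
  1 + 100 / (1 + exp(20 * (conf - 0.4)))
}

#' Inverse of the confidence-to-noise-scale curve
#'
#' Maps a prior noise scale back to the detector confidence that would have
#' produced it under [s0FromConfidence()], clipped to [0, 1]. Used by the
#' simulator to emit confidences consistent with its drawn noise scales.
#'
#' @param s0 Numeric vector of noise scales in (1, 101).
#' @return Confidences in [0, 1].
#' @export
confidenceFromS0 <- function(s0) {
  s0 <- pmin(pmax(s0, 1 + 1e-10), 101 - 1e-10)
  conf <- 0.4 + log(100 / (s0 - 1) - 1) / 20
  pmin(pmax(conf, 0), 1)
}

#' Planar rotation matrix acting on coordinate rows
#'
#' Rotation by heading angle `h` (radians, counterclockwise, measured from the
#' +x axis) in the xy plane. The convention throughout the package is that
#' poses are stored as K x D matrices with one keypoint per row, and a pose is
#' rotated as `pose %*% rotationMatrix(h, D)`; a row point (1, 0) maps to
#' (cos h, sin h). For D = 3 the z axis is left untouched.
#'
#' @param h Heading angle in radians.
#' @param D Spatial dimension, 2 or 3.
#' @return A D x D rotation matrix.
#' @export
rotationMatrix <- function(h, D = 2L) {
  R <- diag(D)
  c_ <- cos(h); s_ <- sin(h)
  R[1L, 1L] <- c_; R[1L, 2L] <- s_
  R[2L, 1L] <- -s_; R[2L, 2L] <- c_
  R
}

#' Rigid transform of a centered pose into world coordinates
#'
#' Maps a centered/oriented pose to world coordinates by rotating
#' counterclockwise by heading `h` in the xy plane and translating by the
#' centroid `v`: \eqn{Y = \tilde Y R(h) + 1_K v^\top}. The inverse operation
#' (egocentrizing a world pose) is `rigidTransform(Y, -v %*% R(-h), -h)`, or
#' more directly `(Y - v) %*% t(R(h))`; see [egocentrize()].
#'
#' @param pose K x D matrix of centered coordinates (one keypoint per row).
#' @param v Length-D centroid.
#' @param h Heading angle in radians.
#' @return K x D matrix of world coordinates.
#' @export
rigidTransform <- function(pose, v, h) {
  pose <- as.matrix(pose)
  D <- ncol(pose)
  if (length(v) != D)
    stop("rigidTransform: centroid length must equal pose dimension")
  pose %*% rotationMatrix(h, D) + rep(1, nrow(pose)) %*% t(v)
}

#' Egocentrize a world pose
#'
#' Removes centroid and heading: \eqn{\tilde Y = (Y - 1_K v^\top) R(h)^\top}.
#' Exact inverse of [rigidTransform()].
#'
#' @inheritParams rigidTransform
#' @param pose K x D matrix of world coordinates.
#' @return K x D centered/oriented pose.
#' @export
egocentrize <- function(pose, v, h) {
  pose <- as.matrix(pose)
  sweep(pose, 2L, v) %*% t(rotationMatrix(h, ncol(pose)))
}

#' Wrap angles to [0, 2*pi)
#' @param h Numeric vector of angles in radians.
#' @return Angles wrapped to [0, 2*pi).
#' @export
wrapAngle <- function(h) {
  h %% (2 * pi)
}

## Smallest signed difference a - b on the circle, in (-pi, pi].
circularDiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}
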