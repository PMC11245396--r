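#' @import methods
#' @importFrom stats rnorm runif rchisq rgamma rbeta rbinom median sd var
#'   quantile dnorm ks.test chisq.test pchisq cov prcomp dist
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib poseSLDS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' KeypointSeries: multi-recording keypoint coordinate time series
#'
#' Container for the raw output of a markerless pose tracker: per-frame
#' coordinates of K anatomical keypoints in D = 2 or 3 dimensions, per-frame
#' per-keypoint detector confidences, a frame rate, and a recording label per
#' frame. Frames belonging to one recording must be contiguous; recording
#' boundaries break all temporal couplings downstream (the syllable Markov
#' chain, autoregressive pose dynamics and the centroid random walk).
#'
#' @slot coords Numeric array T x K x D (length units of the tracker,
#'   typically pixels or mm).
#' @slot confidences Numeric matrix T x K with entries in [0, 1]. Missing
#'   confidence input is represented as all ones.
#' @slot fps Frame rate in Hz.
#' @slot recording Character vector of length T; per-frame recording label.
#' @slot keypointNames Character vector of length K.
#' @export
setClass("KeypointSeries",
  representation(
    coords = "array",
    confidences = "matrix",
    fps = "numeric",
    recording = "character",
    keypointNames = "character"
  )
)

setValidity("KeypointSeries", function(object) {
  msg <- character()
  dm <- dim(object@coords)
  if (length(dm) != 3L)
    return("coords must be a T x K x D array")
  T_ <- dm[1L]; K <- dm[2L]; D <- dm[3L]
  if (T_ < 1L) msg <- c(msg, "need at least one frame")
  if (K < 3L) msg <- c(msg, "need at least 3 keypoints")
  if (!D %in% c(2L, 3L)) msg <- c(msg, "D must be 2 or 3")
  if (!all(dim(object@confidences) == c(T_, K)))
    msg <- c(msg, "confidences must be T x K")
  cf <- object@confidences
  if (any(!is.finite(cf)) || any(cf < 0) || any(cf > 1))
    msg <- c(msg, "confidences must be finite and in [0, 1]")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (length(object@recording) != T_)
    msg <- c(msg, "recording labels must have length T")
  if (anyDuplicated(rle(object@recording)$values))
    msg <- c(msg, "frames of one recording must be contiguous")
  if (length(object@keypointNames) != K)
    msg <- c(msg, "keypointNames must have length K")
  if (length(msg)) msg else TRUE
})

#' Construct a KeypointSeries
#'
#' @param coords Numeric array T x K x D.
#' @param confidences Optional T x K matrix in [0, 1]; defaults to all ones.
#' @param fps Frame rate in Hz.
#' @param recording Optional per-frame recording labels (length T or 1);
#'   default a single recording `"rec1"`.
#' @param keypointNames Optional keypoint names; default `kp1..kpK`.
#' @return A [KeypointSeries-class] object.
#' @examples
#' y <- array(rnorm(30), dim = c(5, 3, 2))
#' ks <- KeypointSeries(y, fps = 30)
#' nFrames(ks); nKeypoints(ks)
#' @export
KeypointSeries <- function(coords, confidences = NULL, fps,
                           recording = NULL, keypointNames = NULL) {
  coords <- unname(coords)
  dm <- dim(coords)
  if (is.null(confidences))
    confidences <- matrix(1, dm[1L], dm[2L])
  confidences <- unname(as.matrix(confidences))
  if (is.null(recording)) recording <- "rec1"
  if (length(recording) == 1L) recording <- rep(recording, dm[1L])
  if (is.null(keypointNames)) keypointNames <- paste0("kp", seq_len(dm[2L]))
  new("KeypointSeries", coords = coords, confidences = confidences,
      fps = as.numeric(fps), recording = as.character(recording),
      keypointNames = as.character(keypointNames))
}

#' KeypointSLDS: one fitted (or simulated) model state
#'
#' Holds every latent variable and parameter of one switching linear
#' dynamical system fit: the transition parameters (global state weights
#' `beta` and row-stochastic matrix `pi`), the per-state autoregressive
#' dynamics (`A`, `b`, `Q`), the observation parameters (latent-to-pose
#' loading `C`, offset `d`, the centered-subspace embedding `Gamma`,
#' per-keypoint variances `sigmasq`, and per-frame noise scales `s` with
#' their confidence-derived priors `s0`), the latent states (syllable
#' sequence `z`, continuous pose `x`, centroid `v`, heading `h`), and the
#' hyperparameter list.
#'
#' @slot hyper Named list of hyperparameters; see [defaultHyperparams()].
#' @slot trans List with elements `beta` (length N) and `pi` (N x N).
#' @slot ar List with `A` (N x M x LM array), `b` (N x M), `Q` (N x M x M).
#' @slot obs List with `C` ((K-1)D x M), `d` (length (K-1)D), `Gamma`
#'   (K x (K-1)), `sigmasq` (length K), `s` (T x K), `s0` (T x K).
#' @slot latent List with `z` (length T, values in 1..N), `x` (T x M),
#'   `v` (T x D), `h` (length T, wrapped to [0, 2pi)).
#' @slot seed Integer seed recorded for the fit.
#' @export
setClass("KeypointSLDS",
  representation(
    hyper = "list",
    trans = "list",
    ar = "list",
    obs = "list",
    latent = "list",
    seed = "integer"
  )
)

setValidity("KeypointSLDS", function(object) {
  msg <- character()
  tr <- object@trans; ar <- object@ar; lt <- object@latent
  N <- length(tr$beta)
  if (N > 0) {
    if (abs(sum(tr$beta) - 1) > 1e-8) msg <- c(msg, "beta must sum to 1")
    if (any(tr$beta < 0)) msg <- c(msg, "beta must be nonnegative")
    if (!all(dim(tr$pi) == c(N, N))) msg <- c(msg, "pi must be N x N")
    else {
      if (any(tr$pi < 0)) msg <- c(msg, "pi entries must be nonnegative")
      if (max(abs(rowSums(tr$pi) - 1)) > 1e-8)
        msg <- c(msg, "pi rows must sum to 1")
    }
    if (!is.null(lt$z) && length(lt$z) &&
        (min(lt$z) < 1L || max(lt$z) > N))
      msg <- c(msg, "z values must lie in 1..N")
  }
  if (!is.null(ar$Q)) {
    for (i in seq_len(dim(ar$Q)[1L])) {
      Qi <- ar$Q[i, , , drop = TRUE]
      if (max(abs(Qi - t(Qi))) > 1e-8) {
        msg <- c(msg, "each Q_i must be symmetric"); break
      }
    }
  }
  if (!is.null(lt$h) && length(lt$h) &&
      (min(lt$h) < 0 || max(lt$h) >= 2 * pi + 1e-12))
    msg <- c(msg, "headings must be wrapped to [0, 2pi)")
  if (length(msg)) msg else TRUE
})

## internal constructor (no validity-triggering partial states)
newKeypointSLDS <- function(hyper, trans, ar, obs, latent, seed = NA_integer_) {
  new("KeypointSLDS", hyper = hyper, trans = trans, ar = ar, obs = obs,
      latent = latent, seed = as.integer(seed))
}
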