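#' @rdname KeypointSeries-class
#' @param object,x A `KeypointSeries` or `KeypointSLDS`.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("keypointNames", function(x) standardGeneric("keypointNames"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("nKeypoints", function(x) standardGeneric("nKeypoints"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("nDims", function(x) standardGeneric("nDims"))

#' @rdname KeypointSLDS-class
#' @export
setGeneric("syllables", function(x) standardGeneric("syllables"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("latentPose", function(x) standardGeneric("latentPose"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("headings", function(x) standardGeneric("headings"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("arParams", function(x) standardGeneric("arParams"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("obsParams", function(x) standardGeneric("obsParams"))
#' @rdname KeypointSLDS-class
#' @export
setGeneric("hyperparams", function(x) standardGeneric("hyperparams"))

setMethod("coords", "KeypointSeries", function(x) x@coords)
setMethod("confidences", "KeypointSeries", function(x) x@confidences)
setMethod("fps", "KeypointSeries", function(x) x@fps)
setMethod("recordings", "KeypointSeries", function(x) x@recording)
setMethod("keypointNames", "KeypointSeries", function(x) x@keypointNames)
setMethod("nFrames", "KeypointSeries", function(x) dim(x@coords)[1L])
setMethod("nKeypoints", "KeypointSeries", function(x) dim(x@coords)[2L])
setMethod("nDims", "KeypointSeries", function(x) dim(x@coords)[3L])

setMethod("syllables", "KeypointSLDS", function(x) x@latent$z)
setMethod("latentPose", "KeypointSLDS", function(x) x@latent$x)
setMethod("centroids", "KeypointSLDS", function(x) x@latent$v)
setMethod("headings", "KeypointSLDS", function(x) x@latent$h)
setMethod("transitionMatrix", "KeypointSLDS", function(x) x@trans$pi)
setMethod("arParams", "KeypointSLDS", function(x) x@ar)
setMethod("obsParams", "KeypointSLDS", function(x) x@obs)
setMethod("hyperparams", "KeypointSLDS", function(x) x@hyper)

setMethod("show", "KeypointSeries", function(object) {
  dm <- dim(object@coords)
  cat(sprintf(
    "KeypointSeries: %d frames, %d keypoints, %dD, %.6g Hz, %d recording(s)\n",
    dm[1L], dm[2L], dm[3L], object@fps, length(unique(object@recording))))
  cat("  keypoints:", paste(object@keypointNames, collapse = ", "), "\n")
  lo <- min(object@confidences); hi <- max(object@confidences)
  cat(sprintf("  confidence range: [%.3g, %.3g]\n", lo, hi))
  invisible(object)
})

setMethod("show", "KeypointSLDS", function(object) {
  N <- length(object@trans$beta)
  z <- object@latent$z
  cat(sprintf("KeypointSLDS model: N = %d states", N))
  if (!is.null(object@hyper$M))
    cat(sprintf(", M = %d latent dims, L = %d lags", object@hyper$M,
                object@hyper$L))
  cat("\n")
  if (length(z)) {
    used <- length(unique(z))
    cat(sprintf("  %d frames assigned; %d states in use\n", length(z), used))
  }
  invisible(object)
})

## Row index ranges of each recording, in order of appearance.
recordingIndex <- function(recording) {
  r <- rle(recording)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(recording = r$values, start = starts, end = ends,
             stringsAsFactors = FALSE)
}
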