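#' Default hyperparameters of the model
#'
#' Returns the full list of fixed prior constants. Defaults follow the
#' standard settings for rodent keypoint data:
#' N = 100 maximum states, transition concentrations gamma = 1000 and
#' alpha = 100, stickiness `kappa` calibrated per dataset (see
#' [calibrateKappa()]), AR lag order L = 3, matrix-normal inverse-Wishart
#' prior with nu0 = M + 2, S0 = 0.01 I_M, M0 = [0 | I_M | 1] ("copy the last
#' pose"), K0 = 10 I_{LM+1}; observation noise priors sigma0^2 = 1 with
#' nu_sigma = 1e5 (pinning per-keypoint variances near 1) and nu_s = 5 for
#' the per-frame scales; centroid random-walk variance sigma_loc^2 = 0.4
#' (squared length units per frame); confidence threshold 0.5 for
#' interpolation; kappa-calibration target duration 400 ms.
#'
#' @param M Latent pose dimension (from PCA; see [fitPCAWhiten()]).
#' @param N Maximum number of discrete states.
#' @param L AR lag order.
#' @param kappa Stickiness; `NA` until calibrated.
#' @param ... Overrides for any other element.
#' @return Named list of hyperparameters.
#' @export
defaultHyperparams <- function(M, N = 100L, L = 3L, kappa = NA_real_, ...) {
  M <- as.integer(M)
  hp <- list(
    N = as.integer(N),
    gamma = 1000,
    alpha = 100,
    kappa = kappa,
    L = as.integer(L),
    M = M,
    nu0 = M + 2,
    S0 = 0.01 * diag(M),
    M0 = cbind(matrix(0, M, M * (as.integer(L) - 1L)), diag(M),
               matrix(1, M, 1)),
    K0 = 10 * diag(M * as.integer(L) + 1L),
    sigmasq0 = 1,
    nu_sigma = 1e5,
    nu_s = 5,
    sigmasq_loc = 0.4,
    sigmasq_v1 = 100,
    sigmasq_C = 10,
    conf_threshold = 0.5,
    target_duration = 400
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad))
    stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "))
  hp[names(dots)] <- dots
  validateHyperparams(hp)
  hp
}

validateHyperparams <- function(hp) {
  stopifnot(
    hp$N >= 1, hp$L >= 1, hp$M >= 1,
    hp$nu0 > hp$M - 1,
    hp$gamma > 0, hp$alpha > 0,
    is.na(hp$kappa) || hp$kappa >= 0,
    all(diag(hp$S0) > 0),
    hp$sigmasq0 > 0, hp$nu_sigma > 0, hp$nu_s > 0,
    hp$sigmasq_loc > 0, hp$sigmasq_v1 > 0, hp$sigmasq_C > 0,
    hp$conf_threshold >= 0, hp$conf_threshold <= 1,
    hp$target_duration > 0,
    all(dim(hp$M0) == c(hp$M, hp$L * hp$M + 1L)),
    all(dim(hp$K0) == c(hp$L * hp$M + 1L, hp$L * hp$M + 1L))
  )
  invisible(TRUE)
}
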