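## Shared helpers for the test suite. All fixtures are generated in code.

## greedy label alignment: best frame accuracy of zHat against zTrue after
## matching each inferred label to one true label
alignedAccuracy <- function(zHat, zTrue) {
  tab <- table(zHat, zTrue)
  used <- integer(0)
  acc <- 0
  for (i in order(-apply(tab, 1L, max))) {
    avail <- setdiff(seq_len(ncol(tab)), used)
    if (!length(avail)) break          # extra inferred labels contribute 0
    j <- avail[which.max(tab[i, avail])]
    acc <- acc + as.numeric(tab[i, j])
    used <- c(used, j)
  }
  acc / length(zHat)
}

## map each inferred label to the true label it overlaps most
labelMap <- function(zHat, zTrue) {
  tab <- table(zHat, zTrue)
  map <- as.integer(colnames(tab))[apply(tab, 1L, which.max)]
  names(map) <- rownames(tab)
  map
}

## small fully-specified model + series for conditional-sampler tests
tinyModelFixture <- function(T_ = 5L, K = 4L, D = 2L, M = 2L, L = 2L,
                             N = 2L, seed = 71) {
  set.seed(seed)
  hp <- defaultHyperparams(M = M, N = N, L = L, kappa = 10, nu_sigma = 10)
  pars <- simulationParams(N, K, D, M, L)
  sim <- simulateKeypointSLDS(T_, K, D, 30, N, params = pars, hyper = hp)
  tr <- sim$truth
  model <- poseSLDS:::newKeypointSLDS(
    hp, list(beta = pars$beta, pi = pars$pi), pars$ar,
    list(C = pars$C, d = pars$d, Gamma = pars$Gamma, sigmasq = rep(1, K),
         s = tr@latent$s, s0 = tr@params$s0),
    list(z = tr@latent$z, x = tr@latent$x, v = tr@latent$v, h = tr@latent$h))
  list(model = model, series = sim$series, truth = tr, params = pars,
       hyper = hp)
}

## circular distance
circDist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}
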