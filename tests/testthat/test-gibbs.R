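## Conditional-sampler correctness against independent oracles.

test_that("centroid sampler matches the dense joint-Gaussian conditional", {
  fx <- tinyModelFixture(T_ = 4L, seed = 61)
  model <- fx$model; ser <- fx$series
  hp <- fx$hyper
  T_ <- nFrames(ser); D <- nDims(ser)
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  predW <- poseSLDS:::rotateToWorldAll(pred, model@latent$h)
  w <- 1 / sweep(model@obs$s, 2, model@obs$sigmasq, "*")
  prec <- rowSums(w)
  P <- diag(prec)
  P[1, 1] <- P[1, 1] + 1 / hp$sigmasq_v1
  for (t in 2:T_) {
    P[t, t] <- P[t, t] + 1 / hp$sigmasq_loc
    P[t - 1, t - 1] <- P[t - 1, t - 1] + 1 / hp$sigmasq_loc
    P[t, t - 1] <- P[t, t - 1] - 1 / hp$sigmasq_loc
    P[t - 1, t] <- P[t - 1, t] - 1 / hp$sigmasq_loc
  }
  Y <- coords(ser)
  rhs <- sapply(1:D, function(dd) rowSums(w * (Y[, , dd] - predW[, , dd])))
  mu <- solve(P, rhs)
  Sg <- solve(P)
  set.seed(611)
  n <- 3000
  draws <- array(0, c(n, T_, D))
  for (r in seq_len(n)) draws[r, , ] <- resampleCentroids(model, ser)
  se <- sqrt(max(diag(Sg)) / n)
  expect_lt(max(abs(apply(draws, c(2, 3), mean) - mu)), 4 * se)
  expect_lt(max(abs(cov(draws[, , 1]) - Sg)), 8 * max(Sg) / sqrt(n))
  ## near-frozen random walk: sampled centroid nearly constant
  model2 <- model
  model2@hyper$sigmasq_loc <- 1e-10
  v2 <- resampleCentroids(model2, ser)
  expect_lt(max(abs(diff(v2))), 1e-3)
})

test_that("latent-pose sampler matches the dense joint-Gaussian conditional", {
  fx <- tinyModelFixture(T_ = 5L, seed = 62)
  model <- fx$model; ser <- fx$series
  hp <- fx$hyper
  T_ <- nFrames(ser); D <- nDims(ser); K <- nKeypoints(ser)
  M <- hp$M; L <- hp$L
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  ego <- poseSLDS:::egocentrizeAll(coords(ser), model@latent$v,
                                   model@latent$h)
  w <- 1 / sweep(model@obs$s, 2, model@obs$sigmasq, "*")
  P <- matrix(0, T_ * M, T_ * M); r0 <- numeric(T_ * M)
  for (k in 1:K) {
    Bk <- matrix(ld$B[k, , ], nrow = D)
    for (t in 1:T_) {
      idx <- (t - 1) * M + 1:M
      P[idx, idx] <- P[idx, idx] + w[t, k] * crossprod(Bk)
      r0[idx] <- r0[idx] +
        w[t, k] * as.numeric(crossprod(Bk, ego[t, k, ] - ld$dmat[k, ]))
    }
  }
  z <- model@latent$z
  for (t in 1:T_) {
    i <- z[t]
    G <- cbind(-matrix(model@ar$A[i, , ], nrow = M), diag(M))
    J <- solve(matrix(model@ar$Q[i, , ], M, M))
    nlag <- min(L, t - 1)
    keep <- ((L - nlag) * M + 1):((L + 1) * M)
    Gs <- G[, keep, drop = FALSE]
    gidx <- as.numeric(sapply((t - nlag):t, function(f) (f - 1) * M + 1:M))
    P[gidx, gidx] <- P[gidx, gidx] + t(Gs) %*% J %*% Gs
    r0[gidx] <- r0[gidx] + as.numeric(t(Gs) %*% J %*% model@ar$b[i, ])
  }
  mu <- solve(P, r0)
  set.seed(621)
  n <- 3000
  draws <- matrix(0, n, T_ * M)
  for (r in seq_len(n))
    draws[r, ] <- as.numeric(t(resampleLatentPose(model, ser)))
  se <- sqrt(max(diag(solve(P))) / n)
  expect_lt(max(abs(colMeans(draws) - mu)), 4 * se)
  expect_lt(max(abs(cov(draws) - solve(P))), 8 * max(solve(P)) / sqrt(n))
})

test_that("noiseless emissions pin the latent pose to its projection", {
  fx <- tinyModelFixture(T_ = 6L, seed = 63)
  model <- fx$model; ser <- fx$series
  ## rebuild observations exactly at the model prediction, tiny noise scale
  D <- nDims(ser)
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  Y <- poseSLDS:::rotateToWorldAll(pred, model@latent$h)
  for (dd in 1:D) Y[, , dd] <- Y[, , dd] + model@latent$v[, dd]
  ser2 <- KeypointSeries(Y, confidences(ser), fps(ser))
  model@obs$s[] <- 1e-12
  x2 <- resampleLatentPose(model, ser2)
  expect_lt(max(abs(x2 - model@latent$x)), 1e-5)
})

test_that("heading sampler matches the raw observation likelihood", {
  fx <- tinyModelFixture(T_ = 3L, seed = 64)
  model <- fx$model; ser <- fx$series
  K <- nKeypoints(ser); D <- nDims(ser)
  ## inflate noise so the posterior is moderately concentrated
  model@obs$s <- model@obs$s * 400
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  t0 <- 2L
  gridLik <- function(hh) {
    ego <- egocentrize(matrix(coords(ser)[t0, , ], K, D),
                       model@latent$v[t0, ], hh)
    -0.5 * sum((ego - matrix(pred[t0, , ], K, D))^2 /
                 (model@obs$s[t0, ] * model@obs$sigmasq))
  }
  grid <- seq(0, 2 * pi, length.out = 5001)[-5001]
  lp <- vapply(grid, gridLik, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  set.seed(641)
  draws <- replicate(20000, resampleHeadings(model, ser)[t0])
  ## KS against the grid CDF
  cdf <- cumsum(p)
  u <- approx(grid, cdf, xout = draws, rule = 2)$y
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
  ## scaling all noise up scales concentration down (sd up by ~sqrt(c))
  model4 <- model
  model4@obs$s <- model@obs$s * 4
  d4 <- replicate(8000, resampleHeadings(model4, ser)[t0])
  circSd <- function(x) sqrt(-2 * log(sqrt(mean(cos(x))^2 + mean(sin(x))^2)))
  expect_equal(circSd(d4) / circSd(draws), 2, tolerance = 0.15)
})

test_that("zero concentration gives uniform headings", {
  fx <- tinyModelFixture(T_ = 3L, seed = 65)
  model <- fx$model
  ## zero predicted pose and centered observation -> a = b = 0
  model@obs$C[] <- 0; model@obs$d[] <- 0
  Y <- coords(fx$series)
  for (dd in 1:2) Y[, , dd] <- model@latent$v[, dd]   # all keypoints at v
  ser0 <- KeypointSeries(Y, confidences(fx$series), fps(fx$series))
  set.seed(651)
  hs <- replicate(4000, resampleHeadings(model, ser0)[1L])
  expect_gt(ks.test(hs / (2 * pi), "punif")$p.value, 0.01)
})

test_that("noise-scale posterior matches its scaled-inverse-chi-squared form", {
  fx <- tinyModelFixture(T_ = 4L, seed = 66)
  model <- fx$model; ser <- fx$series
  hp <- fx$hyper
  D <- nDims(ser)
  ## zero residual: posterior is chi^-2(nu_s + D, nu_s s0 / (nu_s + D))
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  Y <- poseSLDS:::rotateToWorldAll(pred, model@latent$h)
  for (dd in 1:D) Y[, , dd] <- Y[, , dd] + model@latent$v[, dd]
  serExact <- KeypointSeries(Y, confidences(ser), fps(ser))
  set.seed(661)
  n <- 1e5
  draws <- matrix(0, n, 2)
  for (r in seq_len(n)) {
    s <- resampleScales(model, serExact)
    draws[r, ] <- c(s[1, 1], s[3, 2])
  }
  expect_true(all(draws > 0))
  nu <- hp$nu_s + D
  for (j in 1:2) {
    s0 <- model@obs$s0[c(1, 3)[j], c(1, 2)[j]]
    tau <- hp$nu_s * s0 / nu
    m <- nu * tau / (nu - 2)
    v <- 2 * nu^2 * tau^2 / ((nu - 2)^2 * (nu - 4))
    expect_lt(abs(mean(draws[, j]) - m), 3 * sqrt(v / n))
  }
  ## with residuals: mean matches the general closed form
  ego <- poseSLDS:::egocentrizeAll(coords(ser), model@latent$v,
                                   model@latent$h)
  sq <- poseSLDS:::egoResidualSq(ego, pred)
  tau11 <- (hp$nu_s * model@obs$s0[1, 1] +
              sq[1, 1] / model@obs$sigmasq[1]) / nu
  d2 <- replicate(n / 2, resampleScales(model, ser)[1, 1])
  m2 <- nu * tau11 / (nu - 2)
  v2 <- 2 * nu^2 * tau11^2 / ((nu - 2)^2 * (nu - 4))
  expect_lt(abs(mean(d2) - m2), 3 * sqrt(v2 / (n / 2)))
})

test_that("keypoint-variance posterior matches its conjugate form", {
  fx <- tinyModelFixture(T_ = 4L, seed = 67)
  model <- fx$model; ser <- fx$series
  hp <- fx$hyper           # nu_sigma = 10 in the fixture
  D <- nDims(ser); T_ <- nFrames(ser)
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  ego <- poseSLDS:::egocentrizeAll(coords(ser), model@latent$v,
                                   model@latent$h)
  sq <- poseSLDS:::egoResidualSq(ego, pred)
  Sy <- colSums(sq / model@obs$s)
  nu <- hp$nu_sigma + D * T_
  tau <- (hp$nu_sigma * hp$sigmasq0 + Sy) / nu
  set.seed(671)
  n <- 2e4
  draws <- t(replicate(n, resampleSigmasq(model, ser)))
  m <- nu * tau / (nu - 2)
  v <- 2 * nu^2 * tau^2 / ((nu - 2)^2 * (nu - 4))
  for (k in seq_len(nKeypoints(ser)))
    expect_lt(abs(mean(draws[, k]) - m[k]), 3 * sqrt(v[k] / n))
  ## default nu_sigma = 1e5 pins sigma^2 near 1 (CV < 1 percent)
  modelPin <- model
  modelPin@hyper$nu_sigma <- 1e5
  dp <- replicate(3000, resampleSigmasq(modelPin, ser)[1L])
  expect_lt(sd(dp) / mean(dp), 0.01)
  expect_equal(mean(dp), 1, tolerance = 0.05)
  ## monotonicity: inflating a residual raises the posterior scale
  ser2 <- ser
  Y2 <- coords(ser); Y2[2, 1, 1] <- Y2[2, 1, 1] + 50
  ser2 <- KeypointSeries(Y2, confidences(ser), fps(ser))
  d2 <- replicate(3000, resampleSigmasq(model, ser2)[1L])
  expect_gt(mean(d2), mean(draws[, 1]))
})

test_that("loading posterior recovers known C and d with abundant data", {
  set.seed(68)
  fxBig <- tinyModelFixture(T_ = 2000L, K = 5L, M = 2L, L = 1L, N = 1L,
                            seed = 68)
  model <- fxBig$model; ser <- fxBig$series
  model@hyper$sigmasq_C <- 1e4         # weak prior
  ## shrink noise for sharp identification
  cd <- resampleLoading(model, ser)
  expect_lt(max(abs(cd$C - model@obs$C)), 0.15)
  expect_lt(max(abs(cd$d - model@obs$d)), 0.15)
  ## tight prior collapses the draw toward zero
  model@hyper$sigmasq_C <- 1e-8
  cd0 <- resampleLoading(model, ser)
  expect_lt(max(abs(cd0$C)), 1e-2)
  expect_lt(max(abs(cd0$d)), 1e-2)
})

test_that("log joint is finite, decreases with residuals, and is label-symmetric", {
  fx <- tinyModelFixture(T_ = 30L, seed = 69)
  model <- fx$model; ser <- fx$series
  lj <- logJoint(model, ser)
  expect_true(is.finite(lj))
  ## doubling a residual strictly decreases the observation term
  Y2 <- coords(ser); Y2[5, 2, 1] <- Y2[5, 2, 1] + 30
  expect_lt(logJoint(model, KeypointSeries(Y2, confidences(ser), fps(ser))),
            lj)
  ## term-by-term oracle: observation block recomputed by brute force
  D <- nDims(ser); K <- nKeypoints(ser)
  ld <- poseSLDS:::keypointLoadings(model@obs$C, model@obs$d,
                                    model@obs$Gamma, D)
  pred <- poseSLDS:::predictedEgoPose(model@latent$x, ld)
  obsTerm <- 0
  for (t in seq_len(nFrames(ser))) for (k in seq_len(K)) {
    ego <- egocentrize(matrix(coords(ser)[t, , ], K, D),
                       model@latent$v[t, ], model@latent$h[t])[k, ]
    vv <- model@obs$s[t, k] * model@obs$sigmasq[k]
    obsTerm <- obsTerm +
      sum(dnorm(ego, pred[t, k, ], sqrt(vv), log = TRUE))
  }
  ## strip the observation block by zeroing residual influence: recompute
  ## full log joint with a modified model whose obs term we can isolate is
  ## impractical; instead compare the difference induced by a data change.
  Y3 <- coords(ser); Y3[7, 1, 2] <- Y3[7, 1, 2] + 3
  ser3 <- KeypointSeries(Y3, confidences(ser), fps(ser))
  obsTerm3 <- 0
  for (t in seq_len(nFrames(ser))) for (k in seq_len(K)) {
    ego <- egocentrize(matrix(Y3[t, , ], K, D),
                       model@latent$v[t, ], model@latent$h[t])[k, ]
    vv <- model@obs$s[t, k] * model@obs$sigmasq[k]
    obsTerm3 <- obsTerm3 +
      sum(dnorm(ego, pred[t, k, ], sqrt(vv), log = TRUE))
  }
  expect_equal(logJoint(model, ser3) - lj, obsTerm3 - obsTerm,
               tolerance = 1e-8)
  ## label-permutation symmetry
  perm <- c(2L, 1L)
  m2 <- model
  m2@latent$z <- perm[model@latent$z]
  m2@trans$beta <- model@trans$beta[order(perm)]
  m2@trans$pi <- model@trans$pi[order(perm), order(perm)]
  m2@ar$A <- model@ar$A[order(perm), , , drop = FALSE]
  m2@ar$b <- model@ar$b[order(perm), , drop = FALSE]
  m2@ar$Q <- model@ar$Q[order(perm), , , drop = FALSE]
  expect_equal(logJoint(m2, ser), lj, tolerance = 1e-8)
  ## non-finite states are reported by term name
  m3 <- model
  m3@obs$s[1, 1] <- 0
  expect_error(logJoint(m3, ser), "non-finite")
})

test_that("samplers are deterministic given the seed stream", {
  fx <- tinyModelFixture(T_ = 20L, seed = 70)
  set.seed(123)
  a <- poseSLDS:::gibbsSweep(fx$model, fx$series)
  set.seed(123)
  b <- poseSLDS:::gibbsSweep(fx$model, fx$series)
  expect_identical(a@latent, b@latent)
  expect_identical(a@ar, b@ar)
  expect_identical(a@trans, b@trans)
})
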