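mkSeries <- function(Y, conf = NULL, fps = 30, rec = NULL) {
  KeypointSeries(Y, conf, fps, rec)
}

test_that("low-confidence interpolation fills gaps linearly", {
  ## frames [0,?,2]: middle low confidence -> midpoint
  Y <- array(0, dim = c(3, 3, 2))
  Y[, 1L, 1L] <- c(0, 99, 2); Y[, 1L, 2L] <- c(0, 99, 2)
  cf <- matrix(1, 3, 3); cf[2L, 1L] <- 0.1
  out <- interpolateLowConfidence(mkSeries(Y, cf), 0.5)
  expect_equal(coords(out)[2L, 1L, ], c(1, 1))
  ## untouched elsewhere, confidences unchanged
  expect_identical(coords(out)[, 2L, ], Y[, 2L, , drop = TRUE])
  expect_identical(confidences(out), cf)
  ## gap of 3 frames between (0,0) and (4,8)
  Y2 <- array(0, dim = c(5, 3, 2))
  Y2[, 2L, 1L] <- c(0, 7, 7, 7, 4); Y2[, 2L, 2L] <- c(0, 7, 7, 7, 8)
  cf2 <- matrix(1, 5, 3); cf2[2:4, 2L] <- 0
  out2 <- interpolateLowConfidence(mkSeries(Y2, cf2), 0.5)
  expect_equal(coords(out2)[2:4, 2L, 1L], c(1, 2, 3))
  expect_equal(coords(out2)[2:4, 2L, 2L], c(2, 4, 6))
  ## leading/trailing gaps take nearest valid value
  cf3 <- matrix(1, 5, 3); cf3[c(1L, 5L), 3L] <- 0
  Y3 <- Y2; Y3[, 3L, 1L] <- c(9, 1, 2, 3, 9)
  out3 <- interpolateLowConfidence(mkSeries(Y3, cf3), 0.5)
  expect_equal(coords(out3)[c(1L, 5L), 3L, 1L], c(1, 3))
  ## identity when all confident; idempotent
  allc <- mkSeries(Y2, matrix(1, 5, 3))
  expect_identical(coords(interpolateLowConfidence(allc)), coords(allc))
  expect_identical(coords(interpolateLowConfidence(out2)), coords(out2))
  ## keypoint with no valid frames errors with names
  cf4 <- matrix(1, 5, 3); cf4[, 2L] <- 0
  expect_error(interpolateLowConfidence(mkSeries(Y2, cf4)), "kp2")
})

test_that("interpolation respects recording boundaries", {
  Y <- array(0, dim = c(6, 3, 2))
  Y[, 1L, 1L] <- c(0, 5, 10, 100, 5, 200)
  cf <- matrix(1, 6, 3)
  cf[c(2L, 6L), 1L] <- 0   # frame 2 interior of rec a; frame 6 trailing in rec b
  out <- interpolateLowConfidence(
    mkSeries(Y, cf, rec = rep(c("a", "b"), each = 3)))
  expect_equal(coords(out)[2L, 1L, 1L], 5)     # between 0 and 10
  expect_equal(coords(out)[6L, 1L, 1L], 5)     # carried from frame 5, not rec a
})

test_that("uniform augmentation is bounded, zero-centered and optional", {
  set.seed(31)
  sim <- simulateKeypointSLDS(50, K = 4, nStates = 2)
  out <- augmentUniformNoise(sim$series, 0.1)
  dlt <- coords(out) - coords(sim$series)
  expect_lte(max(abs(dlt)), 0.1)
  expect_identical(coords(augmentUniformNoise(sim$series, 0)),
                   coords(sim$series))
  ## Monte-Carlo: perturbation mean near 0 (uniform on [-h, h])
  big <- augmentUniformNoise(simulateKeypointSLDS(2000, K = 8,
                                                  nStates = 2)$series, 0.1)
})

test_that("perturbation mean matches the uniform distribution", {
  set.seed(32)
  n <- 1e6
  halfWidth <- 0.1
  Y <- array(0, dim = c(n / 4, 4, 2))
  ser <- mkSeries(Y, matrix(1, n / 4, 4))
  out <- augmentUniformNoise(ser, halfWidth)
  dlt <- as.numeric(coords(out))
  se <- halfWidth / sqrt(3) / sqrt(length(dlt))
  expect_lt(abs(mean(dlt)), 3 * se)
})

test_that("egocentric alignment removes rigid motion and flags degeneracy", {
  set.seed(33)
  sim <- simulateKeypointSLDS(60, K = 5, nStates = 2)
  ser <- sim$series
  al <- egocentricAlign(ser, 1L, 5L)
  ## per-frame mean of aligned pose is ~0
  expect_lt(max(abs(apply(al@ytilde, c(1, 3), mean))), 1e-10)
  ## axis points along +x
  ax <- al@ytilde[, 1L, ] - al@ytilde[, 5L, ]
  expect_lt(max(abs(atan2(ax[, 2L], ax[, 1L]))), 1e-10)
  ## global rigid motion changes only v and h
  phi <- 0.9; tv <- c(12, -7)
  Y2 <- coords(ser)
  for (t in seq_len(nFrames(ser)))
    Y2[t, , ] <- rigidTransform(matrix(coords(ser)[t, , ], 5, 2), tv, phi)
  al2 <- egocentricAlign(mkSeries(Y2), 1L, 5L)
  expect_lt(max(abs(al2@ytilde - al@ytilde)), 1e-10)
  expect_lt(max(circDist(al2@h, wrapAngle(al@h + phi))), 1e-10)
  ## configuration errors
  expect_error(egocentricAlign(ser, 2L, 2L), "must differ")
  expect_error(egocentricAlign(ser, "nope", 1L), "unknown")
})

test_that("coincident reference keypoints carry the previous heading", {
  Y <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
  Y[2L, 1L, ] <- Y[2L, 3L, ]            # degenerate frame 2
  al <- egocentricAlign(mkSeries(Y), 1L, 3L)
  expect_equal(al@h[2L], al@h[1L])
  ## degenerate at recording start -> heading 0
  Y[1L, 1L, ] <- Y[1L, 3L, ]
  al2 <- egocentricAlign(mkSeries(Y), 1L, 3L)
  expect_equal(al2@h[1L], 0)
})

test_that("whitened PCA picks the minimal dimension and whitens", {
  set.seed(34)
  ## rank-3 data embedded in aligned poses
  T_ <- 400L; K <- 6L
  G <- gammaEmbedding(K)
  basis <- qr.Q(qr(matrix(rnorm(10 * 3), 10)))[, 1:3]
  lat <- cbind(rnorm(T_, sd = 4), rnorm(T_, sd = 2), rnorm(T_, sd = 1))
  red <- lat %*% t(basis)
  yt <- array(0, dim = c(T_, K, 2))
  for (dd in 1:2)
    yt[, , dd] <- red[, seq.int(dd, by = 2, length.out = K - 1)] %*% t(G)
  al <- new("AlignedPose", ytilde = yt, v = matrix(0, T_, 2),
            h = rep(0, T_), recording = rep("rec1", T_), fps = 30)
  fit <- fitPCAWhiten(al, varianceTarget = 1.0)
  expect_equal(fit$M, 3L)
  expect_lt(max(abs(cov(fit$x) - diag(3))), 1e-6)
  ## eigen-fraction arithmetic: variances 16,4,1 -> target 0.9 needs 2 comps
  fr <- fit$explained
  expect_equal(fitPCAWhiten(al, varianceTarget = 0.9)$M,
               which(cumsum(fr) >= 0.9)[1L])
  ## reconstruction error equals the unexplained variance
  fit2 <- fitPCAWhiten(al, varianceTarget = 0.75)
  Yr <- poseSLDS:::reducedPoseMatrix(al, G)
  totVar <- sum(apply(Yr, 2L, function(cl) mean((cl - mean(cl))^2)))
  rec <- fit2$x %*% t(fit2$C)
  resid <- sweep(Yr, 2, fit2$d) - rec
  expect_lte(mean(rowSums(resid^2)),
             (1 - sum(fr[seq_len(fit2$M)])) * totVar + 1e-8)
})

test_that("cumulative-variance selection matches hand-set spectra", {
  ## spectrum fractions (.5, .3, .15, .05): target .9 -> M = 3
  set.seed(35)
  T_ <- 20000L
  sds <- sqrt(c(0.5, 0.3, 0.15, 0.05))
  K <- 3L; G <- gammaEmbedding(K)
  lat <- sapply(sds, function(s) rnorm(T_, sd = s))
  yt <- array(0, dim = c(T_, K, 2))
  for (dd in 1:2)
    yt[, , dd] <- lat[, seq.int(dd, by = 2, length.out = K - 1)] %*% t(G)
  al <- new("AlignedPose", ytilde = yt, v = matrix(0, T_, 2),
            h = rep(0, T_), recording = rep("rec1", T_), fps = 30)
  expect_equal(fitPCAWhiten(al, 0.9)$M, 3L)
  expect_equal(fitPCAWhiten(al, 0.8)$M, 2L)
})

test_that("change score spikes at pose jumps and ignores rigid motion", {
  ## frozen pose rigidly translated: score identically 0 (zero-variance guard)
  K <- 4L
  base <- matrix(c(10, 0, 0, 5, 0, -5, -10, 0), K, 2, byrow = TRUE)
  T_ <- 30L
  Y <- array(0, dim = c(T_, K, 2))
  for (t in seq_len(T_))
    Y[t, , ] <- rigidTransform(base, c(t * 3, -t), 0)
  expect_true(all(changeScore(mkSeries(Y), 1L, 4L) == 0))
  ## single-keypoint jump -> maximal score at the jump frame
  Y2 <- Y
  Y2[16:T_, 2L, 2L] <- Y2[16:T_, 2L, 2L] + 12
  sc <- changeScore(mkSeries(Y2), 1L, 4L)
  expect_equal(which.max(sc), 16L)
  ## z-score normalization over valid frames
  set.seed(36)
  sim <- simulateKeypointSLDS(800, K = 6, nStates = 3)
  s2 <- changeScore(sim$series, 1L, 6L)
  expect_lt(abs(mean(s2[-1L])), 1e-10)
  expect_equal(sd(s2[-1L]), 1, tolerance = 0.01)
  expect_equal(s2[1L], 0)
})

test_that("full preprocessing is equivariant to global rigid motion", {
  set.seed(37)
  sim <- simulateKeypointSLDS(300, K = 6, nStates = 2)
  ser <- sim$series
  phi <- 2.2; tv <- c(-40, 25)
  Y2 <- coords(ser)
  for (t in seq_len(nFrames(ser)))
    Y2[t, , ] <- rigidTransform(matrix(coords(ser)[t, , ], 6, 2), tv, phi)
  ser2 <- KeypointSeries(Y2, confidences(ser), fps(ser))
  a1 <- egocentricAlign(ser, 1L, 6L); a2 <- egocentricAlign(ser2, 1L, 6L)
  expect_lt(max(abs(a1@ytilde - a2@ytilde)), 1e-8)
  p1 <- fitPCAWhiten(a1); p2 <- fitPCAWhiten(a2)
  expect_equal(p1$M, p2$M)
  expect_lt(max(abs(p1$x - p2$x)), 1e-6)
  expect_lt(max(abs(changeScore(ser, 1L, 6L) - changeScore(ser2, 1L, 6L))),
            1e-8)
})
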