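test_that("betaN reproduces the reference kernel values", {
  expect_identical(round(betaN(1, 512), 4), -0.1013)
  expect_equal(betaN(-1, 512), betaN(1, 512))
  expect_identical(round(betaN(3, 64), 4), -0.0113)
  expect_identical(round(betaN(1, 64), 4), -0.1014)
  for (N in c(64L, 128L, 256L)) expect_lt(abs(betaN(2, N)), 1e-3)
  expect_identical(betaN(0, 128), 0.25)
  expect_error(betaN(1, 63), "even")
})

test_that("betaLimit closed form and convergence of betaN", {
  expect_identical(betaLimit(0), 0.25)
  expect_identical(betaLimit(4), 0)
  expect_equal(betaLimit(3), -1 / (9 * pi^2))
  expect_equal(betaLimit(c(-5, 5)), rep(-1 / (25 * pi^2), 2))

  # |beta_N - beta_inf| decreasing in N for fixed odd t
  for (t in c(1, 3, 5)) {
    err <- abs(vapply(c(64, 128, 256, 512, 1024),
                      function(N) betaN(t, N), 1) - betaLimit(t))
    expect_true(all(diff(err) < 0))
  }
})

test_that("ramp kernel taps are symmetric with exact center and tiny even taps", {
  h <- rampKernel(5, 128)
  taps <- filterTaps(h)
  expect_length(taps, 11)
  expect_identical(taps, rev(taps))
  expect_identical(taps[6], 0.25)
  expect_true(all(abs(taps[c(2, 4, 8, 10)]) < 1e-3))

  # agrees with the asymptotic closed form for large N
  big <- filterTaps(rampKernel(5, 4096))
  expect_lt(max(abs(big - betaLimit(-5:5))), 1e-4)

  expect_error(rampKernel(5, 16), "wrap")
})

test_that("frequency-domain ramp equals spatial circular convolution when unpadded", {
  set.seed(21)
  for (N in c(32L, 64L, 128L)) {
    p <- rnorm(N)
    q <- rampFilterRow(p, N)
    oracle <- oracleCircularConv(p, function(off) {
      o <- if (off <= N / 2) off else off - N
      betaN(o, N)
    })
    expect_lt(max(abs(q - oracle)), 1e-8)
  }
})

test_that("ramp filtering basics: zeros, impulse response, argument checks", {
  expect_identical(rampFilterRow(numeric(40), 64), numeric(40))

  # impulse response around the center approximates the spatial kernel
  p <- numeric(129); p[65] <- 1
  q <- rampFilterRow(p, 1024)
  expect_equal(q[60:70], filterTaps(rampKernel(5, 1024)), tolerance = 1e-6)

  expect_error(rampFilterRow(numeric(100), 64), ">=")
  expect_error(rampFilterRow(numeric(10), 15), "even")
})

test_that("backprojection geometry: zero input, single-angle ridge, scaling", {
  z <- Sinogram(matrix(0, 4, 21), c(0, 45, 90, 135))
  expect_identical(pixels(backproject(z, 16)), matrix(0, 16, 16))

  # single angle, impulse at t=0: vertical ridge through the center for
  # theta = 0 (rays x = const), scaled by pi/K with K = 1
  q <- matrix(0, 1, 21); q[1, 11] <- 1
  bp <- pixels(backproject(Sinogram(q, 0), 15))
  expect_equal(bp[, 8], rep(pi, 15))      # center column hits the impulse
  expect_equal(bp[, 5], rep(0, 15))       # |t| >= 1 away: no contribution
})

test_that("FBP is linear, preserves zero and recovers a disk", {
  ex <- phantomExperiment(48)
  rec <- fbpReconstruct(ex$sino, reconConfig(48))
  rec2 <- fbpReconstruct(Sinogram(2 * sinoData(ex$sino), angles(ex$sino)),
                         reconConfig(48))
  expect_equal(pixels(rec2), 2 * pixels(rec), tolerance = 1e-12)

  z <- Sinogram(matrix(0, 90, ncol(sinoData(ex$sino))), angles(ex$sino))
  expect_identical(pixels(fbpReconstruct(z, reconConfig(48))),
                   matrix(0, 48, 48))

  d <- diskImage(48, 12)
  sgd <- forwardProject(d, seq(0, 178, by = 2))
  recd <- fbpReconstruct(sgd, reconConfig(48))
  expect_lt(imageMSE(recd, d), 0.01)
  expect_gt(uqi(recd, d), 0.9)
})

test_that("reconstructing shifted-angle data equals rotating the reconstruction", {
  n <- 48
  d <- diskImage(n, 10)
  off <- ImageGrid({m <- matrix(0, n, n); m[16:26, 20:30] <- 1; m})
  img <- ImageGrid(pixels(d) + 0.5 * pixels(off))
  sg <- forwardProject(img, seq(0, 178, by = 2))
  # shifting the angle labels by 90 degrees (with the detector axis
  # reversed for the wrapped angles, since p(theta + 180) is the
  # mirrored p(theta)) reconstructs the image rotated clockwise by 90
  # degrees -- an exact pixel-grid rotation about the geometric center
  P <- sinoData(sg)
  shifted <- Sinogram(rbind(P[46:90, ], P[1:45, ncol(P):1]), angles(sg))
  recS <- fbpReconstruct(shifted, reconConfig(n))
  rec <- fbpReconstruct(sg, reconConfig(n))
  rotCW <- t(pixels(rec)[n:1, ])
  expect_equal(pixels(recS), rotCW, tolerance = 1e-10)
})

test_that("guessImageSize returns the largest size fitting the detector", {
  for (n in c(32L, 64L, 128L, 200L)) {
    sg <- Sinogram(matrix(0, 2, detectorLength(n)), c(0, 90))
    g <- guessImageSize(sg)
    expect_gte(g, n)
    expect_lte(detectorLength(g), detectorLength(n))
    expect_gt(detectorLength(g + 1L), detectorLength(n))
  }
})
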