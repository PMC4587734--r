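test_that("designFilter reproduces the reference normalized taps for h_5 at N = 128", {
  filt <- designFilter(rampKernel(5, 128))
  taps <- filterTaps(filt)
  printed <- c(0.0321, 0.0716, 0.1231, 0.1841, 0.3078, 0.5625,
               0.3078, 0.1841, 0.1231, 0.0716, 0.0321)
  expect_equal(taps, printed, tolerance = 2e-3)
  expect_lt(max(abs(taps - printed)), 1e-3 + 1e-8)
  expect_equal(sum(taps), 2, tolerance = 1e-12)
  expect_identical(taps, rev(taps))
})

test_that("designFilter inverts the identity kernel exactly", {
  id <- new("RampKernel", taps = c(0, 0, 1, 0, 0), halfWidth = 2L,
            N = NA_integer_)
  filt <- designFilter(id)
  # unnormalised solution is delta; sum-to-2 normalisation doubles it
  expect_equal(filterTaps(filt) / filt@normConstant, c(0, 0, 1, 0, 0),
               tolerance = 1e-12)
  expect_equal(filt@residualNorm, 0, tolerance = 1e-12)
})

test_that("designFilter agrees with the brute-force normal-equation oracle", {
  for (N in c(64L, 128L, 256L)) {
    h <- rampKernel(5, N)
    expect_lt(max(abs(filterTaps(designFilter(h)) -
                        oracleDesignTaps(filterTaps(h)))), 1e-10)
  }
  h3 <- rampKernel(3, 64)
  expect_lt(max(abs(filterTaps(designFilter(h3)) -
                      oracleDesignTaps(filterTaps(h3)))), 1e-10)
})

test_that("circular design convention solves its deconvolution exactly", {
  h <- rampKernel(5, 128)
  filt <- designFilter(h, method = "circular")
  f <- filterTaps(filt) / filt@normConstant
  m <- 11
  conv <- oracleCircularConv(f, function(off) {
    o <- if (off <= 5) off else off - m
    filterTaps(h)[o + 6]
  })
  delta <- numeric(m); delta[6] <- 1
  expect_lt(max(abs(conv - delta)), 1e-10)
})

test_that("designFilter rejects a degenerate all-zero kernel", {
  z <- new("RampKernel", taps = numeric(5), halfWidth = 2L, N = NA_integer_)
  expect_error(designFilter(z), "degenerate")
})

test_that("filterResidual is a linear 'same' convolution with the taps", {
  filt <- designFilter(rampKernel(5, 128))
  expect_identical(filterResidual(numeric(64), filt), numeric(64))

  x <- numeric(41); x[21] <- 1
  y <- filterResidual(x, filt)
  expect_equal(y[16:26], filterTaps(filt), tolerance = 1e-12)

  set.seed(31)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(filterResidual(2 * a - 3 * b, filt),
               2 * filterResidual(a, filt) - 3 * filterResidual(b, filt),
               tolerance = 1e-10)

  expect_error(filterResidual(numeric(5), filt), "shorter")
})

test_that("filtering then ramp-filtering an impulse approximates the impulse", {
  filt <- designFilter(rampKernel(5, 128))
  L <- 101
  x <- numeric(L); x[51] <- 1
  # undo the sum-to-2 normalisation to test the raw deconvolution contract
  comp <- rampFilterRow(filterResidual(x, filt) / filt@normConstant, 2048)
  delta <- numeric(L); delta[51] <- 1
  achieved <- sqrt(sum((comp - delta)^2))
  # the recorded design residual is against the truncated kernel; the
  # full ramp adds its 1/t^2 tails, so allow a modest margin
  expect_equal(achieved, filt@residualNorm, tolerance = 0.35)
  expect_lt(achieved, 0.25)
})

test_that("iterateFBP with zero iterations is classic FBP bit-for-bit", {
  ex <- phantomExperiment(48)
  cfg0 <- reconConfig(48, maxIterations = 0)
  fit <- iterateFBP(ex$sino, cfg0)
  expect_identical(pixels(fit$image), pixels(fbpReconstruct(ex$sino, cfg0)))
  expect_equal(nrow(fit$log), 1L)
  expect_null(fit$filter)
})

test_that("reprojection residual s decreases over early iterations on clean data", {
  ex <- phantomExperiment(64, step = 2, maxIterations = 3)
  fit <- iterateFBP(ex$sino, ex$cfg)
  s <- fit$log$s
  expect_gte(length(s), 3)
  expect_lt(s[2], s[1])
  expect_lt(s[3], s[2])
  # best-s iterate is returned
  rp <- forwardProject(fit$image, angles(ex$sino),
                       nbins = ncol(sinoData(ex$sino)))
  expect_equal(projectionResidualStat(ex$sino, rp), min(s), tolerance = 1e-10)
})

test_that("iterative FBP improves on classic FBP on noiseless phantoms", {
  for (n in c(64L, 96L)) {
    ex <- phantomExperiment(n, step = 2, maxIterations = 2)
    classic <- fbpReconstruct(ex$sino, ex$cfg)
    fit <- iterateFBP(ex$sino, ex$cfg)
    expect_lt(imageMSE(fit$image, ex$phantom),
              imageMSE(classic, ex$phantom))
  }
})

test_that("the correction loop is homogeneous: scaling data scales all iterates", {
  ex <- phantomExperiment(48, maxIterations = 2)
  cfg <- reconConfig(48, maxIterations = 2, stopTolerance = 0)
  fit1 <- iterateFBP(ex$sino, cfg)
  fit2 <- iterateFBP(Sinogram(3 * sinoData(ex$sino), angles(ex$sino)), cfg)
  expect_equal(pixels(fit2$image), 3 * pixels(fit1$image), tolerance = 1e-10)
  expect_equal(fit2$log$s, 9 * fit1$log$s, tolerance = 1e-8)
})

test_that("the stopping rule halts when s stops improving", {
  ex <- phantomExperiment(48)
  cfg <- reconConfig(48, maxIterations = 4, stopTolerance = 1)
  # a relative-improvement threshold of 1 can never be met: stops after
  # the first correction
  fit <- iterateFBP(ex$sino, cfg)
  expect_equal(nrow(fit$log), 2L)
})
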