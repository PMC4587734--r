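test_that("MSE identities and argument checks", {
  ph <- headPhantom(32)
  expect_identical(imageMSE(ph, ph), 0)
  expect_identical(imageMSE(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  expect_error(imageMSE(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
})

test_that("UQI identities, sign and degenerate input", {
  ph <- headPhantom(32)
  expect_equal(uqi(ph, ph), 1, tolerance = 1e-3)   # M/(M-1) covariance factor
  # anti-correlated image with positive mean: the covariance term makes
  # the index negative (a plain sign flip would also flip the luminance
  # term, cancelling the sign)
  shifted <- ImageGrid(pixels(ph) + 2)
  flipped <- ImageGrid(max(pixels(shifted)) + min(pixels(shifted)) -
                         pixels(shifted))
  expect_lt(uqi(flipped, shifted), 0)
  expect_error(uqi(matrix(1, 4, 4), matrix(2, 4, 4)), "constant")
  # not shift-invariant: luminance term changes under joint shifts
  a <- ImageGrid(pixels(ph) + 0.2)
  b <- ImageGrid(pixels(fbpReconstruct(forwardProject(ph, seq(0, 178, 2)),
                                       reconConfig(32))))
  bshift <- ImageGrid(pixels(b) + 0.2)
  expect_false(isTRUE(all.equal(uqi(b, ph), uqi(bshift, a))))
})

test_that("mutual information: identity, symmetry, independence, bins", {
  ph <- headPhantom(64)
  p <- pixels(ph)
  for (nb in c(16L, 64L)) {
    mi <- mutualInformation(ph, ph, nb)
    # MI of an image with itself is its marginal entropy
    counts <- tabulate(pmin(floor((p - min(p)) / diff(range(p)) * nb) + 1L,
                            nb), nb)
    prob <- counts[counts > 0] / length(p)
    expect_equal(mi, -sum(prob * log2(prob)), tolerance = 1e-10)
  }

  set.seed(41)
  a <- matrix(rnorm(512 * 512), 512)
  b <- matrix(sample(a), 512)       # same values, shuffled: independent
  expect_lt(mutualInformation(a, b, 64L), 0.05)
  expect_identical(mutualInformation(a, b, 64L),
                   mutualInformation(b, a, 64L))
  expect_gte(mutualInformation(a, b, 64L), 0)
  expect_error(mutualInformation(a, b, 1L), "nBins")
})

test_that("projection residual statistic is the total-sample mean square", {
  ex <- phantomExperiment(32)
  expect_identical(projectionResidualStat(ex$sino, ex$sino), 0)
  other <- Sinogram(sinoData(ex$sino) + 2, angles(ex$sino))
  expect_equal(projectionResidualStat(ex$sino, other), 4)
  expect_error(projectionResidualStat(sinoData(ex$sino),
                                      matrix(0, 2, 2)), "shape")
})

test_that("metrics are invariant under a common pixel permutation", {
  set.seed(42)
  ph <- headPhantom(32)
  rec <- fbpReconstruct(forwardProject(ph, seq(0, 178, 2)), reconConfig(32))
  perm <- sample(length(pixels(ph)))
  a <- matrix(pixels(rec)[perm], 32); b <- matrix(pixels(ph)[perm], 32)
  expect_identical(imageMSE(rec, ph), imageMSE(a, b))
  expect_equal(uqi(rec, ph), uqi(a, b), tolerance = 1e-12)
  expect_identical(mutualInformation(rec, ph, 64L),
                   mutualInformation(a, b, 64L))
})

test_that("qualityReport bundles the criteria consistently", {
  ph <- headPhantom(32)
  rec <- fbpReconstruct(forwardProject(ph, seq(0, 178, 2)), reconConfig(32))
  rep <- qualityReport(rec, ph, nBins = 64L, sValues = c(0.3, 0.05))
  expect_identical(rep@mse, imageMSE(rec, ph))
  expect_identical(rep@mi, mutualInformation(rec, ph, 64L))
  expect_identical(rep@sValues, c(0.3, 0.05))
})
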