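test_that("position generation is deterministic, bounded and validated", {
    g1 <- generatePositions(50, seed = 1)
    g2 <- generatePositions(50, seed = 1)
    expect_identical(positions(g1), positions(g2))
    expect_false(identical(positions(g1),
                           positions(generatePositions(50, seed = 2))))
    ext <- c(140, 170, 100)
    expect_true(max(dist(positions(g1))) <= sqrt(sum(ext^2)))
    expect_error(generatePositions(1), ">= 2")
    expect_error(generatePositions(10, extent = c(10, 0, 5)),
                 "strictly positive")
})

test_that("EDR connectivity has the closed-form structure", {
    geo <- new("NodeGeometry",
               coords = rbind(c(0, 0, 0), c(10, 0, 0), c(0, 40, 0)))
    C <- generateEDRConnectivity(geo, 0.106)
    w <- connWeights(C)
    # closest pair carries the maximum, normalized to 1
    expect_equal(w[1, 2], 1)
    # ratios preserve the exponential decay exactly
    expect_equal(w[1, 3] / w[1, 2], exp(-0.106 * (40 - 10)))
    expect_true(isSymmetric(w))
    expect_equal(diag(w), rep(0, 3))
    # gamma = 0: uniform couplings
    w0 <- connWeights(generateEDRConnectivity(geo, 0))
    expect_equal(w0[upper.tri(w0)], rep(1, 3))
})

test_that("independent raster matches Bernoulli statistics", {
    p <- 0.2; n <- 60; nT <- 5000
    r <- generateIndependentRaster(n, nT, p, seed = 3)
    rates <- rowMeans(rasterValues(r))
    se <- sqrt(p * (1 - p) / nT)
    expect_true(all(abs(rates - p) < 3 * se + 1e-12) ||
                    mean(abs(rates - p) < 3 * se) > 0.98)
    cc <- pairwisePearson(r)
    expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(nT))
    expect_identical(rasterValues(generateIndependentRaster(n, 100, p, seed = 9)),
                     rasterValues(generateIndependentRaster(n, 100, p, seed = 9)))
    expect_error(generateIndependentRaster(10, 10, 1.2), "probability")
})

test_that("fully correlated raster replicates one series", {
    r <- generateFullyCorrelatedRaster(20, 500, 0.3, seed = 4)
    v <- rasterValues(r)
    expect_true(all(v == rep(v[1, ], each = 20)))
    cc <- pairwisePearson(r)
    expect_equal(unname(cc[upper.tri(cc)]), rep(1, 190))
})

test_that("dichotomized-Gaussian raster decays with distance and theta", {
    geo <- generatePositions(80, seed = 5)
    r1 <- generatePowerLawRaster(geo, eta = 0.5, theta = 1, nFrames = 4000,
                                 seed = 6)
    cf <- correlationFunction(pairwisePearson(r1), geo, dr = 20)
    ok <- cf@nPairs >= 10
    g <- cf@g[ok]
    # monotone decrease over well-populated bins
    expect_true(all(diff(g) < 0))
    r2 <- generatePowerLawRaster(geo, eta = 0.5, theta = 1.8, nFrames = 4000,
                                 seed = 6)
    expect_lt(mean(rasterValues(r2)), mean(rasterValues(r1)))
})

test_that("frame shuffling preserves row marginals and destroys correlation", {
    r <- generatePowerLawRaster(generatePositions(40, seed = 7), eta = 0.4,
                                theta = 1, nFrames = 2000, seed = 8)
    s <- shuffleTimeFrames(r, seed = 9)
    expect_identical(rowSums(rasterValues(s)), rowSums(rasterValues(r)))
    expect_identical(rasterValues(shuffleTimeFrames(r, seed = 9)),
                     rasterValues(s))
    cc <- pairwisePearson(s)
    expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(2000))
})

test_that("connectivity shuffling preserves the weight multiset only", {
    geo <- generatePositions(120, seed = 10)
    C <- generateEDRConnectivity(geo, 0.106)
    S <- shuffleConnectivity(C, seed = 11)
    w0 <- connWeights(C); w1 <- connWeights(S)
    expect_identical(sort(w0[upper.tri(w0)]), sort(w1[upper.tri(w1)]))
    expect_true(isSymmetric(w1))
    expect_equal(diag(w1), rep(0, 120))
    d <- as.matrix(dist(positions(geo)))
    ut <- upper.tri(d)
    expect_lt(abs(cor(w1[ut], d[ut])), 0.05)
    # and it really did have structure before shuffling: the log-weights
    # are an exact linear function of distance
    expect_lt(cor(log(w0[ut]), d[ut]), -0.999)
})
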