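test_that("normalization divides by the maximum and is idempotent", {
    w <- matrix(c(0, 2, 4, 2, 0, 1, 4, 1, 0), 3)
    C <- normalizeConnectivity(w)
    expect_equal(connWeights(C), w / 4)
    expect_true(isNormalized(C))
    expect_equal(connWeights(normalizeConnectivity(C)), connWeights(C))
    expect_error(normalizeConnectivity(matrix(0, 3, 3)), "all-zero")
})

test_that("asymmetric input is symmetrized by averaging with a warning", {
    w <- matrix(c(0, 1, 3, 2, 0, 1, 1, 5, 0), 3, byrow = TRUE)
    expect_warning(C <- normalizeConnectivity(w), "symmetriz")
    avg <- (w + t(w)) / 2
    expect_equal(connWeights(C), avg / max(avg))
})

test_that("EDR fit inverts noiseless exponential weights exactly", {
    geo <- generatePositions(60, seed = 1)
    C <- generateEDRConnectivity(geo, 0.106)
    f <- fitEDR(C, geo, maxDistance = 50)
    expect_equal(f@gamma, 0.106, tolerance = 1e-10)
    expect_equal(f@r2, 1, tolerance = 1e-10)
    # round-trip residual on the full distance range too
    f2 <- fitEDR(C, geo, maxDistance = Inf)
    expect_lt(abs(f2@gamma - 0.106), 1e-10)
    # binned variant agrees on noiseless data
    fb <- fitEDR(C, geo, maxDistance = 50, binWidth = 2)
    expect_equal(fb@gamma, 0.106, tolerance = 1e-8)
})

test_that("EDR fit recovers gamma under multiplicative lognormal noise", {
    geo <- generatePositions(300, seed = 2)
    r <- as.matrix(dist(positions(geo)))
    set.seed(3)
    noise <- matrix(exp(rnorm(300^2, 0, 0.3)), 300)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    w <- exp(-0.106 * r) * noise
    diag(w) <- 0
    f <- fitEDR(normalizeConnectivity(w), geo, maxDistance = 50)
    expect_lt(abs(f@gamma - 0.106), 2 * f@gammaSE)
})

test_that("EDR fit rejects starved inputs with a count", {
    geo <- new("NodeGeometry",
               coords = rbind(c(0, 0, 0), c(60, 0, 0), c(0, 60, 0)))
    C <- generateEDRConnectivity(geo, 0.05)
    expect_error(fitEDR(C, geo, maxDistance = 10), "have 0")
})

test_that("node strength sums off-diagonal weights", {
    w <- matrix(0.4, 5, 5); diag(w) <- 0
    expect_equal(nodeStrength(makeConn(w)), rep(4 * 0.4, 5))
    w2 <- connWeights(randomConn(20, seed = 4))
    s <- nodeStrength(makeConn(w2))
    oracle <- vapply(1:20, function(i) sum(w2[i, -i]), numeric(1))
    expect_equal(s, oracle)
    w3 <- w2; w3[3, ] <- 0; w3[, 3] <- 0
    expect_equal(nodeStrength(makeConn(w3))[3], 0)
})

test_that("linear prediction scores identical coupled signals perfectly", {
    set.seed(5)
    x <- rnorm(200)
    X <- rbind(x, x, rnorm(200))
    w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
    sc <- suppressWarnings(linearPredictionScores(makeConn(w), X))
    expect_equal(sc[1], 1)
    expect_equal(sc[2], 1)
    expect_true(is.na(sc[3]))  # node 3 has zero predicted variance
})

test_that("shuffled couplings predict white noise at chance level", {
    set.seed(6)
    n <- 80; nT <- 2000
    X <- matrix(rnorm(n * nT), n)
    C <- shuffleConnectivity(randomConn(n, seed = 7), seed = 8)
    sc <- linearPredictionScores(C, X)
    expect_lt(abs(mean(sc)), 3 / sqrt(nT))
})

test_that("constant rows yield NA scores with a warning, never zero", {
    set.seed(9)
    X <- rbind(rnorm(100), rep(2, 100), rnorm(100))
    C <- makeConn(matrix(1, 3, 3) - diag(3))
    expect_warning(sc <- linearPredictionScores(C, X), "zero-variance")
    expect_true(is.na(sc[2]))
    expect_false(anyNA(sc[c(1, 3)]))
})

test_that("prediction scores are invariant under joint node permutation", {
    set.seed(10)
    n <- 30
    X <- matrix(rnorm(n * 500), n)
    C <- randomConn(n, seed = 11)
    sc <- linearPredictionScores(C, X)
    perm <- sample(n)
    Cp <- makeConn(connWeights(C)[perm, perm], normalized = TRUE)
    scp <- linearPredictionScores(Cp, X[perm, ])
    expect_equal(scp, sc[perm], tolerance = 1e-12)
})

test_that("hemisphere masks restrict couplings to the requested block", {
    set.seed(12)
    n <- 20
    X <- matrix(rnorm(n * 400), n)
    C <- randomConn(n, seed = 13)
    src <- 1:10; tgt <- 11:20
    sc <- linearPredictionScores(C, X, nodeMask = list(source = src,
                                                       target = tgt))
    expect_true(all(is.na(sc[src])))
    w <- connWeights(C)
    pred9 <- w[15, src, drop = FALSE] %*% X[src, ]
    expect_equal(unname(sc[15]), cor(as.numeric(pred9), X[15, ]))
})
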