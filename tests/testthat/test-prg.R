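test_that("greedy pairing reproduces a literal re-execution of the rule", {
    set.seed(1)
    for (n in c(4, 7, 12)) {
        s <- matrix(rnorm(n * n), n)
        s <- (s + t(s)) / 2
        got <- pairGreedy(s)
        want <- bruteGreedyPairs(s)
        expect_identical(got$pairs, matrix(as.integer(want$pairs),
                                           ncol = 2))
        expect_identical(got$leftover, as.integer(want$leftover))
    }
})

test_that("odd counts leave one leftover and ties break to smallest index", {
    s <- matrix(0, 3, 3)
    s[1, 2] <- s[2, 1] <- 0.9
    s[1, 3] <- s[3, 1] <- 0.1
    s[2, 3] <- s[3, 2] <- 0.2
    p <- pairGreedy(s)
    expect_identical(p$pairs, matrix(c(1L, 2L), 1))
    expect_identical(p$leftover, 3L)
    # two equal maxima: (1,2) and (3,4) both 0.9 -> smallest first index
    s4 <- matrix(0, 4, 4)
    s4[1, 2] <- s4[2, 1] <- 0.9
    s4[3, 4] <- s4[4, 3] <- 0.9
    expect_identical(pairGreedy(s4)$pairs[1, ], c(1L, 2L))
})

test_that("raster coarse-graining sums pairs and conserves activity", {
    r <- makeRaster(rbind(c(0, 1, 0), c(1, 1, 0)))
    out <- coarseGrainRaster(r, list(pairs = matrix(c(1L, 2L), 1)))
    expect_equal(rasterValues(out), rbind(c(1, 2, 0)))
    expect_identical(rasterLevel(out), 1L)

    r4 <- generateIndependentRaster(8, 50, 0.4, seed = 2)
    p <- pairGreedy(pairwisePearson(r4))
    out4 <- coarseGrainRaster(r4, p)
    expect_equal(colSums(rasterValues(out4)), colSums(rasterValues(r4)))
})

test_that("level-k entries equal the sum of their 2^k level-0 members", {
    r <- generateIndependentRaster(32, 700, 0.3, seed = 3)
    h <- runPRG(r, kMax = 3)
    X0 <- rasterValues(h@rasters[[1]])
    for (k in 1:3) {
        Xk <- rasterValues(h@rasters[[k + 1]])
        mem <- h@members[[k + 1]]
        expect_true(all(lengths(mem) == 2^k))
        for (i in seq_along(mem))
            expect_equal(Xk[i, ], colSums(X0[mem[[i]], , drop = FALSE]))
    }
})

test_that("connectivity coarse-graining averages the four cross weights", {
    w <- matrix(0, 4, 4)
    w[1, 3] <- w[3, 1] <- 0.2
    w[1, 4] <- w[4, 1] <- 0.1
    w[2, 3] <- w[3, 2] <- 0.3
    w[2, 4] <- w[4, 2] <- 0.4
    p <- list(pairs = rbind(c(1L, 2L), c(3L, 4L)))
    out <- coarseGrainConnectivity(w, p)
    expect_equal(out[1, 2], 0.25)
    expect_equal(diag(out), c(0, 0))
    # uniform couplings stay uniform with the same value
    u <- matrix(0.7, 4, 4); diag(u) <- 0
    expect_equal(coarseGrainConnectivity(u, p)[1, 2], 0.7)
})

test_that("PRG enforces the sample-size rule with a helpful bound", {
    r <- generateIndependentRaster(64, 200, 0.2, seed = 4)
    expect_error(runPRG(r, kMax = 6), "maximal admissible kMax is 4")
    h0 <- runPRG(r, kMax = 0)
    expect_identical(rasterValues(h0@rasters[[1]]), rasterValues(r))
})

test_that("retained counts halve with floor and discards are logged", {
    r <- generateIndependentRaster(50, 700, 0.2, seed = 5)
    h <- runPRG(r, kMax = 3)
    nk <- vapply(h@rasters, function(x) nrow(rasterValues(x)), integer(1))
    expect_identical(nk, c(50L, 25L, 12L, 6L))
    # the level-1 leftover discarded at step 2 carries 2 level-0 members
    expect_identical(lengths(h@discarded), c(0L, 2L, 0L))
    # partition: every retained level-0 node sits in exactly one cluster
    mem <- unlist(h@members[[4]])
    expect_identical(sort(mem), setdiff(1:50, unlist(h@discarded)))
    expect_identical(anyDuplicated(mem), 0L)
})

test_that("duplicate variables are grouped with their twins at level 1", {
    set.seed(6)
    base <- matrix(rbinom(6 * 400, 1, 0.3), 6)
    # noise rows plus three exact duplicate pairs
    X <- rbind(base[1, ], base[1, ], base[2, ], base[2, ], base[3, ], base[3, ])
    h <- runPRG(makeRaster(X), kMax = 1)
    prs <- h@pairings[[1]]$pairs
    expect_identical(prs, rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
})

test_that("connectivity-mode pairing depends on couplings, not activity", {
    C <- randomConn(16, seed = 7)
    r1 <- generateIndependentRaster(16, 700, 0.3, seed = 8)
    r2 <- generateIndependentRaster(16, 700, 0.3, seed = 9)
    h1 <- runPRG(r1, kMax = 3, mode = "connectivity", connectivity = C)
    h2 <- runPRG(r2, kMax = 3, mode = "connectivity", connectivity = C)
    for (k in 1:3)
        expect_identical(h1@pairings[[k]]$pairs, h2@pairings[[k]]$pairs)
    expect_error(runPRG(r1, kMax = 2, mode = "connectivity"),
                 "requires a ConnectivityMatrix")
})

test_that("variance curve hits the analytic limits at small scale", {
    ri <- generateIndependentRaster(128, 6000, 0.2, seed = 10)
    vc <- varianceCurve(runPRG(ri, kMax = 5))
    expect_lt(abs(exponent(vc) - 1), 0.06)
    expect_equal(vc@normalized[1], 1)

    rf <- generateFullyCorrelatedRaster(128, 6000, 0.2, seed = 11)
    vf <- varianceCurve(runPRG(rf, kMax = 5))
    expect_equal(exponent(vf), 2, tolerance = 1e-10)
})

test_that("silence free energy matches counting and its two limits", {
    r <- generateIndependentRaster(64, 4000, 0.25, seed = 12)
    h <- runPRG(r, kMax = 4)
    sc <- silenceCurve(h)
    expect_equal(sc@value[1], log(1 - mean(rasterValues(r))))
    expect_lt(abs(exponent(sc) - 1), 0.06)

    rf <- generateFullyCorrelatedRaster(64, 4000, 0.25, seed = 13)
    sf <- silenceCurve(runPRG(rf, kMax = 4))
    # the silence event is identical at every scale
    expect_true(all(abs(sf@normalized - 1) < 1e-12))
    expect_equal(exponent(sf), 0, tolerance = 1e-10)

    all1 <- makeRaster(matrix(1, 8, 200))
    expect_error(silenceCurve(runPRG(all1, kMax = 2)), "silence")
})

test_that("eigen-spectra match a brute-force decomposition per cluster", {
    r <- generatePowerLawRaster(generatePositions(32, seed = 14), 0.5, 1,
                                1200, seed = 15)
    h <- runPRG(r, kMax = 4)
    es <- eigenspectrumCurve(h, KSet = c(8, 16))
    X0 <- rasterValues(h@rasters[[1]])
    mem <- h@members[[4]]
    oracle <- rowMeans(vapply(mem, function(ids) {
        sort(eigen(cov(t(X0[ids, ])))$values, decreasing = TRUE)
    }, numeric(8)))
    expect_equal(es@spectra$K8, oracle, tolerance = 1e-10)
})

test_that("eigen-spectrum limits: flat when independent, rank-1 when shared", {
    ri <- generateIndependentRaster(64, 4000, 0.3, seed = 16)
    es <- eigenspectrumCurve(runPRG(ri, kMax = 4))
    expect_lt(abs(exponent(es)), 0.1)

    rf <- generateFullyCorrelatedRaster(64, 4000, 0.3, seed = 17)
    hf <- runPRG(rf, kMax = 4)
    X0 <- rasterValues(hf@rasters[[1]])
    ids <- hf@members[[4]][[1]]
    ev <- sort(eigen(cov(t(X0[ids, ])))$values, decreasing = TRUE)
    expect_gt(ev[1], 0)
    expect_true(all(abs(ev[-1]) < 1e-10 * ev[1]))
})

test_that("the mu-eta relation follows the stated dimensional form", {
    expect_equal(muEtaRelation(3, 0.513), (3 - 0.513) / 3)
    expect_equal(muEtaRelation(3, 0), 1)
    expect_equal(muEtaRelation(3, 3), 0)
    expect_error(muEtaRelation(3, 3.2), "lie in")
})

test_that("subsampling at fraction 1 reproduces the full result", {
    r <- generatePowerLawRaster(generatePositions(72, seed = 18), 0.5, 1,
                                1500, seed = 19)
    h <- runPRG(r, kMax = 4)
    sub <- subsamplePRG(r, fraction = 1, kMax = 4)
    expect_equal(sub$alpha, exponent(varianceCurve(h)))
    s1 <- subsamplePRG(r, fraction = 0.5, seed = 20, kMax = 4)
    s2 <- subsamplePRG(r, fraction = 0.5, seed = 20, kMax = 4)
    expect_identical(s1$nodes, s2$nodes)
    expect_equal(s1$alpha, s2$alpha)
    expect_error(subsamplePRG(r, fraction = 0.1, kMax = 4), "cannot support")
})
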