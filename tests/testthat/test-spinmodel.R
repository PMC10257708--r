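test_that("infinite temperature gives unbiased independent spins", {
    C <- randomConn(10, seed = 1)
    tr <- metropolisSample(C, beta = 0, nSamples = 5000,
                           burnInAttempts = 1000, storeInterval = 10,
                           seed = 2)
    expect_lt(abs(mean(tr@M)), 3 / sqrt(5000 * 10))
    expect_true(all(tr@configurations %in% c(-1L, 1L)))
})

test_that("two coupled spins reach the closed-form correlation", {
    c12 <- 1; beta <- 0.4
    C <- makeConn(matrix(c(0, c12, c12, 0), 2), normalized = TRUE)
    tr <- metropolisSample(C, beta, nSamples = 60000,
                           burnInAttempts = 20000, storeInterval = 2,
                           seed = 3)
    prod <- tr@configurations[, 1] * tr@configurations[, 2]
    expect_lt(abs(mean(prod) - tanh(2 * beta * c12)), 3 * batchSE(prod))
})

test_that("enumeration oracle has the expected exact structure", {
    C <- makeConn(matrix(c(0, 0.6, 0.6, 0), 2), normalized = FALSE)
    em0 <- exactBoltzmannMoments(C, beta = 0)
    expect_equal(em0$Z, 4)
    expect_equal(em0$sisj[1, 2], 0)
    em <- exactBoltzmannMoments(C, beta = 0.5)
    expect_equal(em$sisj[1, 2], tanh(2 * 0.5 * 0.6))
    expect_equal(em$si, c(0, 0))   # global flip symmetry
    big <- randomConn(16, seed = 4)
    expect_error(exactBoltzmannMoments(big, 0.1), "N <= 15")
})

test_that("sampled moments agree with enumeration on a small system", {
    C <- randomConn(6, seed = 5)
    beta <- 0.35
    em <- exactBoltzmannMoments(C, beta)
    tr <- metropolisSample(C, beta, nSamples = 50000,
                           burnInAttempts = 50000, storeInterval = 6,
                           seed = 6)
    S <- tr@configurations
    checks <- logical(0)
    for (i in 1:6) {
        s <- S[, i]
        checks <- c(checks, abs(mean(s) - em$si[i]) < 4 * batchSE(s))
        for (j in seq_len(i - 1)) {
            p <- S[, i] * S[, j]
            checks <- c(checks,
                        abs(mean(p) - em$sisj[i, j]) < 4 * batchSE(p))
        }
    }
    expect_gt(mean(checks), 0.9)
})

test_that("incremental local fields never drift from recomputation", {
    C <- randomConn(40, seed = 7)
    tr <- metropolisSample(C, 0.5, nSamples = 2000, burnInAttempts = 50000,
                           storeInterval = 40, checkInterval = 10000,
                           seed = 8)
    expect_lt(tr@fieldCheckError, 1e-10)
})

test_that("the sampler rejects self-coupling", {
    w <- matrix(0.5, 3, 3)
    expect_error(
        metropolisSample(new("ConnectivityMatrix",
                             weights = w - diag(0.5, 3) + diag(0.2, 3),
                             normalized = FALSE), 0.1),
        "symmetric|diagonal")
})

test_that("order parameter grows with beta across the transition", {
    # near-uniform ferromagnetic couplings (slow EDR decay) so the whole
    # network orders globally at large beta
    fix <- edrSurrogate(nNodes = 64, gamma = 0.02, seed = 9)
    scan <- betaScan(fix$conn, betas = c(0.01, 0.1, 1), realizations = 2,
                     nSamples = 1500, burnInAttempts = 100000, seed = 10)
    a <- scan@meanAbsM
    expect_lt(a[1], 0.3)        # disordered: O(N^-1/2) activity
    expect_gt(a[3], 0.9)        # deep ordered phase
    expect_true(all(diff(a) > -0.05))
})

test_that("critical-point location validates its scan", {
    mkScan <- function(absM, chi) {
        new("BetaScanResult", beta = seq(0.1, by = 0.1,
                                         length.out = length(absM)),
            meanM = rep(0, length(absM)), meanAbsM = absM, chi = chi,
            perRealization = list(), realizations = 1L)
    }
    # interior peak, both phases spanned -> refined estimate inside grid
    s <- mkScan(c(0.05, 0.1, 0.3, 0.7, 0.9), c(1, 3, 8, 4, 2))
    bc <- criticalBeta(locateCriticalBeta(s))
    expect_gt(bc, 0.2); expect_lt(bc, 0.4)
    # single-phase scan rejected
    expect_error(locateCriticalBeta(mkScan(c(0.6, 0.7, 0.8, 0.9, 0.95),
                                           c(1, 2, 3, 2, 1))),
                 "straddle")
    # boundary peak rejected
    expect_error(locateCriticalBeta(mkScan(c(0.05, 0.2, 0.6, 0.8, 0.9),
                                           c(9, 5, 3, 2, 1))),
                 "boundary")
})

test_that("spin-raster conversion maps and round-trips conventions", {
    C <- randomConn(5, seed = 11)
    tr <- metropolisSample(C, 0.2, nSamples = 200, burnInAttempts = 1000,
                           storeInterval = 5, seed = 12)
    kept <- spinsToRaster(tr, "keep")
    r01 <- spinsToRaster(tr, "map01")
    expect_identical(2 * rasterValues(r01) - 1, kept + 0)
    expect_identical(dim(kept), c(5L, 200L))
    allUp <- new("SpinTrace",
                 configurations = matrix(1L, 4, 3), beta = 1,
                 burnInAttempts = 0, storeInterval = 1, M = rep(1, 4),
                 fieldCheckError = 0)
    expect_true(all(rasterValues(spinsToRaster(allUp, "map01")) == 1))
})

test_that("variance scaling of model activity is seed-reproducible", {
    fix <- edrSurrogate(nNodes = 64, seed = 13)
    alphas <- vapply(c(21, 22), function(s) {
        tr <- metropolisSample(fix$conn, 0.45, nSamples = 3000,
                               burnInAttempts = 150000, seed = s)
        h <- runPRG(spinsToRaster(tr, "map01"), kMax = 4)
        f <- varianceCurve(h)
        c(exponent(f), exponentError(f))
    }, numeric(2))
    combined <- sqrt(sum(alphas[2, ]^2))
    expect_lt(abs(alphas[1, 1] - alphas[1, 2]), 3 * combined + 0.1)
})
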