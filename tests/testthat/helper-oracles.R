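# Independent oracles used to validate the implementation. Each is a
# deliberately naive or closed-form computation, kept free of the package
# code paths it checks.

# Monte-Carlo standard error of the mean of a correlated series via batch
# means (contiguous batches absorb the autocorrelation).
batchSE <- function(x, nBatches = 100) {
    n <- length(x)
    b <- floor(n / nBatches)
    means <- vapply(seq_len(nBatches),
                    function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                    numeric(1))
    stats::sd(means) / sqrt(nBatches)
}

# Upper-orthant probability P(X > th, Y > th) of a standard bivariate
# normal with correlation rho, by one-dimensional quadrature.
bvnOrthant <- function(rho, th) {
    if (rho > 1 - 1e-12) return(1 - pnorm(th))
    f <- function(x) dnorm(x) * pnorm((rho * x - th) / sqrt(1 - rho^2))
    integrate(f, th, Inf, rel.tol = 1e-10)$value
}

# Correlation of two thresholded (dichotomized) unit Gaussians with latent
# correlation rho -- the tetrachoric mapping.
dichotomizedCorrelation <- function(rho, th) {
    p <- 1 - pnorm(th)
    (bvnOrthant(rho, th) - p^2) / (p * (1 - p))
}

# Expected binned correlation function of the dichotomized-Gaussian
# fixture: the latent kernel mapped pair-by-pair through the tetrachoric
# relation and averaged over the same distance bins the package uses.
oracleEtaDG <- function(geometry, eta, theta, dr, window) {
    kern <- powerLawKernel(geometry, eta)
    d <- as.matrix(dist(positions(geometry)))
    ut <- upper.tri(d)
    bin <- floor(d[ut] / dr)
    cexp <- vapply(kern$rho[ut], dichotomizedCorrelation, numeric(1),
                   th = theta)
    gexp <- tapply(cexp, bin, mean)
    centers <- as.numeric(names(gexp)) * dr + dr / 2
    keep <- gexp > 0
    -fitLogLogPowerLaw(centers[keep], as.numeric(gexp[keep]),
                       window = window)$exponent
}

# Literal re-execution of the greedy pairing rule by scanning all entries
# with nested loops (no vectorized shortcuts).
bruteGreedyPairs <- function(s) {
    n <- nrow(s)
    alive <- rep(TRUE, n)
    pairs <- NULL
    while (sum(alive) >= 2) {
        best <- -Inf; bi <- bj <- 0L
        for (i in seq_len(n - 1)) {
            if (!alive[i]) next
            for (j in (i + 1):n) {
                if (!alive[j]) next
                v <- s[i, j]
                if (is.na(v)) v <- -Inf
                if (v > best) { best <- v; bi <- i; bj <- j }
            }
        }
        pairs <- rbind(pairs, c(bi, bj))
        alive[c(bi, bj)] <- FALSE
    }
    list(pairs = pairs, leftover = which(alive))
}
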