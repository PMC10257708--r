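# Pairwise spin model on a weighted connectome: Metropolis sampling,
# exact enumeration for small systems, inverse-temperature scans and
# critical-point location.
#
# Energy convention: E(sigma) = -beta * sum_{i,j} C_ij sigma_i sigma_j with
# an ordered double sum, so each undirected pair is counted twice and the
# Boltzmann weight is exp(-E). Because beta is already inside E, the
# Metropolis acceptance is exp(-dE). All closed-form benchmarks (the
# two-spin correlation tanh(2 beta c), the square-lattice critical point
# beta_c = ln(1 + sqrt(2)) / 4) are stated in this convention.

#' Metropolis sampling of the connectome spin model
#'
#' Starts from a uniform random +/-1 configuration, attempts single-spin
#' flips of uniformly chosen nodes, accepts a flip with probability
#' min(1, exp(-dE)) where dE = 4 beta sigma_i h_i and h_i is the cached
#' local field, and stores the configuration every `storeInterval` attempts
#' once `burnInAttempts` attempts have elapsed. Local fields are updated
#' incrementally and re-derived from scratch every `checkInterval` attempts;
#' the largest bookkeeping deviation is returned with the trace.
#'
#' @param C a \linkS4class{ConnectivityMatrix} (zero diagonal enforced).
#' @param beta inverse temperature >= 0 (scales the couplings).
#' @param nSamples number of stored configurations.
#' @param burnInAttempts flip attempts discarded before storing.
#' @param storeInterval attempts between stored configurations (default N,
#'   i.e. one sweep).
#' @param checkInterval attempts between from-scratch local-field checks.
#' @param seed integer seed.
#' @return a \linkS4class{SpinTrace}.
#' @export
metropolisSample <- function(C, beta, nSamples = 50000,
                             burnInAttempts = 500000,
                             storeInterval = NULL, checkInterval = 10000,
                             seed = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"))
    if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
        stop("'beta' must be a single non-negative number")
    w <- C@weights
    if (any(diag(w) != 0))
        stop("self-coupling is undefined: C must have a zero diagonal")
    if (is.null(storeInterval)) storeInterval <- nrow(w)
    stopifnot(nSamples >= 1, burnInAttempts >= 0, storeInterval >= 1)
    res <- withSeed(seed, {
        cpp_metropolis(w, beta, as.integer(nSamples),
                       as.numeric(burnInAttempts),
                       as.integer(storeInterval),
                       as.numeric(checkInterval))
    })
    new("SpinTrace", configurations = res$configurations, beta = beta,
        burnInAttempts = as.numeric(burnInAttempts),
        storeInterval = as.numeric(storeInterval),
        M = as.numeric(res$M),
        fieldCheckError = res$fieldCheckError)
}

#' Exact Boltzmann moments by enumeration
#'
#' Sums over all 2^N spin configurations to compute exact first and second
#' moments and the partition function under
#' P(sigma) = exp(beta sum_{i,j} C_ij sigma_i sigma_j) / Z. Test oracle for
#' the Metropolis sampler; limited to N <= 15.
#'
#' @param C a \linkS4class{ConnectivityMatrix} with at most 15 nodes.
#' @param beta inverse temperature.
#' @return list with `si` (N vector of <sigma_i>), `sisj` (N x N matrix of
#'   <sigma_i sigma_j>), `meanM`, `meanM2`, `meanAbsM` and `Z`.
#' @export
exactBoltzmannMoments <- function(C, beta) {
    stopifnot(is(C, "ConnectivityMatrix"))
    w <- C@weights
    n <- nrow(w)
    if (n > 15L)
        stop("exact enumeration limited to N <= 15 (2^N configurations)")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    colnames(S) <- NULL
    E <- -beta * rowSums((S %*% w) * S)
    lw <- -E
    lw <- lw - max(lw)          # overflow guard; Z rescaled back below
    wts <- exp(lw)
    Z <- sum(wts) * exp(max(-E) - max(lw))  # equals sum(exp(-E))
    p <- wts / sum(wts)
    m <- rowMeans(S)
    list(si = as.numeric(colSums(S * p)),
         sisj = t(S) %*% (S * p),
         meanM = sum(m * p),
         meanM2 = sum(m^2 * p),
         meanAbsM = sum(abs(m) * p),
         Z = sum(exp(-E)))
}

#' Scan the spin model over inverse temperatures
#'
#' Runs `realizations` independent Metropolis chains (different random
#' initial conditions) at each beta and averages the order parameter and
#' susceptibility over realizations. Per realization: <M>, <|M|> and
#' chi = N (<M^2> - <|M|>^2) across stored configurations. <|M|> (not <M>)
#' is the order parameter, to avoid sign cancellation between symmetric
#' ordered branches.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @param betas ascending numeric grid of inverse temperatures.
#' @param realizations chains per beta.
#' @param nSamples,burnInAttempts,storeInterval,checkInterval passed to
#'   [metropolisSample()].
#' @param seed master seed; each (beta, realization) chain gets a derived
#'   seed via [deriveSeed()].
#' @return a \linkS4class{BetaScanResult}.
#' @export
betaScan <- function(C, betas, realizations = 5, nSamples = 50000,
                     burnInAttempts = 500000, storeInterval = NULL,
                     checkInterval = 10000, seed = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"), is.numeric(betas),
              length(betas) >= 2)
    if (is.unsorted(betas, strictly = TRUE))
        stop("'betas' must be strictly ascending")
    nb <- length(betas)
    mM <- mA <- ch <- matrix(NA_real_, nb, realizations)
    for (b in seq_len(nb)) {
        for (rlz in seq_len(realizations)) {
            s <- if (is.null(seed)) NULL else
                deriveSeed(seed, sprintf("beta%03d_real%02d", b, rlz))
            tr <- metropolisSample(C, betas[b], nSamples = nSamples,
                                   burnInAttempts = burnInAttempts,
                                   storeInterval = storeInterval,
                                   checkInterval = checkInterval, seed = s)
            m <- tr@M
            mM[b, rlz] <- mean(m)
            mA[b, rlz] <- mean(abs(m))
            ch[b, rlz] <- ncol(tr@configurations) *
                (mean(m^2) - mean(abs(m))^2)
        }
    }
    new("BetaScanResult", beta = as.numeric(betas),
        meanM = rowMeans(mM), meanAbsM = rowMeans(mA), chi = rowMeans(ch),
        perRealization = list(meanM = mM, meanAbsM = mA, chi = ch),
        realizations = as.integer(realizations))
}

#' Locate the critical inverse temperature from a scan
#'
#' The critical point is estimated as the susceptibility peak, refined by a
#' quadratic interpolation through the peak and its two neighbors. The scan
#' must straddle the transition (order parameter near zero at one end and
#' above 0.5 at the other) and the peak must be interior to the grid.
#'
#' @param scan a \linkS4class{BetaScanResult}.
#' @return the scan with its `betaC` slot filled; retrieve it with
#'   [criticalBeta()].
#' @export
locateCriticalBeta <- function(scan) {
    stopifnot(is(scan, "BetaScanResult"))
    a <- scan@meanAbsM
    if (!(min(a) < 0.25 && max(a) > 0.5))
        stop("scan does not straddle the transition (<|M|> range [",
             signif(min(a), 3), ", ", signif(max(a), 3),
             "]); widen the beta grid")
    i <- which.max(scan@chi)
    if (i == 1L || i == length(scan@chi))
        stop("susceptibility peak at the grid boundary; widen the beta grid")
    x <- scan@beta[(i - 1):(i + 1)]
    y <- scan@chi[(i - 1):(i + 1)]
    # vertex of the parabola through the three points around the peak
    d21 <- (y[2] - y[1]) / (x[2] - x[1])
    d32 <- (y[3] - y[2]) / (x[3] - x[2])
    curv <- (d32 - d21) / (x[3] - x[1])
    bc <- if (curv < 0)
        0.5 * (x[1] + x[2] - d21 / curv)
    else scan@beta[i]
    bc <- min(max(bc, x[1]), x[3])
    scan@betaC <- bc
    scan
}

#' @rdname locateCriticalBeta
#' @param scan a \linkS4class{BetaScanResult} processed by
#'   [locateCriticalBeta()].
#' @export
criticalBeta <- function(scan) {
    stopifnot(is(scan, "BetaScanResult"))
    scan@betaC
}

#' Convert spin configurations to a raster
#'
#' `"map01"` maps -1 to 0 and +1 to 1 and returns a level-0
#' \linkS4class{BinaryRaster} (N x S), enabling the variance and
#' eigen-spectrum PRG observables on model activity. The silence observable
#' remains undefined for spin data: the +/-1 symmetry admits no silent
#' state, so `silenceCurve()` on model rasters is not meaningful. `"keep"`
#' returns the +/-1 matrix unchanged (transposed to N x S).
#'
#' @param trace a \linkS4class{SpinTrace}.
#' @param convention "map01" or "keep".
#' @return a \linkS4class{BinaryRaster} (map01) or a numeric matrix (keep).
#' @export
spinsToRaster <- function(trace, convention = c("map01", "keep")) {
    stopifnot(is(trace, "SpinTrace"))
    convention <- match.arg(convention)
    m <- t(trace@configurations)
    if (convention == "keep") return(m)
    new("BinaryRaster", values = (m + 1) / 2, level = 0L)
}
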