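# Binarization of continuous recordings and the distance-resolved
# correlation function g(r).

#' Binarize signals at a z-score threshold
#'
#' Each row is z-scored over the full record and set to 1 where z > theta,
#' 0 otherwise. The default theta = 1 keeps roughly the supra-threshold
#' excursions of each signal (about 16% of frames for Gaussian signals).
#' Binarization is invariant to per-row affine transforms with positive
#' gain.
#'
#' @param X numeric N x T matrix of continuous signals.
#' @param theta threshold in z-units.
#' @return a level-0 \linkS4class{BinaryRaster}.
#' @export
zscoreBinarize <- function(X, theta = 1) {
    stopifnot(is.matrix(X), is.numeric(X))
    v <- rowVariances(X)
    if (any(v == 0))
        stop("zero-variance row(s): ",
             paste(head(which(v == 0), 5), collapse = ", "),
             if (sum(v == 0) > 5) ", ..." else "")
    z <- (X - rowMeans(X)) / sqrt(v)
    new("BinaryRaster", values = (z > theta) + 0, level = 0L)
}

#' Pairwise Pearson correlation matrix
#'
#' Correlations between all row pairs of a raster or signal matrix. Rows
#' with zero variance yield NA entries (reported with a warning) rather
#' than silent zeros.
#'
#' @param x numeric N x T matrix or \linkS4class{BinaryRaster}.
#' @return symmetric N x N matrix with unit diagonal on valid rows.
#' @export
pairwisePearson <- function(x) {
    m <- asSignalMatrix(x)
    v <- rowVariances(m)
    cc <- suppressWarnings(stats::cor(t(m)))
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance row(s); their correlations ",
                "are NA")
        cc[v == 0, ] <- NA_real_
        cc[, v == 0] <- NA_real_
    }
    cc
}

#' Distance-resolved correlation function g(r)
#'
#' Averages the pairwise correlation c_ij over node pairs whose Euclidean
#' distance falls in half-open bins [r, r + dr). Half-open bins prevent any
#' pair from being counted twice. All N(N-1)/2 pairs are assigned to a bin;
#' pairs with undefined correlation contribute to the pair count but not to
#' the bin mean.
#'
#' @param corr N x N correlation matrix (e.g. from [pairwisePearson()]).
#' @param geometry the matching \linkS4class{NodeGeometry}.
#' @param dr bin width in mm (default 0.43 mm, fine enough to resolve
#'   centroid distances at whole-brain parcellation scale).
#' @return a \linkS4class{CorrelationFunction}.
#' @export
correlationFunction <- function(corr, geometry, dr = 0.43) {
    stopifnot(is.matrix(corr), is(geometry, "NodeGeometry"), dr > 0)
    n <- nrow(corr)
    if (n != nrow(positions(geometry)))
        stop("correlation matrix and geometry disagree on N")
    d <- distanceMatrix(positions(geometry))
    ut <- upper.tri(corr)
    bin <- floor(d[ut] / dr)
    cij <- corr[ut]
    counts <- tapply(cij, bin, length)
    gbar <- tapply(cij, bin, function(z) {
        z <- z[is.finite(z)]
        if (length(z)) mean(z) else NA_real_
    })
    edges <- as.numeric(names(counts)) * dr
    new("CorrelationFunction", r = edges, g = as.numeric(gbar),
        nPairs = as.numeric(counts), binWidth = dr, nNodes = as.integer(n))
}

#' Fit the correlation-function decay exponent
#'
#' Power-law fit g(r) ~ r^-eta of a correlation function over a distance
#' window, against the exponential alternative. The regression uses bin
#' centers; bins with g <= 0 are excluded (log undefined) and counted in
#' the result.
#'
#' @param cf a \linkS4class{CorrelationFunction}.
#' @param window numeric length-2 distance window in mm; the default
#'   \code{c(10, 90)} is the standard whole-brain fitting range.
#' @return a \linkS4class{PowerLawFit}; the decay exponent eta is
#'   \code{-exponent(fit)}.
#' @export
fitCorrelationExponent <- function(cf, window = c(10, 90)) {
    stopifnot(is(cf, "CorrelationFunction"))
    fitPowerLaw(cf@r + cf@binWidth / 2, cf@g, window = window)
}

#' Scan power-law fit windows of g(r)
#'
#' Re-fits the correlation-function power law for every combination of
#' window edges, flagging windows with fewer than 3 positive bins as
#' invalid. Used to check that the estimated exponent is stable over a
#' region of the (rmin, rmax) plane rather than an artifact of one window.
#'
#' @param cf a \linkS4class{CorrelationFunction}.
#' @param rminGrid,rmaxGrid numeric vectors of window edges in mm.
#' @return data.frame with columns rmin, rmax, eta, etaSE, r2, rEV, nBins,
#'   valid.
#' @export
scanFitWindow <- function(cf, rminGrid, rmaxGrid) {
    stopifnot(is(cf, "CorrelationFunction"))
    grid <- expand.grid(rmin = rminGrid, rmax = rmaxGrid)
    grid <- grid[grid$rmin < grid$rmax, , drop = FALSE]
    centers <- cf@r + cf@binWidth / 2
    out <- lapply(seq_len(nrow(grid)), function(i) {
        win <- c(grid$rmin[i], grid$rmax[i])
        ok <- is.finite(cf@g) & cf@g > 0 & centers >= win[1] &
            centers <= win[2]
        if (sum(ok) < 3L)
            return(data.frame(rmin = win[1], rmax = win[2], eta = NA_real_,
                              etaSE = NA_real_, r2 = NA_real_,
                              rEV = NA_real_, nBins = sum(ok),
                              valid = FALSE))
        f <- fitPowerLaw(centers, cf@g, window = win)
        data.frame(rmin = win[1], rmax = win[2], eta = -f@exponent,
                   etaSE = f@exponentSE, r2 = f@r2PowerLaw, rEV = f@rEV,
                   nBins = f@nPoints, valid = TRUE)
    })
    do.call(rbind, out)
}
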