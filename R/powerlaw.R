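# Least-squares power-law fitting with an exponential alternative.
#
# Distribution-tail (MLE/Kolmogorov-Smirnov) machinery is deliberately not
# used: the quantities fitted here (variances, free energies, correlation
# functions, eigenvalues) are not probability densities, so the fits are
# ordinary least squares on transformed coordinates and model adequacy is
# judged by the explained-variance ratio of the two competing regressions.

# OLS on (u, v) in closed form; returns slope, intercept, slope SE and
# R^2. A zero total sum of squares (constant v) is a perfect fit of the
# constant model: slope 0, R^2 = 1.
.olsLine <- function(u, v) {
    n <- length(u)
    ubar <- mean(u)
    vbar <- mean(v)
    suu <- sum((u - ubar)^2)
    if (suu == 0) stop("degenerate fit: no spread on the x axis")
    slope <- sum((u - ubar) * (v - vbar)) / suu
    intercept <- vbar - slope * ubar
    ssr <- sum((v - intercept - slope * u)^2)
    sst <- sum((v - vbar)^2)
    slopeSE <- if (n > 2L) sqrt(ssr / (n - 2L) / suu) else NA_real_
    r2 <- if (sst < .Machine$double.eps * n) 1 else 1 - ssr / sst
    list(slope = slope, intercept = intercept, slopeSE = slopeSE, r2 = r2)
}

# Select the common point set for both regression models: finite, strictly
# positive x and y, inside the window.
.fitPointSet <- function(x, y, window) {
    stopifnot(length(x) == length(y))
    keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    if (!is.null(window)) {
        stopifnot(length(window) == 2L, window[1] <= window[2])
        keep <- keep & x >= window[1] & x <= window[2]
    }
    list(x = x[keep], y = y[keep], nExcluded = sum(!keep))
}

#' Fit a power law by least squares on log-log coordinates
#'
#' Fits the linear model log y = a log x + b. Points with non-positive x or
#' y (log undefined) and points outside the window are excluded; their count
#' is reported.
#'
#' @param x,y positive numeric vectors.
#' @param window optional numeric length-2 x-range to restrict the fit.
#' @return list with `exponent` (a), `intercept` (b), `exponentSE`, `r2`,
#'   `nPoints`, `nExcluded`.
#' @examples
#' fitLogLogPowerLaw(c(1, 2, 4, 8, 16), c(1, 2, 4, 8, 16)^2)$exponent  # 2
#' @export
fitLogLogPowerLaw <- function(x, y, window = NULL) {
    pts <- .fitPointSet(x, y, window)
    if (length(pts$x) < 3L)
        stop("need at least 3 positive points inside the window (have ",
             length(pts$x), ")")
    ols <- .olsLine(log(pts$x), log(pts$y))
    list(exponent = ols$slope, intercept = ols$intercept,
         exponentSE = unname(ols$slopeSE), r2 = ols$r2,
         nPoints = length(pts$x), nExcluded = pts$nExcluded)
}

#' Fit an exponential by least squares on semilog coordinates
#'
#' Fits the linear model log y = c x + d on the same point-selection rule as
#' [fitLogLogPowerLaw()] so both models see identical point sets.
#'
#' @inheritParams fitLogLogPowerLaw
#' @return list with `rate` (c), `intercept` (d), `rateSE`, `r2`, `nPoints`,
#'   `nExcluded`.
#' @export
fitSemilogExponential <- function(x, y, window = NULL) {
    pts <- .fitPointSet(x, y, window)
    if (length(pts$x) < 3L)
        stop("need at least 3 positive points inside the window (have ",
             length(pts$x), ")")
    ols <- .olsLine(pts$x, log(pts$y))
    list(rate = ols$slope, intercept = ols$intercept,
         rateSE = unname(ols$slopeSE), r2 = ols$r2,
         nPoints = length(pts$x), nExcluded = pts$nExcluded)
}

#' Explained-variance ratio between power-law and exponential fits
#'
#' @param r2PowerLaw,r2Exponential coefficients of determination of the two
#'   competing fits (computed on identical point sets).
#' @return R_EV = r2PowerLaw / r2Exponential; ratios above 1 favor the power
#'   law. When r2Exponential is 0 the ratio is reported as `Inf`.
#' @export
modelComparisonRatio <- function(r2PowerLaw, r2Exponential) {
    stopifnot(is.finite(r2PowerLaw), is.finite(r2Exponential))
    if (r2Exponential == 0) return(Inf)
    r2PowerLaw / r2Exponential
}

#' Power-law fit with exponential alternative and R_EV
#'
#' Runs both competing least-squares models on the identical positive point
#' set and assembles a \linkS4class{PowerLawFit} with the explained-variance
#' ratio R_EV and the relative exponent error 100 * SE(a) / |a|.
#'
#' @inheritParams fitLogLogPowerLaw
#' @return a \linkS4class{PowerLawFit}.
#' @examples
#' x <- c(1, 2, 4, 8, 16, 32)
#' fitPowerLaw(x, x^1.5)                 # exact power law, R_EV > 1
#' fitPowerLaw(x, exp(-0.5 * x))         # exact exponential, R_EV < 1
#' @export
fitPowerLaw <- function(x, y, window = NULL) {
    pl <- fitLogLogPowerLaw(x, y, window)
    ex <- fitSemilogExponential(x, y, window)
    stopifnot(pl$nPoints == ex$nPoints)
    rev <- modelComparisonRatio(pl$r2, ex$r2)
    relErr <- if (pl$exponent == 0) NA_real_ else
        100 * pl$exponentSE / abs(pl$exponent)
    new("PowerLawFit",
        exponent = pl$exponent, intercept = pl$intercept,
        exponentSE = pl$exponentSE, r2PowerLaw = pl$r2,
        expRate = ex$rate, expIntercept = ex$intercept,
        r2Exponential = ex$r2, rEV = rev,
        relativeErrorPercent = relErr,
        window = if (is.null(window)) c(-Inf, Inf) else as.numeric(window),
        nPoints = as.integer(pl$nPoints), nExcluded = as.integer(pl$nExcluded))
}
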