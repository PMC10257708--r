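#' @rdname NodeGeometry-class
#' @export
setMethod("positions", "NodeGeometry", function(object) object@coords)

#' @rdname NodeGeometry-class
#' @export
setMethod("hemisphereLabels", "NodeGeometry",
          function(object) object@hemisphere)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connWeights", "ConnectivityMatrix", function(object) object@weights)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("isNormalized", "ConnectivityMatrix",
          function(object) object@normalized)

#' @rdname BinaryRaster-class
#' @export
setMethod("rasterValues", "BinaryRaster", function(object) object@values)

#' @rdname BinaryRaster-class
#' @export
setMethod("rasterLevel", "BinaryRaster", function(object) object@level)

#' @rdname BinaryRaster-class
#' @export
setMethod("clusterSize", "BinaryRaster",
          function(object) as.integer(2^object@level))

#' @rdname exponent
#' @export
setMethod("exponent", "PowerLawFit", function(object) object@exponent)

#' @rdname exponent
#' @export
setMethod("exponentError", "PowerLawFit", function(object) object@exponentSE)

#' @rdname exponent
#' @export
setMethod("exponent", "ScalingCurve", function(object) object@fit@exponent)

#' @rdname exponent
#' @export
setMethod("exponentError", "ScalingCurve",
          function(object) object@fit@exponentSE)

#' @rdname exponent
#' @export
setMethod("exponent", "EigenSpectra", function(object) -object@fit@exponent)

#' @rdname exponent
#' @export
setMethod("exponentError", "EigenSpectra",
          function(object) object@fit@exponentSE)

#' @rdname explainedVarianceRatio
#' @export
setMethod("explainedVarianceRatio", "PowerLawFit", function(object) object@rEV)

#' @rdname explainedVarianceRatio
#' @export
setMethod("explainedVarianceRatio", "ScalingCurve",
          function(object) object@fit@rEV)

#' @rdname explainedVarianceRatio
#' @export
setMethod("explainedVarianceRatio", "EigenSpectra",
          function(object) object@fit@rEV)

setMethod("show", "NodeGeometry", function(object) {
    n <- nrow(object@coords)
    cat("NodeGeometry with", n, "nodes\n")
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  extent (mm): x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
    if (length(object@hemisphere))
        cat("  hemisphere labels: ", sum(object@hemisphere == 0L), "/",
            sum(object@hemisphere == 1L), " (0/1)\n", sep = "")
})

setMethod("show", "ConnectivityMatrix", function(object) {
    w <- object@weights
    cat("ConnectivityMatrix:", nrow(w), "x", ncol(w),
        if (object@normalized) "(normalized)" else "", "\n")
    off <- w[upper.tri(w)]
    cat(sprintf("  off-diagonal weights: max %.4g, mean %.4g, %.1f%% nonzero\n",
                max(off), mean(off), 100 * mean(off > 0)))
})

setMethod("show", "BinaryRaster", function(object) {
    cat(sprintf("BinaryRaster: %d variables x %d frames, level %d (K = %d)\n",
                nrow(object@values), ncol(object@values), object@level,
                2^object@level))
    cat(sprintf("  mean activity per frame-variable: %.4g\n",
                mean(object@values)))
})

setMethod("show", "CorrelationFunction", function(object) {
    cat(sprintf("CorrelationFunction: %d occupied bins, dr = %.3g mm, N = %d nodes\n",
                length(object@r), object@binWidth, object@nNodes))
    cat(sprintf("  r in [%.2f, %.2f] mm, g in [%.3g, %.3g]\n",
                min(object@r), max(object@r),
                min(object@g, na.rm = TRUE), max(object@g, na.rm = TRUE)))
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf("PowerLawFit: a = %.4g +/- %.2g (R2 = %.4f)\n",
                object@exponent, object@exponentSE, object@r2PowerLaw))
    cat(sprintf("  exponential alternative: c = %.4g (R2 = %.4f); R_EV = %.3f\n",
                object@expRate, object@r2Exponential, object@rEV))
    cat(sprintf("  %d points used, %d excluded\n",
                object@nPoints, object@nExcluded))
})

setMethod("show", "EDRFit", function(object) {
    cat(sprintf("EDRFit: gamma = %.4g +/- %.2g mm^-1 (R2 = %.3f, %d pairs, r < %.3g mm)\n",
                object@gamma, object@gammaSE, object@r2, object@nPairs,
                object@fitMaxDistance))
})

setMethod("show", "CoarseGrainHierarchy", function(object) {
    n0 <- nrow(object@rasters[[1]]@values)
    cat(sprintf("CoarseGrainHierarchy (%s mode): %d levels, N0 = %d\n",
                object@mode, object@kMax, n0))
    nk <- vapply(object@rasters, function(r) nrow(r@values), integer(1))
    cat("  variables per level:", paste(nk, collapse = " -> "), "\n")
    nd <- sum(lengths(object@discarded))
    if (nd > 0) cat("  level-0 nodes discarded as leftovers:", nd, "\n")
})

setMethod("show", "ScalingCurve", function(object) {
    cat(sprintf("ScalingCurve (%s): K = %s\n", object@observable,
                paste(object@K, collapse = ", ")))
    if (length(object@excludedK))
        cat("  excluded K:", paste(object@excludedK, collapse = ", "), "\n")
    cat(sprintf("  exponent = %.4g +/- %.2g (R_EV = %.3f)\n",
                object@fit@exponent, object@fit@exponentSE, object@fit@rEV))
})

setMethod("show", "EigenSpectra", function(object) {
    cat("EigenSpectra for K =", paste(object@K, collapse = ", "), "\n")
    cat(sprintf("  mu = %.4g +/- %.2g over %d pooled points (R_EV = %.3f)\n",
                -object@fit@exponent, object@fit@exponentSE,
                nrow(object@points), object@fit@rEV))
})

setMethod("show", "SpinTrace", function(object) {
    cat(sprintf("SpinTrace: %d configurations of %d spins at beta = %.4g\n",
                nrow(object@configurations), ncol(object@configurations),
                object@beta))
    cat(sprintf("  <M> = %.4g, <|M|> = %.4g\n",
                mean(object@M), mean(abs(object@M))))
})

setMethod("show", "BetaScanResult", function(object) {
    cat(sprintf("BetaScanResult: %d beta values in [%.4g, %.4g], %d realizations\n",
                length(object@beta), min(object@beta), max(object@beta),
                object@realizations))
    if (!is.na(object@betaC))
        cat(sprintf("  located beta_c = %.4g\n", object@betaC))
})
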