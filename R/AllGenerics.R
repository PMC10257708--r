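#' @rdname NodeGeometry-class
#' @param object,x an object.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname NodeGeometry-class
#' @export
setGeneric("hemisphereLabels",
           function(object) standardGeneric("hemisphereLabels"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connWeights", function(object) standardGeneric("connWeights"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname BinaryRaster-class
#' @export
setGeneric("rasterValues", function(object) standardGeneric("rasterValues"))

#' @rdname BinaryRaster-class
#' @export
setGeneric("rasterLevel", function(object) standardGeneric("rasterLevel"))

#' @rdname BinaryRaster-class
#' @export
setGeneric("clusterSize", function(object) standardGeneric("clusterSize"))

#' Extract a fitted scaling exponent
#'
#' For a \linkS4class{PowerLawFit} this is the log-log slope a; for a
#' \linkS4class{ScalingCurve} the slope of its normalized observable vs K;
#' for an \linkS4class{EigenSpectra} the rank-decay exponent mu (the sign
#' convention lambda ~ (rank/K)^-mu makes mu = -slope).
#'
#' @param object a fitted object.
#' @return numeric exponent.
#' @export
setGeneric("exponent", function(object) standardGeneric("exponent"))

#' @rdname exponent
#' @export
setGeneric("exponentError", function(object) standardGeneric("exponentError"))

#' Explained-variance ratio of power-law vs exponential fits
#'
#' @param object a fitted object carrying both model fits.
#' @return numeric R_EV = R2(power law) / R2(exponential).
#' @export
setGeneric("explainedVarianceRatio",
           function(object) standardGeneric("explainedVarianceRatio"))
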