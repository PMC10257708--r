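#' Node geometry: 3D coordinates of network nodes
#'
#' Positions (in mm) of the N nodes of a brain-wide network, e.g. the
#' centroids of an atlas parcellation. Distances between nodes are Euclidean.
#'
#' @slot coords numeric matrix, N x 3, coordinates in mm.
#' @slot hemisphere integer vector of length N with values 0/1 tagging the
#'   hemisphere of each node, or length 0 when no tag is available.
#' @exportClass NodeGeometry
setClass("NodeGeometry",
         slots = c(coords = "matrix", hemisphere = "integer"),
         prototype = prototype(hemisphere = integer(0)))

setValidity("NodeGeometry", function(object) {
    xyz <- object@coords
    if (!is.numeric(xyz) || ncol(xyz) != 3L)
        return("coords must be a numeric N x 3 matrix")
    if (nrow(xyz) < 2L)
        return("at least 2 nodes are required")
    if (!all(is.finite(xyz)))
        return("all coordinates must be finite")
    if (anyDuplicated(xyz) > 0L)
        return("duplicated node positions (zero pairwise distance)")
    nh <- length(object@hemisphere)
    if (nh != 0L && nh != nrow(xyz))
        return("hemisphere must have length 0 or N")
    if (nh > 0L && !all(object@hemisphere %in% c(0L, 1L)))
        return("hemisphere labels must be 0 or 1")
    TRUE
})

#' Symmetric non-negative coupling matrix
#'
#' Holds structural couplings C_ij between nodes (e.g. fiber counts from
#' tractography or an EDR model). The matrix is symmetric with zero diagonal;
#' when `normalized` the maximum entry is 1 so weights live in [0, 1].
#'
#' @slot weights numeric N x N matrix.
#' @slot normalized logical flag.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
         slots = c(weights = "matrix", normalized = "logical"),
         prototype = prototype(normalized = FALSE))

setValidity("ConnectivityMatrix", function(object) {
    w <- object@weights
    if (!is.numeric(w) || nrow(w) != ncol(w))
        return("weights must be a square numeric matrix")
    if (nrow(w) < 2L)
        return("at least 2 nodes are required")
    if (!all(is.finite(w)))
        return("weights must be finite")
    if (any(w < 0))
        return("weights must be non-negative")
    if (any(diag(w) != 0))
        return("diagonal must be zero (no self-coupling)")
    if (max(abs(w - t(w))) > 1e-9 * max(1, max(abs(w))))
        return("weights must be symmetric")
    if (isTRUE(object@normalized) && abs(max(w) - 1) > 1e-12)
        return("normalized matrix must have maximum entry 1")
    TRUE
})

#' Binary activity raster (possibly coarse-grained)
#'
#' N x T matrix of activity. At level 0 entries are 0/1; after k
#' coarse-graining steps each row is the sum of a cluster of 2^k original
#' variables, so entries are integers in [0, 2^k].
#'
#' @slot values integer-valued numeric N x T matrix.
#' @slot level integer coarse-graining depth k (cluster size K = 2^k).
#' @exportClass BinaryRaster
setClass("BinaryRaster",
         slots = c(values = "matrix", level = "integer"),
         prototype = prototype(level = 0L))

setValidity("BinaryRaster", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("values must be a numeric matrix")
    k <- object@level
    if (length(k) != 1L || is.na(k) || k < 0L)
        return("level must be a single non-negative integer")
    if (any(v != round(v)))
        return("entries must be integers")
    if (min(v) < 0 || max(v) > 2^k)
        return(sprintf("level-%d entries must lie in [0, %d]", k, 2^k))
    TRUE
})

#' Distance-resolved correlation function g(r)
#'
#' Mean pairwise correlation among node pairs whose distance falls in the
#' half-open bin [r, r + dr). Bins with no pairs are dropped; `nPairs` sums
#' to N(N-1)/2 over the retained bins.
#'
#' @slot r numeric, left bin edges in mm.
#' @slot g numeric, mean correlation per bin (NA when all pair correlations
#'   in the bin are undefined).
#' @slot nPairs numeric, pair count per bin.
#' @slot binWidth numeric scalar dr in mm.
#' @slot nNodes integer, number of nodes the function was computed from.
#' @exportClass CorrelationFunction
setClass("CorrelationFunction",
         slots = c(r = "numeric", g = "numeric", nPairs = "numeric",
                   binWidth = "numeric", nNodes = "integer"))

setValidity("CorrelationFunction", function(object) {
    n <- length(object@r)
    if (length(object@g) != n || length(object@nPairs) != n)
        return("r, g and nPairs must have equal length")
    if (length(object@binWidth) != 1L || object@binWidth <= 0)
        return("binWidth must be a positive scalar")
    if (any(object@nPairs <= 0))
        return("retained bins must contain at least one pair")
    tot <- object@nNodes * (object@nNodes - 1) / 2
    if (abs(sum(object@nPairs) - tot) > 1e-8)
        return("pair counts must sum to N(N-1)/2")
    TRUE
})

#' Power-law fit with exponential alternative
#'
#' Result of fitting log Y = a log X + b (power law) and log Y = c X + d
#' (exponential) to the same positive point set by ordinary least squares.
#' R_EV = R2(power law) / R2(exponential); values above 1 favor the power
#' law. `relativeErrorPercent` is 100 * Delta(a) / |a| with Delta(a) the
#' standard error of the log-log slope.
#'
#' @slot exponent,intercept,exponentSE numeric: a, b and SE(a).
#' @slot r2PowerLaw numeric coefficient of determination of the log-log fit.
#' @slot expRate,expIntercept numeric: c and d of the semilog fit.
#' @slot r2Exponential numeric coefficient of determination of the semilog fit.
#' @slot rEV numeric explained-variance ratio (Inf when r2Exponential = 0).
#' @slot relativeErrorPercent numeric relative exponent error in percent.
#' @slot window numeric length-2 x-range used, or c(-Inf, Inf).
#' @slot nPoints integer number of points entering both fits.
#' @slot nExcluded integer number of points dropped (non-positive or outside
#'   the window).
#' @exportClass PowerLawFit
setClass("PowerLawFit",
         slots = c(exponent = "numeric", intercept = "numeric",
                   exponentSE = "numeric", r2PowerLaw = "numeric",
                   expRate = "numeric", expIntercept = "numeric",
                   r2Exponential = "numeric", rEV = "numeric",
                   relativeErrorPercent = "numeric", window = "numeric",
                   nPoints = "integer", nExcluded = "integer"))

#' Exponential-distance-rule fit
#'
#' Least-squares fit of ln C_ij = -gamma * r_ij + const over node pairs with
#' positive weight and distance below `fitMaxDistance`.
#'
#' @slot gamma numeric decay rate in 1/mm.
#' @slot gammaSE numeric standard error of gamma.
#' @slot fitMaxDistance numeric distance cutoff in mm.
#' @slot r2 numeric coefficient of determination of the semilog fit.
#' @slot nPairs integer number of pairs used.
#' @exportClass EDRFit
setClass("EDRFit",
         slots = c(gamma = "numeric", gammaSE = "numeric",
                   fitMaxDistance = "numeric", r2 = "numeric",
                   nPairs = "integer"))

#' Coarse-graining hierarchy produced by the PRG
#'
#' Records everything produced by iterated pairwise coarse-graining: the
#' raster at each level, the pairing used to build it, the level-0 members
#' of every coarse variable, discarded (leftover) nodes, and -- in
#' connectivity mode -- the coarse connectivity matrix at each level.
#'
#' @slot rasters list of length kMax + 1; element k + 1 is the level-k
#'   \linkS4class{BinaryRaster}.
#' @slot pairings list of pairings (two-column index matrices) applied at
#'   each step.
#' @slot members list of length kMax + 1; element k + 1 is a list mapping
#'   each level-k variable to its level-0 member indices.
#' @slot discarded list of integer vectors of level-0 ids dropped at each
#'   step (leftover variable when the count was odd).
#' @slot connectivities list of coarse weight matrices per level
#'   (connectivity mode only; empty otherwise).
#' @slot mode character, "correlation" or "connectivity".
#' @slot kMax integer, number of coarse-graining steps.
#' @exportClass CoarseGrainHierarchy
setClass("CoarseGrainHierarchy",
         slots = c(rasters = "list", pairings = "list", members = "list",
                   discarded = "list", connectivities = "list",
                   mode = "character", kMax = "integer"))

#' Scaling curve of a PRG observable
#'
#' Observable values (variance V or silence free energy F) per cluster size
#' K = 2^k, normalized by the level-0 value, together with the power-law fit
#' of the normalized curve.
#'
#' @slot K numeric cluster sizes.
#' @slot value numeric raw observable per K (NA where excluded).
#' @slot normalized numeric observable normalized by its K = 1 value.
#' @slot excludedK numeric cluster sizes excluded from the fit (e.g. levels
#'   with zero empirical silence probability).
#' @slot observable character label ("variance" or "silence free energy").
#' @slot fit the \linkS4class{PowerLawFit} of normalized value vs K.
#' @exportClass ScalingCurve
setClass("ScalingCurve",
         slots = c(K = "numeric", value = "numeric", normalized = "numeric",
                   excludedK = "numeric", observable = "character",
                   fit = "ANY"))

#' Rank spectra of within-cluster covariance eigenvalues
#'
#' For each cluster size K, eigenvalues of the K x K covariance matrix of
#' the level-0 signals of cluster members, sorted descending and averaged
#' rank-wise across clusters of equal K. The pooled power-law fit of
#' eigenvalue vs relative rank (rank/K) within 1/K < rank/K < 0.4 gives the
#' decay exponent mu.
#'
#' @slot K numeric cluster sizes.
#' @slot spectra list of numeric eigenvalue vectors, one per K.
#' @slot points data.frame of pooled (relRank, lambda) points in the fit
#'   window.
#' @slot fit the pooled \linkS4class{PowerLawFit}; mu = -exponent(fit).
#' @exportClass EigenSpectra
setClass("EigenSpectra",
         slots = c(K = "numeric", spectra = "list", points = "data.frame",
                   fit = "ANY"))

#' Metropolis-sampled spin configurations
#'
#' Stored +/-1 configurations of the connectome spin model at a fixed
#' inverse temperature beta, after burn-in, thinned every `storeInterval`
#' flip attempts.
#'
#' @slot configurations integer S x N matrix of spins in {-1, +1}.
#' @slot beta numeric inverse temperature (scales the coupling matrix).
#' @slot burnInAttempts numeric flip attempts discarded before storing.
#' @slot storeInterval numeric flip attempts between stored configurations.
#' @slot M numeric population activity (mean spin) per stored configuration.
#' @slot fieldCheckError numeric largest deviation between incrementally
#'   updated and recomputed local fields observed during the run.
#' @exportClass SpinTrace
setClass("SpinTrace",
         slots = c(configurations = "matrix", beta = "numeric",
                   burnInAttempts = "numeric", storeInterval = "numeric",
                   M = "numeric", fieldCheckError = "numeric"))

setValidity("SpinTrace", function(object) {
    if (!all(object@configurations %in% c(-1L, 1L)))
        return("configurations must contain only -1 and +1")
    if (length(object@M) != nrow(object@configurations))
        return("M must have one value per stored configuration")
    if (any(object@M < -1 | object@M > 1))
        return("population activity must lie in [-1, 1]")
    TRUE
})

#' Inverse-temperature scan of the spin model
#'
#' Order parameter and susceptibility over a beta grid. Per realization the
#' order parameter is the mean absolute population activity <|M|> and the
#' susceptibility is chi = N (<M^2> - <|M|>^2); both are averaged over
#' realizations started from independent initial conditions.
#'
#' @slot beta numeric grid of inverse temperatures.
#' @slot meanM,meanAbsM,chi numeric per-beta averages over realizations.
#' @slot perRealization list with matrices meanM, meanAbsM, chi of dimension
#'   length(beta) x realizations.
#' @slot realizations integer number of realizations per beta.
#' @slot betaC numeric critical-point estimate (NA until located).
#' @exportClass BetaScanResult
setClass("BetaScanResult",
         slots = c(beta = "numeric", meanM = "numeric", meanAbsM = "numeric",
                   chi = "numeric", perRealization = "list",
                   realizations = "integer", betaC = "numeric"),
         prototype = prototype(betaC = NA_real_))

setValidity("BetaScanResult", function(object) {
    if (is.unsorted(object@beta, strictly = TRUE))
        return("beta grid must be strictly increasing")
    n <- length(object@beta)
    if (length(object@meanM) != n || length(object@meanAbsM) != n ||
        length(object@chi) != n)
        return("observable vectors must match the beta grid")
    if (any(object@meanAbsM < 0 | object@meanAbsM > 1))
        return("meanAbsM must lie in [0, 1]")
    if (any(object@chi < -1e-9))
        return("susceptibility must be non-negative")
    TRUE
})
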