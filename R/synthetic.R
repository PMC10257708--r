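# Synthetic geometries, connectivities and binary rasters with known
# statistical structure, plus the two shuffling controls. These generators
# make every downstream stage testable without any external recording.

#' Generate uniform node positions in a 3D box
#'
#' Stand-in for atlas parcellation centroids: n node positions drawn
#' uniformly in a box. The default extent (140 x 170 x 100 mm) is a
#' human-cortex bounding scale, chosen so pairwise distances span the same
#' order of magnitude as parcellation centroid distances.
#'
#' @param nNodes number of nodes (>= 2).
#' @param extent numeric length-3 box dimensions in mm, strictly positive.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a \linkS4class{NodeGeometry}; nodes in the left half of the box
#'   along x are tagged hemisphere 0, the rest 1.
#' @examples
#' geo <- generatePositions(100, seed = 1)
#' range(dist(positions(geo)))
#' @export
generatePositions <- function(nNodes, extent = c(140, 170, 100), seed = NULL) {
    if (!is.numeric(nNodes) || length(nNodes) != 1L || nNodes < 2)
        stop("'nNodes' must be a single count >= 2")
    if (!is.numeric(extent) || length(extent) != 3L || any(extent <= 0))
        stop("'extent' must be 3 strictly positive box dimensions (mm)")
    xyz <- withSeed(seed, {
        matrix(stats::runif(3 * nNodes), ncol = 3) %*% diag(extent)
    })
    colnames(xyz) <- c("x", "y", "z")
    hemi <- as.integer(xyz[, 1] > extent[1] / 2)
    new("NodeGeometry", coords = xyz, hemisphere = hemi)
}

#' Build an exponential-distance-rule connectivity
#'
#' Couplings decay exponentially with Euclidean distance,
#' C_ij = exp(-gamma r_ij), normalized so the largest off-diagonal entry is
#' 1. gamma = 0 gives a fully connected uniform network.
#'
#' @param geometry a \linkS4class{NodeGeometry}.
#' @param gamma decay rate in 1/mm (>= 0).
#' @return a normalized \linkS4class{ConnectivityMatrix}.
#' @export
generateEDRConnectivity <- function(geometry, gamma) {
    stopifnot(is(geometry, "NodeGeometry"))
    if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
        stop("'gamma' must be a single non-negative rate (1/mm)")
    r <- distanceMatrix(positions(geometry))
    w <- exp(-gamma * r)
    diag(w) <- 0
    w <- w / max(w)
    new("ConnectivityMatrix", weights = w, normalized = TRUE)
}

#' Independent Bernoulli raster
#'
#' N x T raster of i.i.d. Bernoulli(p) entries -- the uncorrelated limit in
#' which the coarse-grained variance grows linearly with cluster size.
#'
#' @param nNodes,nFrames raster dimensions.
#' @param p activation probability in (0, 1).
#' @param seed integer seed.
#' @return a level-0 \linkS4class{BinaryRaster}.
#' @export
generateIndependentRaster <- function(nNodes, nFrames, p, seed = NULL) {
    .checkRate(p)
    v <- withSeed(seed, {
        matrix(stats::rbinom(nNodes * nFrames, 1L, p), nrow = nNodes)
    })
    new("BinaryRaster", values = v, level = 0L)
}

#' Fully correlated raster
#'
#' One Bernoulli(p) series replicated to all nodes -- the fully correlated
#' limit in which the coarse-grained variance grows quadratically with
#' cluster size.
#'
#' @inheritParams generateIndependentRaster
#' @return a level-0 \linkS4class{BinaryRaster} with identical rows.
#' @export
generateFullyCorrelatedRaster <- function(nNodes, nFrames, p, seed = NULL) {
    .checkRate(p)
    row <- withSeed(seed, stats::rbinom(nFrames, 1L, p))
    v <- matrix(rep(row, each = nNodes), nrow = nNodes)
    new("BinaryRaster", values = v, level = 0L)
}

.checkRate <- function(p) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
        stop("'p' must be a probability strictly inside (0, 1)")
}

#' Distance-dependent power-law correlation kernel
#'
#' rho(r) = min(1, (r / r0)^-eta) with r0 the smallest pairwise distance of
#' the geometry, projected to the nearest correlation matrix by eigenvalue
#' clipping when the raw kernel is not positive semidefinite.
#'
#' @param geometry a \linkS4class{NodeGeometry}.
#' @param eta positive decay exponent of the latent correlation.
#' @return list with `rho` (N x N latent correlation matrix), `r0` and the
#'   number of clipped eigenvalues `nClipped`.
#' @export
powerLawKernel <- function(geometry, eta) {
    stopifnot(is(geometry, "NodeGeometry"))
    if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
        stop("'eta' must be a single positive exponent")
    r <- distanceMatrix(positions(geometry))
    r0 <- min(r[upper.tri(r)])
    rho <- pmin((r / r0)^(-eta), 1)  # pmin keeps the matrix shape this way
    diag(rho) <- 1
    e <- eigen(rho, symmetric = TRUE)
    nClip <- sum(e$values < 0)
    if (nClip > 0) {
        v <- pmax(e$values, 0)
        rho <- e$vectors %*% (v * t(e$vectors))
        d <- diag(rho)
        if (any(d <= 0))
            stop("kernel not representable: PSD projection produced a ",
                 "zero-variance node")
        rho <- rho / sqrt(d %o% d)
        # guard against a projection that changed the kernel materially
        if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) <
            -1e-8)
            stop("kernel not positive semidefinite after projection")
    }
    list(rho = rho, r0 = r0, nClipped = nClip)
}

#' Dichotomized-Gaussian raster with power-law spatial correlations
#'
#' Draws a latent zero-mean unit-variance Gaussian field whose correlation
#' between nodes i and j is the power-law kernel of [powerLawKernel()], then
#' thresholds it at `theta` z-units. The binary output inherits a
#' monotonically distance-decaying correlation structure whose exact shape
#' follows from the bivariate-normal orthant probability at the given
#' threshold (the tetrachoric mapping).
#'
#' @inheritParams powerLawKernel
#' @param theta threshold in z-units (the latent field is standard normal).
#' @param nFrames number of time frames.
#' @param seed integer seed.
#' @return a level-0 \linkS4class{BinaryRaster}.
#' @export
generatePowerLawRaster <- function(geometry, eta, theta = 1, nFrames,
                                   seed = NULL) {
    kern <- powerLawKernel(geometry, eta)
    e <- eigen(kern$rho, symmetric = TRUE)
    fac <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
    n <- nrow(kern$rho)
    z <- withSeed(seed, fac %*% matrix(stats::rnorm(n * nFrames), n))
    new("BinaryRaster", values = (z > theta) + 0, level = 0L)
}

#' Shuffle time frames independently per row
#'
#' Control that destroys all between-node correlations while preserving each
#' node's marginal statistics exactly: every row of the level-0 raster is
#' permuted with an independent random permutation. PRG scaling exponents on
#' the shuffled raster revert to the uncorrelated expectation of 1.
#'
#' @param raster a level-0 \linkS4class{BinaryRaster}.
#' @param seed integer seed.
#' @return a level-0 \linkS4class{BinaryRaster} with identical row sums.
#' @export
shuffleTimeFrames <- function(raster, seed = NULL) {
    stopifnot(is(raster, "BinaryRaster"))
    if (raster@level != 0L)
        stop("frame shuffling is defined for level-0 rasters")
    v <- raster@values
    nT <- ncol(v)
    out <- withSeed(seed, {
        t(apply(v, 1, function(row) row[sample.int(nT)]))
    })
    new("BinaryRaster", values = out, level = 0L)
}

#' Shuffle connectivity weights, destroying spatial organization
#'
#' Permutes the upper-triangle weights and mirrors them to the lower
#' triangle, preserving the weight distribution (multiset) exactly while
#' erasing any relation between weight and node position.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @param seed integer seed.
#' @return a \linkS4class{ConnectivityMatrix} with the same weight multiset.
#' @export
shuffleConnectivity <- function(C, seed = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"))
    w <- C@weights
    ut <- upper.tri(w)
    vals <- w[ut]
    perm <- withSeed(seed, vals[sample.int(length(vals))])
    out <- matrix(0, nrow(w), ncol(w))
    out[ut] <- perm
    out <- out + t(out)
    new("ConnectivityMatrix", weights = out, normalized = C@normalized)
}

#' Square-lattice nearest-neighbor connectivity
#'
#' L x L periodic square lattice with unit couplings between nearest
#' neighbors. Used to validate the spin-model sampler against the exactly
#' known critical point of the two-dimensional nearest-neighbor model
#' (beta_c = ln(1 + sqrt(2)) / 4 in the ordered-double-sum energy
#' convention used here).
#'
#' @param L lattice side length (>= 2).
#' @param periodic wrap boundaries into a torus (default TRUE).
#' @return a \linkS4class{ConnectivityMatrix} on L^2 nodes.
#' @export
squareLatticeConnectivity <- function(L, periodic = TRUE) {
    stopifnot(is.numeric(L), length(L) == 1L, L >= 2)
    L <- as.integer(L)
    n <- L * L
    idx <- function(i, j) ((i - 1L) %% L) * L + ((j - 1L) %% L) + 1L
    w <- matrix(0, n, n)
    for (i in seq_len(L)) {
        for (j in seq_len(L)) {
            a <- idx(i, j)
            right <- if (periodic || j < L) idx(i, j + 1L) else NA
            down  <- if (periodic || i < L) idx(i + 1L, j) else NA
            for (b in c(right, down)) {
                if (!is.na(b) && b != a) {
                    w[a, b] <- 1
                    w[b, a] <- 1
                }
            }
        }
    }
    new("ConnectivityMatrix", weights = w, normalized = TRUE)
}
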