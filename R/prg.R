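# Phenomenological renormalization group: greedy maximal pairing,
# coarse-graining of rasters and connectivities, and the three scaling
# observables (variance, silence free energy, within-cluster eigen-spectra).

#' Greedy maximal pairing of a similarity matrix
#'
#' Iteratively selects the pair of variables with the globally maximal
#' remaining similarity (signed value, not absolute), removes both from the
#' pool, and repeats until at most one variable is left. Ties are broken by
#' the smallest first index, then the smallest second index. NA entries
#' (e.g. correlations of zero-variance variables) are treated as -Inf and
#' paired last.
#'
#' @param similarity symmetric N x N numeric matrix.
#' @return list with `pairs` (floor(N/2) x 2 integer matrix, each row i < j
#'   in pairing order) and `leftover` (the unpaired index when N is odd,
#'   otherwise integer(0)).
#' @export
pairGreedy <- function(similarity) {
    stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
    n <- nrow(similarity)
    if (n < 2L) stop("need at least 2 variables to pair")
    s <- similarity
    s[!is.finite(s)] <- -Inf
    s[lower.tri(s, diag = TRUE)] <- -Inf
    nPairs <- n %/% 2L
    pairs <- matrix(0L, nPairs, 2L)
    for (p in seq_len(nPairs)) {
        mx <- max(s)
        idx <- which(s == mx)
        if (length(idx) > 1L) {
            ii <- (idx - 1L) %% n + 1L
            jj <- (idx - 1L) %/% n + 1L
            ord <- order(ii, jj)
            idx <- idx[ord[1L]]
        }
        i <- (idx - 1L) %% n + 1L
        j <- (idx - 1L) %/% n + 1L
        pairs[p, ] <- c(i, j)
        s[c(i, j), ] <- -Inf
        s[, c(i, j)] <- -Inf
    }
    leftover <- setdiff(seq_len(n), as.integer(pairs))
    list(pairs = pairs, leftover = as.integer(leftover))
}

#' Coarse-grain a raster by summing paired variables
#'
#' Each coarse variable is the elementwise (per-frame) sum of its pair; a
#' leftover variable is discarded. Summing preserves the total per-frame
#' activity whenever there is no leftover.
#'
#' @param raster a \linkS4class{BinaryRaster} at level k.
#' @param pairing result of [pairGreedy()] on the level-k variables.
#' @return a \linkS4class{BinaryRaster} at level k + 1.
#' @export
coarseGrainRaster <- function(raster, pairing) {
    stopifnot(is(raster, "BinaryRaster"))
    v <- raster@values
    p <- pairing$pairs
    if (max(p) > nrow(v))
        stop("pairing indices exceed the number of raster rows")
    out <- v[p[, 1L], , drop = FALSE] + v[p[, 2L], , drop = FALSE]
    new("BinaryRaster", values = out, level = raster@level + 1L)
}

#' Coarse-grain a connectivity matrix over a pairing
#'
#' The coupling between two coarse variables is the mean of the four
#' cross-pair couplings of their members, so after k steps each coarse
#' weight is the mean of 4^k original cross-weights. The output is
#' symmetric with zero diagonal.
#'
#' @param C numeric symmetric matrix at level k (or a
#'   \linkS4class{ConnectivityMatrix}).
#' @param pairing result of [pairGreedy()].
#' @return numeric matrix at level k + 1.
#' @export
coarseGrainConnectivity <- function(C, pairing) {
    w <- if (is(C, "ConnectivityMatrix")) C@weights else C
    stopifnot(is.matrix(w), nrow(w) == ncol(w))
    p <- pairing$pairs
    nP <- nrow(p)
    agg <- matrix(0, nP, nrow(w))
    agg[cbind(seq_len(nP), p[, 1L])] <- 1
    agg[cbind(seq_len(nP), p[, 2L])] <- 1
    out <- agg %*% w %*% t(agg) / 4
    diag(out) <- 0
    out
}

#' Run the phenomenological renormalization group
#'
#' Iteratively halves the system by pairing variables and summing them.
#' In `"correlation"` mode the pairing maximizes the pairwise Pearson
#' correlation, recomputed from the coarse variables at every level. In
#' `"connectivity"` mode the pairing maximizes the structural coupling,
#' and the coupling matrix is itself coarse-grained (4-weight mean) at
#' every level, so the grouping depends only on the connectivity, never on
#' the activity. When the number of variables at a level is odd, the
#' leftover variable is discarded from deeper levels (keeping every cluster
#' at exactly 2^k members) and logged.
#'
#' The sample-size rule T >= 10 * 2^kMax guards the reliability of
#' coarse-grained statistics; violating it is an error that reports the
#' maximal admissible depth.
#'
#' @param raster a level-0 \linkS4class{BinaryRaster}.
#' @param kMax number of coarse-graining steps (cluster size up to 2^kMax).
#' @param mode "correlation" or "connectivity".
#' @param connectivity a \linkS4class{ConnectivityMatrix} (required in
#'   connectivity mode).
#' @return a \linkS4class{CoarseGrainHierarchy}.
#' @export
runPRG <- function(raster, kMax = 6, mode = c("correlation", "connectivity"),
                   connectivity = NULL) {
    stopifnot(is(raster, "BinaryRaster"))
    mode <- match.arg(mode)
    kMax <- as.integer(kMax)
    if (kMax < 0L) stop("'kMax' must be >= 0")
    nT <- ncol(raster@values)
    if (nT < 10 * 2^kMax)
        stop(sprintf(
            "T = %d frames is too small for kMax = %d (need T >= 10 * 2^kMax); maximal admissible kMax is %d",
            nT, kMax, max(0L, floor(log2(nT / 10)))))
    if (mode == "connectivity") {
        if (is.null(connectivity))
            stop("connectivity mode requires a ConnectivityMatrix")
        stopifnot(is(connectivity, "ConnectivityMatrix"))
        if (nrow(connectivity@weights) != nrow(raster@values))
            stop("connectivity and raster disagree on N")
    }
    rasters <- vector("list", kMax + 1L)
    members <- vector("list", kMax + 1L)
    pairings <- vector("list", kMax)
    discarded <- vector("list", kMax)
    connectivities <- list()
    rasters[[1L]] <- raster
    members[[1L]] <- as.list(seq_len(nrow(raster@values)))
    curC <- if (mode == "connectivity") connectivity@weights else NULL
    if (mode == "connectivity") connectivities[[1L]] <- curC
    k <- 0L
    while (k < kMax) {
        cur <- rasters[[k + 1L]]
        if (nrow(cur@values) < 2L)
            stop("fewer than 2 variables left at level ", k,
                 "; reduce kMax")
        sim <- if (mode == "correlation") {
            suppressWarnings(pairwisePearson(cur))
        } else curC
        pairing <- pairGreedy(sim)
        rasters[[k + 2L]] <- coarseGrainRaster(cur, pairing)
        mem <- members[[k + 1L]]
        members[[k + 2L]] <- lapply(seq_len(nrow(pairing$pairs)), function(p)
            c(mem[[pairing$pairs[p, 1L]]], mem[[pairing$pairs[p, 2L]]]))
        discarded[[k + 1L]] <- if (length(pairing$leftover))
            sort(unlist(mem[pairing$leftover])) else integer(0)
        pairings[[k + 1L]] <- pairing
        if (mode == "connectivity") {
            curC <- coarseGrainConnectivity(curC, pairing)
            connectivities[[k + 2L]] <- curC
        }
        k <- k + 1L
    }
    new("CoarseGrainHierarchy", rasters = rasters, pairings = pairings,
        members = members, discarded = discarded,
        connectivities = connectivities, mode = mode, kMax = kMax)
}

#' Variance scaling curve V(K)
#'
#' Mean temporal variance of the coarse-grained variables at each level,
#' normalized by its level-0 value, with the power-law fit V ~ K^alpha.
#' Uncorrelated activity gives alpha = 1 (variances add), fully correlated
#' activity alpha = 2 (amplitudes add).
#'
#' @param h a \linkS4class{CoarseGrainHierarchy} with kMax >= 2.
#' @return a \linkS4class{ScalingCurve}; `exponent()` returns alpha.
#' @export
varianceCurve <- function(h) {
    stopifnot(is(h, "CoarseGrainHierarchy"))
    if (h@kMax < 2L) stop("need a hierarchy with kMax >= 2")
    K <- 2^(0:h@kMax)
    V <- vapply(h@rasters, function(r) mean(rowVariances(r@values)),
                numeric(1))
    if (V[1L] == 0) stop("level-0 variance is zero; nothing to normalize")
    vn <- V / V[1L]
    fit <- fitPowerLaw(K, vn)
    new("ScalingCurve", K = K, value = V, normalized = vn,
        excludedK = numeric(0), observable = "variance", fit = fit)
}

#' Silence free-energy scaling curve F(K)
#'
#' Per level, the silence probability of a cluster is the fraction of
#' frames in which its coarse variable equals 0; P_silence(K) averages this
#' across the retained clusters, and F(K) = ln P_silence(K) is the
#' associated free energy (-ln Z_K under a Boltzmann ansatz with null
#' silence energy). The curve F(K)/F(1) is fitted as a power of K; the
#' exponent beta is 1 for independent variables and 0 for fully correlated
#' ones. Levels with zero empirical silence probability are excluded with a
#' warning; an all-silent raster (F(1) = 0) is rejected.
#'
#' @param h a \linkS4class{CoarseGrainHierarchy} whose level-0 raster is
#'   {0,1}-valued (silence is undefined for +/-1 spin data).
#' @return a \linkS4class{ScalingCurve}; `exponent()` returns beta.
#' @export
silenceCurve <- function(h) {
    stopifnot(is(h, "CoarseGrainHierarchy"))
    if (h@kMax < 2L) stop("need a hierarchy with kMax >= 2")
    K <- 2^(0:h@kMax)
    P <- vapply(h@rasters, function(r) mean(rowMeans(r@values == 0)),
                numeric(1))
    if (P[1L] == 0)
        stop("no silent frames at level 0; silence free energy undefined")
    Fk <- log(P)
    if (Fk[1L] == 0)
        stop("all-silent raster: F(1) = 0, scaling undefined")
    excluded <- K[P == 0]
    if (length(excluded))
        warning("zero empirical silence probability at K = ",
                paste(excluded, collapse = ", "), "; excluded from the fit")
    ratio <- Fk / Fk[1L]
    keep <- P > 0
    fit <- fitPowerLaw(K[keep], ratio[keep])
    val <- Fk
    val[!keep] <- NA_real_
    norm <- ratio
    norm[!keep] <- NA_real_
    new("ScalingCurve", K = K, value = val, normalized = norm,
        excludedK = excluded, observable = "silence free energy", fit = fit)
}

#' Within-cluster covariance eigen-spectra and the rank exponent mu
#'
#' For each cluster of size K (members traced back to level-0 variables),
#' computes the eigenvalues of the K x K covariance matrix of the member
#' level-0 signals, sorts them in decreasing order, and averages them
#' rank-wise across clusters of equal K. The decay exponent mu is fitted by
#' pooling all (rank/K, lambda) points with 1/K < rank/K < 0.4, a window
#' that drops the rank-1 mode and the finite-size truncation tail. Cluster
#' sizes violating the sample rule T >= 10 K are excluded with a warning.
#'
#' @param h a \linkS4class{CoarseGrainHierarchy}.
#' @param KSet cluster sizes to include (powers of two up to 2^kMax);
#'   default all of 2, 4, ..., 2^kMax.
#' @return an \linkS4class{EigenSpectra}; `exponent()` returns mu.
#' @export
eigenspectrumCurve <- function(h, KSet = NULL) {
    stopifnot(is(h, "CoarseGrainHierarchy"))
    allK <- 2^(seq_len(h@kMax))
    if (is.null(KSet)) KSet <- allK
    if (!all(KSet %in% allK))
        stop("KSet must be powers of two between 2 and 2^kMax")
    X0 <- h@rasters[[1L]]@values
    nT <- ncol(X0)
    bad <- KSet[nT < 10 * KSet]
    if (length(bad)) {
        warning("excluding K = ", paste(bad, collapse = ", "),
                ": fewer than 10 samples per variable")
        KSet <- setdiff(KSet, bad)
    }
    if (!length(KSet)) stop("no admissible cluster sizes left")
    KSet <- sort(KSet)
    spectra <- vector("list", length(KSet))
    pts <- list()
    for (s in seq_along(KSet)) {
        K <- KSet[s]
        k <- as.integer(log2(K))
        mem <- h@members[[k + 1L]]
        specs <- vapply(mem, function(ids) {
            cv <- stats::cov(t(X0[ids, , drop = FALSE]))
            sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
        }, numeric(K))
        lam <- if (is.matrix(specs)) rowMeans(specs) else mean(specs)
        spectra[[s]] <- lam
        rel <- seq_len(K) / K
        win <- rel > 1 / K & rel < 0.4
        if (any(win))
            pts[[length(pts) + 1L]] <-
                data.frame(K = K, relRank = rel[win], lambda = lam[win])
    }
    names(spectra) <- paste0("K", KSet)
    points <- if (length(pts)) do.call(rbind, pts) else
        data.frame(K = numeric(0), relRank = numeric(0), lambda = numeric(0))
    if (nrow(points) < 3L)
        stop("fewer than 3 pooled spectrum points in the fit window; ",
             "include larger cluster sizes")
    fit <- fitPowerLaw(points$relRank, points$lambda)
    new("EigenSpectra", K = as.numeric(KSet), spectra = spectra,
        points = points, fit = fit)
}

#' Predicted eigen-spectrum exponent from the correlation exponent
#'
#' In a D-dimensional translation-invariant system with power-law
#' correlations g(r) ~ r^-eta, the covariance eigenvalues follow from the
#' Fourier transform of g and the rank exponent is mu = (D - eta) / D.
#' Deviations from this relation indicate broken translational invariance.
#'
#' @param D spatial dimension (> 0).
#' @param eta correlation decay exponent, 0 <= eta <= D.
#' @return predicted mu.
#' @examples
#' muEtaRelation(3, 0.513)  # 0.829
#' @export
muEtaRelation <- function(D, eta) {
    stopifnot(is.numeric(D), length(D) == 1L, D > 0,
              is.numeric(eta), length(eta) == 1L)
    if (eta < 0 || eta > D)
        stop("'eta' must lie in [0, D]")
    (D - eta) / D
}

#' PRG exponents on a random node subset
#'
#' Applies the PRG to a random fraction of the nodes and returns the three
#' scaling exponents, to probe how strongly the exponents depend on system
#' size. Deterministic given the seed.
#'
#' @param raster a level-0 \linkS4class{BinaryRaster}.
#' @param fraction fraction of nodes to retain, in (0, 1].
#' @param seed integer seed for the subset draw.
#' @param kMax,mode,connectivity passed to [runPRG()] (the connectivity is
#'   subset to the sampled nodes).
#' @return list with `alpha`, `beta`, `mu` (PowerLawFit-backed exponents;
#'   `beta` is NA when silence is undefined), `nodes` (the subset used) and
#'   the underlying `hierarchy`.
#' @export
subsamplePRG <- function(raster, fraction, seed = NULL, kMax = 6,
                         mode = "correlation", connectivity = NULL) {
    stopifnot(is(raster, "BinaryRaster"))
    if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
        stop("'fraction' must be in (0, 1]")
    n <- nrow(raster@values)
    nSub <- round(fraction * n)
    if (nSub < 2^kMax)
        stop("subset of ", nSub, " nodes cannot support kMax = ", kMax)
    nodes <- if (nSub == n) seq_len(n) else
        sort(withSeed(seed, sample.int(n, nSub)))
    sub <- new("BinaryRaster",
               values = raster@values[nodes, , drop = FALSE],
               level = raster@level)
    subC <- if (!is.null(connectivity)) {
        stopifnot(is(connectivity, "ConnectivityMatrix"))
        new("ConnectivityMatrix",
            weights = connectivity@weights[nodes, nodes],
            normalized = FALSE)
    } else NULL
    h <- runPRG(sub, kMax = kMax, mode = mode, connectivity = subC)
    vc <- varianceCurve(h)
    sc <- tryCatch(silenceCurve(h), error = function(e) NULL)
    es <- eigenspectrumCurve(h)
    list(alpha = exponent(vc),
         beta = if (is.null(sc)) NA_real_ else exponent(sc),
         mu = exponent(es), nodes = nodes, hierarchy = h)
}
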