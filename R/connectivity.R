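# Connectome-level analyses: weight normalization, EDR fitting, node
# strength and linear signal prediction from a coupling matrix.

#' Normalize a raw coupling matrix
#'
#' Forces the diagonal to zero, symmetrizes by averaging (with a warning)
#' when the input is asymmetric beyond tolerance 1e-9, and divides all
#' weights by the largest off-diagonal entry so they lie in [0, 1].
#' Idempotent on already-normalized inputs.
#'
#' @param raw square non-negative numeric matrix, or a
#'   \linkS4class{ConnectivityMatrix}.
#' @return a normalized \linkS4class{ConnectivityMatrix}.
#' @export
normalizeConnectivity <- function(raw) {
    w <- if (is(raw, "ConnectivityMatrix")) raw@weights else raw
    if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w))
        stop("'raw' must be a square numeric matrix")
    if (any(w < 0)) stop("weights must be non-negative")
    asym <- max(abs(w - t(w)))
    if (asym > 1e-9 * max(1, max(abs(w)))) {
        warning("asymmetric input (max |C - t(C)| = ", signif(asym, 3),
                "); symmetrized by averaging")
        w <- (w + t(w)) / 2
    }
    diag(w) <- 0
    mx <- max(w)
    if (mx == 0) stop("all-zero connectivity cannot be normalized")
    new("ConnectivityMatrix", weights = w / mx, normalized = TRUE)
}

#' Fit the exponential distance rule to a connectome
#'
#' Least-squares fit of ln C_ij = -gamma r_ij + const over node pairs with
#' strictly positive weight and distance below `maxDistance` (default 50 mm,
#' the short-range regime where the exponential decay holds). The fit uses
#' raw per-pair log-weights; set `binWidth` to fit binned mean log-weights
#' instead.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @param geometry the matching \linkS4class{NodeGeometry}.
#' @param maxDistance distance cutoff in mm.
#' @param binWidth optional bin width in mm; when given, the regression is
#'   on per-bin means of ln C_ij at bin-center distances.
#' @return an \linkS4class{EDRFit}.
#' @export
fitEDR <- function(C, geometry, maxDistance = 50, binWidth = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"), is(geometry, "NodeGeometry"))
    w <- C@weights
    r <- distanceMatrix(positions(geometry))
    if (nrow(w) != nrow(r))
        stop("connectivity and geometry disagree on the number of nodes")
    ut <- upper.tri(w)
    keep <- ut & w > 0 & r < maxDistance
    nk <- sum(keep)
    if (nk < 3L)
        stop("EDR fit needs >= 3 positive-weight pairs below maxDistance ",
             "(have ", nk, ")")
    xv <- r[keep]
    yv <- log(w[keep])
    if (!is.null(binWidth)) {
        stopifnot(binWidth > 0)
        b <- floor(xv / binWidth)
        xv <- tapply(xv, b, mean)
        yv <- tapply(yv, b, mean)
        if (length(xv) < 3L) stop("fewer than 3 occupied distance bins")
    }
    ols <- .olsLine(as.numeric(xv), as.numeric(yv))
    new("EDRFit", gamma = -ols$slope, gammaSE = unname(ols$slopeSE),
        fitMaxDistance = maxDistance, r2 = ols$r2, nPairs = as.integer(nk))
}

#' Node strength
#'
#' Sum of coupling weights of each node with the rest of the network,
#' s_i = sum_j C_ij.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @return numeric vector of length N.
#' @export
nodeStrength <- function(C) {
    stopifnot(is(C, "ConnectivityMatrix"))
    rowSums(C@weights)
}

#' Linear prediction of signals from couplings
#'
#' Predicts each node's signal as the coupling-weighted sum of all other
#' signals, X_pred = C X, and scores the prediction with the Pearson
#' correlation between X_pred_i(t) and X_i(t). With `nodeMask =
#' list(source =, target =)` only couplings from the source set into the
#' target set are used (e.g. intra- or inter-hemispheric variants); nodes
#' outside the target set get NA.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @param X numeric N x T signal matrix (rows match C's nodes).
#' @param nodeMask optional list with integer vectors `source` and `target`.
#' @return numeric vector of per-node correlations; NA (with a warning) for
#'   nodes whose own or predicted signal has zero variance.
#' @export
linearPredictionScores <- function(C, X, nodeMask = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"), is.matrix(X))
    w <- C@weights
    if (nrow(X) != nrow(w))
        stop("X must have one row per node of C")
    n <- nrow(X)
    targets <- seq_len(n)
    if (!is.null(nodeMask)) {
        stopifnot(is.list(nodeMask), all(c("source", "target") %in%
                                         names(nodeMask)))
        src <- as.integer(nodeMask$source)
        targets <- as.integer(nodeMask$target)
        mask <- matrix(0, n, n)
        mask[targets, src] <- 1
        w <- w * mask
    }
    pred <- w %*% X
    scores <- rep(NA_real_, n)
    sx <- rowVariances(X)
    sp <- rowVariances(pred)
    bad <- targets[sx[targets] == 0 | sp[targets] == 0]
    ok <- setdiff(targets, bad)
    for (i in ok)
        scores[i] <- stats::cor(pred[i, ], X[i, ])
    if (length(bad))
        warning("zero-variance signal or prediction for node(s) ",
                paste(head(bad, 5), collapse = ", "),
                if (length(bad) > 5) ", ..." else "",
                "; scores reported as NA")
    scores
}
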