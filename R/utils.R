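# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer or NULL")
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting rule used by the pipeline so that each stochastic
#' stage has its own reproducible seed: the master seed is mixed with a hash
#' of the stage name, modulo 2^31 - 2.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer seed in 1 .. 2^31 - 2.
#' @export
deriveSeed <- function(seed, stage) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 2) + 1)
}

# Per-row sample variances of a numeric matrix without forming apply() loops.
rowVariances <- function(x) {
    n <- ncol(x)
    if (n < 2L) stop("need at least 2 columns to compute a variance")
    mu <- rowMeans(x)
    (rowSums(x^2) - n * mu^2) / (n - 1)
}

# Pairwise Euclidean distances of an N x 3 coordinate matrix, as a full
# symmetric matrix.
distanceMatrix <- function(coords) {
    m <- as.matrix(stats::dist(coords))
    dimnames(m) <- NULL
    m
}

# Coerce raster-or-matrix input to a plain numeric matrix.
asSignalMatrix <- function(x) {
    if (is(x, "BinaryRaster")) return(x@values)
    if (is.matrix(x) && is.numeric(x)) return(x)
    stop("expected a numeric matrix or a BinaryRaster")
}
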