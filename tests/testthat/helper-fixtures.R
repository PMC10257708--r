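# Small constructors shared across test files. Fixtures are built in code;
# nothing is read from disk.

# Wrap a plain symmetric zero-diagonal matrix as a ConnectivityMatrix.
makeConn <- function(w, normalized = FALSE) {
    new("ConnectivityMatrix", weights = w, normalized = normalized)
}

# Random symmetric non-negative coupling matrix with zero diagonal.
randomConn <- function(n, seed) {
    set.seed(seed)
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    makeConn(w / max(w), normalized = TRUE)
}

makeRaster <- function(values, level = 0L) {
    new("BinaryRaster", values = values, level = as.integer(level))
}

# EDR surrogate study conditions used by the spin-model acceptance checks:
# 256 uniformly placed nodes in the default cortex-scale box, couplings
# exp(-0.106 r) (the whole-brain decay rate), fixed geometry seed.
edrSurrogate <- function(nNodes = 256, gamma = 0.106, seed = 31) {
    geo <- generatePositions(nNodes, seed = seed)
    list(geometry = geo, conn = generateEDRConnectivity(geo, gamma))
}
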