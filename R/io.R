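# Plain-text IO for geometries, connectivities, rasters and correlation
# functions. Matrices are tab-delimited without headers; node indices in
# triplet files are 1-based, matching neuroimaging convention. Every writer
# can drop a JSON sidecar recording provenance (generator spec and seed).

#' Write and read node geometries
#'
#' Geometries are stored as 3-column tab-delimited text (x, y, z in mm),
#' with an optional 4th column of hemisphere labels.
#'
#' @param geometry a \linkS4class{NodeGeometry}.
#' @param file path to the delimited file.
#' @param sidecar optional named list written as `<file>.json`.
#' @return `readGeometry` returns a \linkS4class{NodeGeometry}.
#' @export
writeGeometry <- function(geometry, file, sidecar = NULL) {
    stopifnot(is(geometry, "NodeGeometry"))
    df <- as.data.frame(positions(geometry))
    if (length(geometry@hemisphere))
        df$hemisphere <- geometry@hemisphere
    data.table::fwrite(df, file, sep = "\t", col.names = FALSE)
    .writeSidecar(file, sidecar)
    invisible(file)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(file) {
    df <- data.table::fread(file, header = FALSE)
    xyz <- as.matrix(df[, 1:3])
    colnames(xyz) <- c("x", "y", "z")
    hemi <- if (ncol(df) >= 4L) as.integer(df[[4L]]) else integer(0)
    new("NodeGeometry", coords = xyz, hemisphere = hemi)
}

#' Write and read connectivity matrices
#'
#' Square matrices are tab-delimited with no header. Triplet files carry
#' three columns (i, j, weight) with 1-based indices; missing entries are
#' zero and the matrix is symmetrized from the listed triangle.
#'
#' @param C a \linkS4class{ConnectivityMatrix}.
#' @param file path.
#' @param sidecar optional named list written as `<file>.json`.
#' @export
writeConnectivity <- function(C, file, sidecar = NULL) {
    stopifnot(is(C, "ConnectivityMatrix"))
    data.table::fwrite(as.data.frame(C@weights), file, sep = "\t",
                       col.names = FALSE)
    .writeSidecar(file, sidecar)
    invisible(file)
}

#' @rdname writeConnectivity
#' @param normalized flag stored on the object read back.
#' @export
readConnectivity <- function(file, normalized = FALSE) {
    m <- as.matrix(data.table::fread(file, header = FALSE))
    dimnames(m) <- NULL
    new("ConnectivityMatrix", weights = m, normalized = normalized)
}

#' @rdname writeConnectivity
#' @param nNodes number of nodes of the triplet-encoded matrix.
#' @export
readConnectivityTriplets <- function(file, nNodes) {
    df <- data.table::fread(file, header = FALSE)
    stopifnot(ncol(df) >= 3L)
    i <- as.integer(df[[1L]]); j <- as.integer(df[[2L]])
    if (any(i < 1L | i > nNodes | j < 1L | j > nNodes))
        stop("triplet indices outside 1..nNodes (indices are 1-based)")
    w <- matrix(0, nNodes, nNodes)
    w[cbind(i, j)] <- df[[3L]]
    w[cbind(j, i)] <- df[[3L]]
    diag(w) <- 0
    new("ConnectivityMatrix", weights = w, normalized = FALSE)
}

#' Write and read binary rasters
#'
#' Rasters are stored as N x T tab-delimited integer matrices; the
#' coarse-graining level is recorded in the JSON sidecar and must be passed
#' back on read (default 0).
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param file path.
#' @param sidecar optional named list; the level is always added.
#' @export
writeRaster <- function(raster, file, sidecar = NULL) {
    stopifnot(is(raster, "BinaryRaster"))
    data.table::fwrite(as.data.frame(raster@values), file, sep = "\t",
                       col.names = FALSE)
    .writeSidecar(file, c(list(level = raster@level), sidecar))
    invisible(file)
}

#' @rdname writeRaster
#' @param level coarse-graining level of the stored raster.
#' @export
readRaster <- function(file, level = 0L) {
    m <- as.matrix(data.table::fread(file, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    new("BinaryRaster", values = m, level = as.integer(level))
}

#' Write a correlation function as delimited columns
#'
#' Columns r (left bin edge, mm), g and nPairs; bin width and node count go
#' to the JSON sidecar.
#'
#' @param cf a \linkS4class{CorrelationFunction}.
#' @param file path.
#' @export
writeCorrelationFunction <- function(cf, file) {
    stopifnot(is(cf, "CorrelationFunction"))
    data.table::fwrite(data.frame(r = cf@r, g = cf@g, nPairs = cf@nPairs),
                       file, sep = "\t")
    .writeSidecar(file, list(binWidth = cf@binWidth, nNodes = cf@nNodes))
    invisible(file)
}

.writeSidecar <- function(file, sidecar) {
    if (is.null(sidecar)) return(invisible(NULL))
    jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(NULL)
}
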