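# Orchestration: configuration, staged end-to-end runs with per-stage
# error capture, JSON reports, and the statistical comparisons between
# exponent distributions.

#' Build an analysis configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' Every stochastic stage draws its seed from the single master seed via
#' [deriveSeed()], so stages can be re-run individually and reproducibly.
#'
#' @param signals numeric N x T matrix of continuous signals, or NULL when
#'   `raster` is given.
#' @param geometry a \linkS4class{NodeGeometry}.
#' @param raster optional pre-binarized \linkS4class{BinaryRaster}
#'   (bypasses the binarization stage).
#' @param connectivity optional \linkS4class{ConnectivityMatrix} enabling
#'   the connectivity-based PRG.
#' @param theta binarization threshold in z-units.
#' @param dr correlation-function bin width in mm.
#' @param fitWindow distance window (mm) for the g(r) power-law fit.
#' @param kMax coarse-graining depth.
#' @param spin optional list of spin-model settings: `betas`,
#'   `realizations`, `nSamples`, `burnInAttempts`.
#' @param seed master seed.
#' @param outputDir optional directory for the JSON report and curve files.
#' @return a named list of class `phenoRGConfig`.
#' @export
analysisConfig <- function(signals = NULL, geometry = NULL, raster = NULL,
                           connectivity = NULL, theta = 1, dr = 0.43,
                           fitWindow = c(10, 90), kMax = 6, spin = NULL,
                           seed = 1L, outputDir = NULL) {
    cfg <- list(signals = signals, geometry = geometry, raster = raster,
                connectivity = connectivity, theta = theta, dr = dr,
                fitWindow = fitWindow, kMax = kMax, spin = spin,
                seed = as.integer(seed), outputDir = outputDir)
    class(cfg) <- "phenoRGConfig"
    cfg
}

.stage <- function(report, name, expr) {
    res <- tryCatch(list(status = "ok", value = expr),
                    error = function(e) list(status = "failed",
                                             value = NULL,
                                             message = conditionMessage(e)))
    report$stages[[name]] <- c(list(status = res$status),
                               if (res$status == "failed")
                                   list(error = res$message))
    report$.values[[name]] <- res$value
    report
}

.fitSummary <- function(fit, flip = FALSE) {
    s <- if (flip) -1 else 1
    list(exponent = s * fit@exponent, exponentSE = fit@exponentSE,
         r2 = fit@r2PowerLaw, rEV = fit@rEV,
         relativeErrorPercent = fit@relativeErrorPercent)
}

.prgSummary <- function(h, silence = TRUE) {
    vc <- varianceCurve(h)
    es <- eigenspectrumCurve(h)
    out <- list(alpha = .fitSummary(vc@fit),
                mu = .fitSummary(es@fit, flip = TRUE),
                discardedNodes = sum(lengths(h@discarded)))
    if (silence) {
        sc <- silenceCurve(h)
        out$beta <- .fitSummary(sc@fit)
        out$excludedK <- sc@excludedK
    }
    out
}

#' Run the full analysis pipeline
#'
#' Executes binarization, the correlation function and its power-law fit,
#' the correlation-based PRG, the connectivity-based PRG (when couplings
#' are supplied) and optionally a spin-model scan with model-vs-data
#' exponent comparison. Each stage is wrapped so a failure is recorded in
#' the report and dependent stages are skipped rather than aborting the
#' run. With an `outputDir` the numeric report is written as `report.json`
#' together with the g(r) and scaling curves as delimited text; reruns with
#' the same configuration produce byte-identical numeric output.
#'
#' @param config a configuration from [analysisConfig()].
#' @return the report (named list), invisibly when written to disk.
#' @export
runFullAnalysis <- function(config) {
    stopifnot(inherits(config, "phenoRGConfig"))
    report <- list(
        meta = list(package = "phenoRG",
                    version = as.character(utils::packageVersion("phenoRG")),
                    seed = config$seed,
                    theta = config$theta, dr = config$dr,
                    fitWindow = config$fitWindow, kMax = config$kMax),
        stages = list(), .values = list())

    report <- .stage(report, "binarize", {
        if (!is.null(config$raster)) {
            config$raster
        } else {
            if (is.null(config$signals))
                stop("config must provide 'signals' or 'raster'")
            zscoreBinarize(config$signals, theta = config$theta)
        }
    })
    raster <- report$.values$binarize
    if (!is.null(raster))
        report$stages$binarize$activationRate <- mean(raster@values)

    report <- .stage(report, "corrfunc", {
        if (is.null(raster)) stop("binarization failed")
        if (is.null(config$geometry)) stop("no geometry supplied")
        cf <- correlationFunction(pairwisePearson(raster), config$geometry,
                                  dr = config$dr)
        fit <- fitCorrelationExponent(cf, window = config$fitWindow)
        list(cf = cf, fit = fit)
    })
    if (!is.null(report$.values$corrfunc))
        report$stages$corrfunc <- c(report$stages$corrfunc,
            list(eta = .fitSummary(report$.values$corrfunc$fit,
                                   flip = TRUE)))

    report <- .stage(report, "prg_correlation", {
        if (is.null(raster)) stop("binarization failed")
        h <- runPRG(raster, kMax = config$kMax, mode = "correlation")
        list(hierarchy = h, summary = .prgSummary(h))
    })
    if (!is.null(report$.values$prg_correlation))
        report$stages$prg_correlation <-
            c(report$stages$prg_correlation,
              report$.values$prg_correlation$summary)

    report <- .stage(report, "prg_connectivity", {
        if (is.null(raster)) stop("binarization failed")
        if (is.null(config$connectivity))
            stop("no connectivity supplied for the connectivity-based PRG")
        h <- runPRG(raster, kMax = config$kMax, mode = "connectivity",
                    connectivity = config$connectivity)
        list(hierarchy = h, summary = .prgSummary(h))
    })
    if (!is.null(report$.values$prg_connectivity))
        report$stages$prg_connectivity <-
            c(report$stages$prg_connectivity,
              report$.values$prg_connectivity$summary)

    if (!is.null(config$spin)) {
        report <- .stage(report, "spin", {
            if (is.null(config$connectivity))
                stop("spin model requires a connectivity")
            sp <- config$spin
            scan <- betaScan(config$connectivity, sp$betas,
                             realizations = sp$realizations %||% 5,
                             nSamples = sp$nSamples %||% 50000,
                             burnInAttempts = sp$burnInAttempts %||% 500000,
                             seed = deriveSeed(config$seed, "spin"))
            scan <- locateCriticalBeta(scan)
            tr <- metropolisSample(config$connectivity, criticalBeta(scan),
                                   nSamples = sp$nSamples %||% 50000,
                                   burnInAttempts = sp$burnInAttempts %||%
                                       500000,
                                   seed = deriveSeed(config$seed,
                                                     "spin_critical"))
            mr <- spinsToRaster(tr, "map01")
            mh <- runPRG(mr, kMax = config$kMax, mode = "correlation")
            msum <- .prgSummary(mh, silence = FALSE)
            mcf <- correlationFunction(pairwisePearson(mr),
                                       config$geometry, dr = config$dr)
            mfit <- tryCatch(
                fitCorrelationExponent(mcf, window = config$fitWindow),
                error = function(e) NULL)
            list(scan = scan, model = msum, modelEta = mfit)
        })
        sv <- report$.values$spin
        if (!is.null(sv)) {
            st <- report$stages$spin
            st$betaC <- criticalBeta(sv$scan)
            st$model <- sv$model[c("alpha", "mu")]
            if (!is.null(sv$modelEta))
                st$model$eta <- .fitSummary(sv$modelEta, flip = TRUE)
            # relative deviation of model exponents from the data exponents
            dataStage <- report$stages$prg_correlation
            if (identical(dataStage$status, "ok")) {
                rel <- function(m, d) abs(m - d) / abs(d)
                st$deltaAlpha <- rel(st$model$alpha$exponent,
                                     dataStage$alpha$exponent)
                st$deltaMu <- rel(st$model$mu$exponent,
                                  dataStage$mu$exponent)
                if (!is.null(st$model$eta) &&
                    identical(report$stages$corrfunc$status, "ok"))
                    st$deltaEta <- rel(st$model$eta$exponent,
                                       report$stages$corrfunc$eta$exponent)
            }
            report$stages$spin <- st
        }
    }

    values <- report$.values
    report$.values <- NULL
    if (!is.null(config$outputDir)) {
        dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(report,
                             file.path(config$outputDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (!is.null(values$corrfunc))
            writeCorrelationFunction(values$corrfunc$cf,
                                     file.path(config$outputDir, "gr.tsv"))
        for (m in c("prg_correlation", "prg_connectivity")) {
            if (is.null(values[[m]])) next
            h <- values[[m]]$hierarchy
            vc <- varianceCurve(h)
            data.table::fwrite(
                data.frame(K = vc@K, V = vc@value, Vnorm = vc@normalized),
                file.path(config$outputDir, paste0(m, "_variance.tsv")),
                sep = "\t")
        }
        return(invisible(report))
    }
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two distributions of exponents or correlations
#'
#' Two-sided tests used throughout the pipeline: a rank-based Wilcoxon test
#' for exponent distributions, or Welch's t-test after Fisher
#' z-transformation for distributions of correlation coefficients (which
#' must then lie strictly inside (-1, 1)).
#'
#' @param groupA,groupB numeric vectors (n >= 3 each).
#' @param kind "wilcoxon" or "welch_fisher_z".
#' @return list with `statistic`, `p.value` and `method`.
#' @export
compareExponentDistributions <- function(groupA, groupB,
                                         kind = c("wilcoxon",
                                                  "welch_fisher_z")) {
    kind <- match.arg(kind)
    stopifnot(is.numeric(groupA), is.numeric(groupB))
    if (length(groupA) < 3L || length(groupB) < 3L)
        stop("each group needs at least 3 values")
    if (kind == "wilcoxon") {
        t <- suppressWarnings(stats::wilcox.test(groupA, groupB))
        return(list(statistic = unname(t$statistic), p.value = t$p.value,
                    method = "Wilcoxon rank sum"))
    }
    if (any(abs(groupA) >= 1) || any(abs(groupB) >= 1))
        stop("Fisher z-transform requires correlations strictly in (-1, 1)")
    t <- stats::t.test(atanh(groupA), atanh(groupB), var.equal = FALSE)
    list(statistic = unname(t$statistic), p.value = t$p.value,
         method = "Welch t-test on Fisher z-transformed values")
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report produced by [runFullAnalysis()] against the JSON
#' schema in `inst/schema/report-schema.json`: required top-level fields,
#' required meta fields, and per-stage status values.
#'
#' @param report a report list or path to a report.json file.
#' @return TRUE invisibly; errors describe the first violation found.
#' @export
validateReport <- function(report) {
    if (is.character(report))
        report <- jsonlite::read_json(report, simplifyVector = TRUE)
    schema <- jsonlite::read_json(system.file("schema",
                                              "report-schema.json",
                                              package = "phenoRG"),
                                  simplifyVector = TRUE)
    for (f in schema$required)
        if (is.null(report[[f]]))
            stop("report is missing required field '", f, "'")
    for (f in schema$properties$meta$required)
        if (is.null(report$meta[[f]]))
            stop("report meta is missing required field '", f, "'")
    okStatus <- schema$properties$stages$statusValues
    for (s in names(report$stages)) {
        st <- report$stages[[s]]$status
        if (is.null(st) || !st %in% okStatus)
            stop("stage '", s, "' has invalid status")
    }
    invisible(TRUE)
}
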