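#' Default run configuration
#'
#' Gathers every tunable of the pipeline with its published default: the
#' lenient detection thresholds (depth 4, variant depth 2, base and mapping
#' quality 10), the DNA-only and triple-sample support-filter profiles, the
#' perfect-read parameters, the strand-bias (>4 alt reads, >90\% one
#' strand) and positional-bias (95\%) settings, the remap-check support
#' requirements (4 reads, 10\%), and the behavioral flags.
#'
#' @param dbsnpOnDom apply the dbSNP position filters to the DNA-only path
#'   as well (they normally act on the triple-sample path only).
#' @param posBiasOnDom apply the positional-bias filter to the DNA-only
#'   path as well.
#' @param singleEndProper treat single-end reads as properly paired.
#' @param seed RNG seed for the simulation subcommands.
#' @return A named list of class \code{RunConfig}.
#' @export
defaultConfig <- function(dbsnpOnDom = FALSE, posBiasOnDom = FALSE,
                          singleEndProper = TRUE, seed = 1L) {
    structure(list(
        detection = detectionParams(),
        dom = domProfiles(),
        tbm = tbmProfiles(),
        perfectRead = perfectReadParams(),
        posBiasThreshold = 0.95,
        strandBiasMinAlt = 4L,
        strandBiasMaxFraction = 0.90,
        remapMinValidReads = 4L,
        remapMinFraction = 0.10,
        dbsnpOnDom = dbsnpOnDom,
        posBiasOnDom = posBiasOnDom,
        singleEndProper = singleEndProper,
        seed = as.integer(seed)), class = "RunConfig")
}

loadRegionBindings <- function(paths) {
    intervalKeys <- c("blacklist", "pseudogene", "geneFamily")
    out <- list()
    for (k in names(paths)) {
        if (is.null(paths[[k]])) next
        out[[k]] <- if (is(paths[[k]], "RegionSet")) paths[[k]]
        else if (k %in% intervalKeys) loadBED(paths[[k]], name = k)
        else loadPositionList(paths[[k]], name = k)
    }
    out
}

#' Run the full calling pipeline
#'
#' Reads pileup columns (or takes them pre-built), evaluates every column
#' with both decision procedures, merges the passing somatic calls, applies
#' the perfect-read support filter, and writes the VCF and the per-filter
#' rejection report. Germline calls from the DNA-only path are written to
#' the VCF (tagged \code{CAT=germline}) but excluded from somatic
#' reporting. Reruns on the same inputs produce byte-identical outputs.
#'
#' @param input path to a pileup TSV (see \code{\link{readPileupTSV}}) or a
#'   list of \code{\link{PileupColumn-class}} objects.
#' @param config a \code{\link{defaultConfig}} list.
#' @param regions named list binding filter roles (\code{blacklist},
#'   \code{dbsnpCommon}, \code{dbsnpRetired}, \code{pseudogene},
#'   \code{geneFamily}) to file paths or \code{\link{RegionSet-class}}
#'   objects; missing roles disable their filter.
#' @param vcfPath,reportPath output paths (\code{NULL} skips writing).
#' @param remapAligner,remapLocus optional remap check, see
#'   \code{\link{tbmEvaluate}}.
#' @return A list: \code{calls} (final passing calls, germline + labeled
#'   somatic), \code{merged} (somatic calls after merge, including
#'   read-support failures), \code{report} (rejection table),
#'   \code{domCalls}, \code{tbmCalls} (per-method candidates incl.
#'   failures).
#' @export
runCall <- function(input, config = defaultConfig(), regions = list(),
                    vcfPath = NULL, reportPath = NULL,
                    remapAligner = NULL, remapLocus = NULL) {
    columns <- if (is.character(input)) readPileupTSV(input) else input
    regions <- loadRegionBindings(regions)

    domCalls <- list(); tbmCalls <- list(); colKey <- character(0)
    for (col in columns) {
        d <- domEvaluate(col, config$dom, regions, config$detection,
                         dbsnpOnDom = config$dbsnpOnDom,
                         posBiasOnDom = config$posBiasOnDom,
                         keepFailed = TRUE)
        if (!is.null(d)) domCalls[[length(domCalls) + 1L]] <- d
        t <- tbmEvaluate(col, config$tbm, regions, config$detection,
                         posBiasThreshold = config$posBiasThreshold,
                         remapAligner = remapAligner,
                         remapLocus = remapLocus, keepFailed = TRUE)
        if (!is.null(t)) tbmCalls[[length(tbmCalls) + 1L]] <- t
    }
    columnIndex <- setNames(
        seq_along(columns),
        vapply(columns, function(c) paste(c@chrom, c@pos), character(1)))

    merged <- mergeCalls(domCalls, tbmCalls)
    finalSomatic <- list(); supportFailed <- list()
    for (x in merged) {
        col <- columns[[columnIndex[[paste(x@chrom, x@pos)]]]]
        v <- readSupportFilter(x, col, config$perfectRead)
        if (v$passed) {
            finalSomatic[[length(finalSomatic) + 1L]] <- x
        } else {
            x@failedFilters <- v$failedFilters
            supportFailed[[length(supportFailed) + 1L]] <- x
        }
    }
    germline <- Filter(function(x) x@category == "germline" && callPassed(x),
                       domCalls)
    calls <- c(germline, finalSomatic)
    if (length(calls)) {
        ord <- order(vapply(calls, function(x) x@chrom, character(1)),
                     vapply(calls, function(x) x@pos, integer(1)))
        calls <- calls[ord]
    }
    report <- filterReport(list(DOM = domCalls, TBM = tbmCalls,
                                readSupport = supportFailed))
    if (!is.null(vcfPath))
        writeVCF(calls, vcfPath)
    if (!is.null(reportPath))
        write.table(report, reportPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    list(calls = calls, merged = c(finalSomatic, supportFailed),
         report = report, domCalls = domCalls, tbmCalls = tbmCalls)
}

#' Generate a synthetic dataset (pipeline wrapper)
#'
#' @param nColumns number of synthetic columns.
#' @param seed RNG seed (echoed in a message for the run log).
#' @param pileupPath,truthPath output paths.
#' @param specSampler optional per-column spec sampler, see
#'   \code{\link{generateDataset}}.
#' @return See \code{\link{generateDataset}}.
#' @export
runSynth <- function(nColumns, seed = 1L, pileupPath, truthPath,
                     specSampler = NULL) {
    message("generating ", nColumns, " synthetic columns with seed ", seed)
    generateDataset(nColumns, specSampler = specSampler, seed = seed,
                    pileupPath = pileupPath, truthPath = truthPath)
}
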