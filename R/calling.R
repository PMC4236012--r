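#' Default support-filter profiles for the DNA-only method
#'
#' Three threshold columns: the germline test on the normal DNA, and the
#' somatic test on the normal and tumor DNA. Germline variants require depth
#' 10, at least 4 alt reads at >=10\% with mean alt base quality 20, at most
#' 90\% of alt reads on one strand and at most 2\% third-allele support. The
#' somatic test requires normal depth 10 (power to have seen a germline
#' variant), at most 2\% alt and 2\% other support in the normal, and the
#' same evidence thresholds as germline on the tumor.
#'
#' @return A named list of \code{\link{thresholdSet}}s:
#'   \code{germlineNormal}, \code{somaticNormal}, \code{somaticTumor}.
#' @export
domProfiles <- function() {
    list(
        germlineNormal = thresholdSet(minTotalDepth = 10L, minAltDepth = 4L,
                                      minAltFraction = 0.10,
                                      minAvgAltBaseQual = 20,
                                      maxAltStrandFraction = 0.90,
                                      maxOtherFraction = 0.02),
        somaticNormal = thresholdSet(minTotalDepth = 10L,
                                     maxAltFraction = 0.02,
                                     maxOtherFraction = 0.02),
        somaticTumor = thresholdSet(minTotalDepth = 10L, minAltDepth = 4L,
                                    minAltFraction = 0.10,
                                    minAvgAltBaseQual = 20,
                                    maxAltStrandFraction = 0.90,
                                    maxOtherFraction = 0.02)
    )
}

#' Default support-filter profiles for the triple-sample method
#'
#' The normal DNA needs depth 10 with at most 10\% alt and 10\% other
#' support; the tumor DNA needs only a single alt read, but that read must
#' carry base quality >= 15 (distinguishing weak DNA support from pure RNA
#' signal, i.e. possible RNA editing); the tumor RNA carries the evidential
#' burden: depth 10, at least 4 alt reads at >= 10\% with mean alt base
#' quality 15, balanced strands, and at most 2\% third-allele support.
#'
#' @return A named list of \code{\link{thresholdSet}}s: \code{tbmNormal},
#'   \code{tbmTumorDna}, \code{tbmTumorRna}.
#' @export
tbmProfiles <- function() {
    list(
        tbmNormal = thresholdSet(minTotalDepth = 10L,
                                 maxAltFraction = 0.10,
                                 maxOtherFraction = 0.10),
        tbmTumorDna = thresholdSet(minTotalDepth = 1L, minAltDepth = 1L,
                                   minAvgAltBaseQual = 15,
                                   maxAltStrandFraction = 0.90,
                                   maxOtherFraction = 0.10),
        tbmTumorRna = thresholdSet(minTotalDepth = 10L, minAltDepth = 4L,
                                   minAltFraction = 0.10,
                                   minAvgAltBaseQual = 15,
                                   maxAltStrandFraction = 0.90,
                                   maxOtherFraction = 0.02)
    )
}

regionVerdict <- function(regions, keys, chrom, pos) {
    failed <- character(0)
    for (k in keys)
        if (containsPos(regions[[k]], chrom, pos))
            failed <- c(failed, k)
    failed
}

#' DNA-only method: evaluate one pileup column
#'
#' The matched normal DNA is compared with the reference first: a lenient
#' candidate in the normal that passes the germline profile yields a germline
#' call and ends the evaluation. Only when no germline variant is found is
#' the tumor DNA compared with the normal: a tumor candidate is tested
#' against the somatic normal/tumor profiles (the normal summarized for the
#' tumor's alt allele), with the accessible-genome blacklist and the
#' strand-bias check applied. With \code{dbsnpOnDom} the dbSNP position
#' filters (normally reserved for the triple-sample path) are applied too.
#'
#' @param column a \code{\link{PileupColumn-class}} with normal and tumor DNA
#'   observations.
#' @param profiles threshold profiles, see \code{\link{domProfiles}}.
#' @param regions named list of \code{\link{RegionSet-class}} objects; keys
#'   used here: \code{blacklist} (and \code{dbsnpCommon}/\code{dbsnpRetired}
#'   when \code{dbsnpOnDom}). Missing keys disable the filter.
#' @param params lenient detection parameters.
#' @param dbsnpOnDom also apply the dbSNP position filters to this path.
#' @param posBiasOnDom also apply the positional-bias filter (normally a
#'   triple-sample-path filter) to the tumor-DNA alt reads.
#' @param keepFailed return a failing \code{VariantCall} (with its
#'   \code{failedFilters}) instead of \code{NULL}; used for per-filter
#'   rejection reporting.
#' @return A \code{\link{VariantCall-class}} or \code{NULL}.
#' @export
domEvaluate <- function(column, profiles = domProfiles(), regions = list(),
                        params = detectionParams(), dbsnpOnDom = FALSE,
                        posBiasOnDom = FALSE, keepFailed = FALSE) {
    chrom <- columnChrom(column); pos <- columnPos(column)
    ref <- columnRef(column)
    normalObs <- roleObservations(column, "normalDNA")
    normalSum <- summarizeColumn(normalObs, ref,
                                 minBaseQual = params$minBaseQual,
                                 minMapQual = params$minMapQual)
    regionKeys <- "blacklist"
    if (dbsnpOnDom) regionKeys <- c("dbsnpCommon", "dbsnpRetired",
                                    "blacklist")

    germFailed <- NULL
    if (normalSum@depth >= params$minTotalDepth &&
        normalSum@altDepth >= params$minVariantDepth) {
        failed <- c(regionVerdict(regions, regionKeys, chrom, pos),
                    applyThresholds(normalSum, profiles$germlineNormal,
                                    "germlineNormal")$failedFilters)
        if (length(failed) == 0L)
            return(VariantCall(chrom, pos, ref, normalSum@altAllele,
                               category = "germline", origin = "DOM",
                               summaries = list(normalDNA = normalSum)))
        germFailed <- failed
    }

    tumorCand <- detectCandidate(column, "tumorDNA", params)
    if (is.null(tumorCand)) {
        if (keepFailed && !is.null(germFailed))
            return(VariantCall(chrom, pos, ref, normalSum@altAllele,
                               category = "germline", origin = "DOM",
                               summaries = list(normalDNA = normalSum),
                               failedFilters = germFailed))
        return(NULL)
    }
    alt <- tumorCand@altAllele
    normalAltSum <- summarizeColumn(normalObs, ref,
                                    minBaseQual = params$minBaseQual,
                                    minMapQual = params$minMapQual,
                                    altAllele = alt)
    failed <- c(regionVerdict(regions, regionKeys, chrom, pos),
                applyThresholds(normalAltSum, profiles$somaticNormal,
                                "somaticNormal")$failedFilters,
                applyThresholds(tumorCand, profiles$somaticTumor,
                                "somaticTumor")$failedFilters)
    if (posBiasOnDom) {
        tObs <- roleObservations(column, "tumorDNA")
        tAltObs <- tObs[tObs$base == alt & tObs$baseQual >= params$minBaseQual &
                        tObs$mapQual >= params$minMapQual, , drop = FALSE]
        failed <- c(failed, positionalBiasFilter(tAltObs)$failedFilters)
    }
    call <- VariantCall(chrom, pos, ref, alt, category = "somatic",
                        origin = "DOM",
                        summaries = list(normalDNA = normalAltSum,
                                         tumorDNA = tumorCand),
                        failedFilters = failed)
    if (length(failed) && !keepFailed) return(NULL)
    call
}

#' Triple-sample method: evaluate one pileup column
#'
#' A lenient candidate is detected in the tumor RNA; the tumor DNA and
#' normal DNA are then summarized for that same alternative allele (the RNA
#' alt must be the DNA-supported alt). The three per-role support profiles
#' are applied, followed in order by the dbSNP common and retired-version
#' position filters, the accessible-genome blacklist, the pseudogene and
#' gene-family interval filters, the positional-bias filter on the
#' alt-supporting RNA reads, and — when an aligner is supplied — the
#' re-mapping check. Strand bias is enforced inside the tumor DNA/RNA
#' profiles.
#'
#' @param column a \code{\link{PileupColumn-class}} with all three roles.
#' @param profiles threshold profiles, see \code{\link{tbmProfiles}}.
#' @param regions named list of \code{\link{RegionSet-class}}; keys used:
#'   \code{dbsnpCommon}, \code{dbsnpRetired}, \code{blacklist},
#'   \code{pseudogene}, \code{geneFamily}. Missing keys disable the filter.
#' @param params lenient detection parameters.
#' @param posBiasThreshold positional-bias failing fraction.
#' @param remapAligner optional best-placement function (see
#'   \code{\link{pairwiseRemapAligner}}); \code{NULL} skips the remap check.
#' @param remapLocus name of the home region in the aligner's reference.
#' @param keepFailed return failing calls instead of \code{NULL}.
#' @return A \code{\link{VariantCall-class}} or \code{NULL}.
#' @export
tbmEvaluate <- function(column, profiles = tbmProfiles(), regions = list(),
                        params = detectionParams(),
                        posBiasThreshold = 0.95, remapAligner = NULL,
                        remapLocus = NULL, keepFailed = FALSE) {
    chrom <- columnChrom(column); pos <- columnPos(column)
    ref <- columnRef(column)
    rnaCand <- detectCandidate(column, "tumorRNA", params)
    if (is.null(rnaCand)) return(NULL)
    alt <- rnaCand@altAllele

    normalSum <- summarizeColumn(roleObservations(column, "normalDNA"), ref,
                                 minBaseQual = params$minBaseQual,
                                 minMapQual = params$minMapQual,
                                 altAllele = alt)
    tumorDnaSum <- summarizeColumn(roleObservations(column, "tumorDNA"), ref,
                                   minBaseQual = params$minBaseQual,
                                   minMapQual = params$minMapQual,
                                   altAllele = alt)

    failed <- c(applyThresholds(normalSum, profiles$tbmNormal, "tbmNormal")$failedFilters,
                applyThresholds(tumorDnaSum, profiles$tbmTumorDna,
                                "tbmTumorDna")$failedFilters,
                applyThresholds(rnaCand, profiles$tbmTumorRna,
                                "tbmTumorRna")$failedFilters,
                regionVerdict(regions,
                              c("dbsnpCommon", "dbsnpRetired", "blacklist",
                                "pseudogene", "geneFamily"), chrom, pos))

    rnaObs <- roleObservations(column, "tumorRNA")
    altObs <- rnaObs[rnaObs$base == alt &
                     rnaObs$baseQual >= params$minBaseQual &
                     rnaObs$mapQual >= params$minMapQual, , drop = FALSE]
    failed <- c(failed,
                positionalBiasFilter(altObs, posBiasThreshold)$failedFilters)
    if (!is.null(remapAligner))
        failed <- c(failed,
                    remapCheck(altObs, remapLocus, remapAligner,
                               totalDepth = rnaCand@depth)$failedFilters)

    call <- VariantCall(chrom, pos, ref, alt, category = "somatic",
                        origin = "TBM",
                        summaries = list(normalDNA = normalSum,
                                         tumorDNA = tumorDnaSum,
                                         tumorRNA = rnaCand),
                        failedFilters = failed)
    if (length(failed) && !keepFailed) return(NULL)
    call
}
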