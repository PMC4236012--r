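#' A set of per-sample support thresholds
#'
#' One column of the support-filter tables: any field left \code{NULL} is not
#' enforced. \code{min*} thresholds pass on \code{>=}, \code{max*} thresholds
#' pass on \code{<=}. The strand check compares
#' \code{max(altForwardFraction, 1 - altForwardFraction)} against
#' \code{maxAltStrandFraction} and — as in the standalone strand-bias filter —
#' is only armed when at least \code{strandBiasMinAlt} reads support the
#' variant.
#'
#' @param minTotalDepth,minAltDepth integer floors.
#' @param minAltFraction,minAvgAltBaseQual floors on the alt fraction and the
#'   mean alt base quality (phred).
#' @param maxAltStrandFraction ceiling on the majority-strand fraction of
#'   alt reads.
#' @param maxAltFraction,maxOtherFraction ceilings on the alt fraction
#'   (used for the normal sample in somatic tests) and on third-allele
#'   support.
#' @param strandBiasMinAlt alt-read count below which the strand check is
#'   skipped.
#' @return A named list of class \code{ThresholdSet}.
#' @export
thresholdSet <- function(minTotalDepth = NULL, minAltDepth = NULL,
                         minAltFraction = NULL, minAvgAltBaseQual = NULL,
                         maxAltStrandFraction = NULL, maxAltFraction = NULL,
                         maxOtherFraction = NULL, strandBiasMinAlt = 4L) {
    fr <- c(minAltFraction, maxAltStrandFraction, maxAltFraction,
            maxOtherFraction)
    stopifnot(all(fr >= 0 & fr <= 1))
    structure(list(minTotalDepth = minTotalDepth, minAltDepth = minAltDepth,
                   minAltFraction = minAltFraction,
                   minAvgAltBaseQual = minAvgAltBaseQual,
                   maxAltStrandFraction = maxAltStrandFraction,
                   maxAltFraction = maxAltFraction,
                   maxOtherFraction = maxOtherFraction,
                   strandBiasMinAlt = as.integer(strandBiasMinAlt)),
              class = "ThresholdSet")
}

verdict <- function(failed = character(0)) {
    list(passed = length(failed) == 0L, failedFilters = failed)
}

#' Check an allele summary against a threshold set
#'
#' Each present threshold is checked in a fixed order; every violated
#' threshold is named in the verdict as \code{"<prefix>.<field>"}.
#'
#' @param summary an \code{\link{AlleleSummary-class}}.
#' @param t a \code{\link{thresholdSet}}.
#' @param prefix name prefix identifying which sample/profile failed.
#' @return A verdict list: \code{passed} (logical) and \code{failedFilters}
#'   (ordered character vector, empty iff passed).
#' @examples
#' s <- summarizeColumn(readObservations(base = c(rep("A", 6), rep("T", 4)),
#'                                       baseQual = 30, mapQual = 40,
#'                                       strand = rep(c("+", "-"), 5)), "A")
#' applyThresholds(s, thresholdSet(minTotalDepth = 10, minAltDepth = 4))
#' @export
applyThresholds <- function(summary, t, prefix = "support") {
    failed <- character(0)
    fail <- function(nm) failed <<- c(failed, paste0(prefix, ".", nm))

    if (!is.null(t$minTotalDepth) && summary@depth < t$minTotalDepth)
        fail("minTotalDepth")
    if (!is.null(t$minAltDepth) && summary@altDepth < t$minAltDepth)
        fail("minAltDepth")
    if (!is.null(t$minAltFraction) && summary@altFraction < t$minAltFraction)
        fail("minAltFraction")
    if (!is.null(t$minAvgAltBaseQual)) {
        baq <- summary@avgAltBaseQuality
        if (is.na(baq) || baq < t$minAvgAltBaseQual)
            fail("minAvgAltBaseQual")
    }
    if (!is.null(t$maxAltStrandFraction) &&
        summary@altDepth >= t$strandBiasMinAlt) {
        f <- summary@altForwardFraction
        if (!is.na(f) && max(f, 1 - f) > t$maxAltStrandFraction)
            fail("maxAltStrandFraction")
    }
    if (!is.null(t$maxAltFraction) && summary@altFraction > t$maxAltFraction)
        fail("maxAltFraction")
    if (!is.null(t$maxOtherFraction) &&
        summary@otherFraction > t$maxOtherFraction)
        fail("maxOtherFraction")
    verdict(failed)
}

#' Strand-bias filter
#'
#' Variant reads occurring (almost) exclusively on one strand are a known
#' false-positive signature. With at least \code{minAltForBias} reads
#' supporting the variant, the site fails when more than
#' \code{maxFraction} of those reads lie on the forward strand or more than
#' \code{maxFraction} lie on the reverse strand. Below the read-count guard
#' the filter is not applied. Exactly 90\% on one strand passes; only a
#' strictly greater majority fails.
#'
#' @param summary an \code{\link{AlleleSummary-class}}.
#' @param minAltForBias alt-read count required before the filter is armed.
#' @param maxFraction majority-strand ceiling.
#' @return A verdict list (failure named \code{"strandBias"}).
#' @export
strandBiasFilter <- function(summary, minAltForBias = 4L,
                             maxFraction = 0.90) {
    if (summary@altDepth >= minAltForBias) {
        f <- summary@altForwardFraction
        if (!is.na(f) && max(f, 1 - f) > maxFraction)
            return(verdict("strandBias"))
    }
    verdict()
}

#' Positional-bias filter
#'
#' Misaligned reads tend to place the alternative allele consistently near
#' one end of the read. Over the alt-supporting observations, the filter
#' computes the fraction whose relative offset \code{offsetInRead/readLength}
#' falls in the first third (< 1/3) and the fraction in the last third
#' (>= 2/3); the site fails when either fraction reaches \code{threshold}
#' (95\% or more by default). No alt observations passes trivially.
#'
#' @param altObs observation rows supporting the alternative allele only.
#' @param threshold failing fraction (inclusive).
#' @return A verdict list (failure named \code{"positionalBias"}).
#' @export
positionalBiasFilter <- function(altObs, threshold = 0.95) {
    n <- nrow(altObs)
    if (n == 0L) return(verdict())
    rel <- altObs$offsetInRead / altObs$readLength
    if (mean(rel < 1 / 3) >= threshold || mean(rel >= 2 / 3) >= threshold)
        return(verdict("positionalBias"))
    verdict()
}

#' Build a best-placement aligner over a set of candidate regions
#'
#' Returns a function mapping a read sequence to its best local-alignment
#' score against every sequence of a candidate-region FASTA (the call-locus
#' neighborhood plus any suspected homologs/paralogs). Used as the default
#' engine of \code{\link{remapCheck}}; any function with the same contract
#' (read sequence in, named score vector out) can replace it, e.g. an adapter
#' around an external whole-genome aligner.
#'
#' @param regions path to a FASTA file or a named
#'   \code{Biostrings::DNAStringSet} of candidate regions.
#' @param match,mismatch,gapOpening,gapExtension local-alignment scoring.
#' @return A function \code{(readSeq) -> named numeric scores}.
#' @export
pairwiseRemapAligner <- function(regions, match = 1, mismatch = -2,
                                 gapOpening = 5, gapExtension = 2) {
    seqs <- if (is(regions, "DNAStringSet")) regions else
        Biostrings::readDNAStringSet(regions)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    function(readSeq) {
        scores <- Biostrings::pairwiseAlignment(
            rep(Biostrings::DNAStringSet(readSeq), length(seqs)), seqs,
            type = "local", substitutionMatrix = mat,
            gapOpening = gapOpening, gapExtension = gapExtension,
            scoreOnly = TRUE)
        setNames(scores, names(seqs))
    }
}

#' Re-mapping check on variant-supporting reads
#'
#' RNA-seq reads supporting a variant are re-aligned genome- (or
#' region-)wide; a read whose best placement scores strictly higher somewhere
#' other than the call locus is rejected. After rejection the site must still
#' hold at least \code{minValidReads} surviving variant reads making up at
#' least \code{minFraction} of the total depth.
#'
#' @param altObs observation rows supporting the variant, with
#'   \code{readSeq} populated; rows with a missing sequence count as rejected
#'   (with a warning).
#' @param locus name of the candidate-region sequence containing the call
#'   locus (the "home" region).
#' @param aligner a best-placement function as returned by
#'   \code{\link{pairwiseRemapAligner}}.
#' @param minValidReads,minFraction post-rejection support requirements.
#' @param totalDepth total filtered depth at the site (denominator of the
#'   fraction requirement).
#' @return A verdict list (failure named \code{"remap"}).
#' @export
remapCheck <- function(altObs, locus, aligner, minValidReads = 4L,
                       minFraction = 0.10, totalDepth) {
    survivors <- 0L
    for (i in seq_len(nrow(altObs))) {
        rs <- altObs$readSeq[i]
        if (is.na(rs) || rs == "" || rs == ".") {
            warning("read ", altObs$readId[i],
                    " has no sequence; counted as rejected by remap check")
            next
        }
        scores <- aligner(rs)
        if (!locus %in% names(scores))
            stop("locus region '", locus, "' absent from aligner reference")
        if (scores[[locus]] >= max(scores))   # no strictly better elsewhere
            survivors <- survivors + 1L
    }
    if (survivors < minValidReads || survivors / totalDepth < minFraction)
        return(verdict("remap"))
    verdict()
}
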