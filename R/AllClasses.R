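#' @import methods
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")
SAMPLE_ROLES <- c("normalDNA", "tumorDNA", "tumorRNA")

OBS_COLUMNS <- c("readId", "base", "baseQual", "mapQual", "strand",
                 "offsetInRead", "readLength", "properlyPaired",
                 "mismatchCount", "hasIndel", "flankQuals", "readSeq",
                 "sampleRole")

#' Construct a read-observation table
#'
#' One row per aligned base observed at a single genomic position. This is the
#' atomic unit every downstream summary and filter consumes: the base itself,
#' its phred base quality (assumed already alignment-adjusted upstream), the
#' read's mapping quality, strand, 0-based offset of the base within the read,
#' read length, proper-pairing flag, the read's total mismatch count against
#' the reference, whether the alignment required an insertion or deletion, the
#' phred qualities of up to five flanking bases on each side (comma-joined;
#' fewer near read ends), the full read sequence (optional, needed only by the
#' remap check) and the sample role the read came from.
#'
#' @param readId character vector of read identifiers.
#' @param base observed base, one of A, C, G, T, N.
#' @param baseQual,mapQual non-negative phred integers.
#' @param strand \code{"+"} or \code{"-"}.
#' @param offsetInRead 0-based offset of the observed base within the read.
#' @param readLength read length in bases.
#' @param properlyPaired logical.
#' @param mismatchCount non-negative integer, mismatches of the whole read.
#' @param hasIndel logical; alignment contains an insertion or deletion.
#' @param flankQuals comma-joined phred integers for up to 10 flanking bases
#'   (5 upstream, 5 downstream); \code{""} when unavailable.
#' @param readSeq full read sequence or \code{NA}.
#' @param sampleRole one of \code{"normalDNA"}, \code{"tumorDNA"},
#'   \code{"tumorRNA"}.
#' @return A \code{data.frame} with one row per observation.
#' @examples
#' readObservations(base = c("A", "T"), baseQual = 30, mapQual = 40,
#'                  strand = c("+", "-"), sampleRole = "tumorDNA")
#' @export
readObservations <- function(readId = NULL, base, baseQual, mapQual,
                             strand = "+", offsetInRead = 50L,
                             readLength = 100L, properlyPaired = TRUE,
                             mismatchCount = 0L, hasIndel = FALSE,
                             flankQuals = "", readSeq = NA_character_,
                             sampleRole = "tumorDNA") {
    n <- if (length(base) == 0L) 0L else
        max(length(base), length(baseQual), length(mapQual),
            length(strand), length(offsetInRead), length(readLength),
            length(properlyPaired), length(mismatchCount),
            length(hasIndel), length(flankQuals), length(readSeq),
            length(sampleRole),
            if (is.null(readId)) 0L else length(readId))
    if (is.null(readId))
        readId <- sprintf("read%04d", seq_len(n))
    obs <- data.frame(
        readId        = rep_len(as.character(readId), n),
        base          = rep_len(toupper(as.character(base)), n),
        baseQual      = rep_len(as.integer(baseQual), n),
        mapQual       = rep_len(as.integer(mapQual), n),
        strand        = rep_len(as.character(strand), n),
        offsetInRead  = rep_len(as.integer(offsetInRead), n),
        readLength    = rep_len(as.integer(readLength), n),
        properlyPaired = rep_len(as.logical(properlyPaired), n),
        mismatchCount = rep_len(as.integer(mismatchCount), n),
        hasIndel      = rep_len(as.logical(hasIndel), n),
        flankQuals    = rep_len(as.character(flankQuals), n),
        readSeq       = rep_len(as.character(readSeq), n),
        sampleRole    = rep_len(as.character(sampleRole), n),
        stringsAsFactors = FALSE
    )
    validateObservations(obs)
    obs
}

validateObservations <- function(obs) {
    if (nrow(obs) == 0L)
        return(invisible(TRUE))
    bad <- which(!(obs$base %in% VALID_BASES))
    if (length(bad))
        stop("invalid base '", obs$base[bad[1]], "' in observation row ",
             bad[1])
    bad <- which(!(obs$sampleRole %in% SAMPLE_ROLES))
    if (length(bad))
        stop("invalid sampleRole '", obs$sampleRole[bad[1]],
             "' in observation row ", bad[1])
    bad <- which(!(obs$strand %in% c("+", "-")))
    if (length(bad))
        stop("invalid strand in observation row ", bad[1])
    bad <- which(obs$offsetInRead < 0L | obs$offsetInRead >= obs$readLength)
    if (length(bad))
        stop("offsetInRead out of [0, readLength) in observation row ", bad[1])
    bad <- which(obs$baseQual < 0L | obs$mapQual < 0L | obs$mismatchCount < 0L)
    if (length(bad))
        stop("negative quality or mismatch count in observation row ", bad[1])
    invisible(TRUE)
}

#' Pileup column: all read observations at one genomic position
#'
#' Holds the reference base and the observation table for up to three sample
#' roles (normal DNA, tumor DNA, tumor RNA) at one 0-based position.
#'
#' @slot chrom chromosome name.
#' @slot pos 0-based position.
#' @slot refBase upper-case reference base.
#' @slot observations a \code{data.frame} as built by
#'   \code{\link{readObservations}}, the \code{sampleRole} column keying the
#'   roles.
#' @export
setClass("PileupColumn",
    representation(chrom = "character", pos = "integer",
                   refBase = "character", observations = "data.frame"),
    validity = function(object) {
        if (length(object@chrom) != 1L || length(object@pos) != 1L)
            return("chrom and pos must be length 1")
        if (object@pos < 0L)
            return("pos must be >= 0 (0-based)")
        if (!(object@refBase %in% VALID_BASES))
            return(paste0("refBase must be one of ",
                          paste(VALID_BASES, collapse = ",")))
        if (object@refBase != toupper(object@refBase))
            return("refBase must be upper case")
        ok <- tryCatch({validateObservations(object@observations); TRUE},
                       error = function(e) conditionMessage(e))
        if (!isTRUE(ok)) return(ok)
        TRUE
    })

#' Construct a PileupColumn
#'
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @param refBase reference base (upper-cased).
#' @param observations observation \code{data.frame}; see
#'   \code{\link{readObservations}}.
#' @return A \code{\link{PileupColumn-class}} object.
#' @examples
#' obs <- readObservations(base = "A", baseQual = 30, mapQual = 40,
#'                         sampleRole = "normalDNA")
#' PileupColumn("chr1", 100L, "A", obs)
#' @export
PileupColumn <- function(chrom, pos, refBase, observations) {
    new("PileupColumn", chrom = as.character(chrom), pos = as.integer(pos),
        refBase = toupper(as.character(refBase)), observations = observations)
}

#' @describeIn PileupColumn observations for one sample role (or all).
#' @param x,object a \code{PileupColumn}.
#' @param role a sample role or \code{NULL} for the full table.
#' @export
roleObservations <- function(x, role = NULL) {
    stopifnot(is(x, "PileupColumn"))
    if (is.null(role))
        return(x@observations)
    if (!role %in% SAMPLE_ROLES)
        stop("unknown sample role: ", role)
    x@observations[x@observations$sampleRole == role, , drop = FALSE]
}

#' @describeIn PileupColumn chromosome accessor.
#' @export
columnChrom <- function(x) x@chrom

#' @describeIn PileupColumn 0-based position accessor.
#' @export
columnPos <- function(x) x@pos

#' @describeIn PileupColumn reference-base accessor.
#' @export
columnRef <- function(x) x@refBase

setMethod("show", "PileupColumn", function(object) {
    tab <- table(factor(object@observations$sampleRole, levels = SAMPLE_ROLES))
    cat("PileupColumn ", object@chrom, ":", object@pos, " ref=",
        object@refBase, " (", paste(names(tab), tab, sep = "=",
        collapse = ", "), ")\n", sep = "")
})

#' Per-sample allele summary at a pileup column
#'
#' Aggregates the observations of one sample role after base/mapping-quality
#' filtering: total depth, the chosen alternative allele and its depth and
#' fraction, average alt base quality, average mapping quality over all
#' retained reads, fraction of alt-supporting reads on the forward strand and
#' the fraction of reads supporting any base other than the reference and the
#' chosen alt.
#'
#' @slot depth filtered read depth (N bases excluded).
#' @slot altAllele chosen alternative allele, \code{NA} when none.
#' @slot altDepth reads supporting the alt allele.
#' @slot altFraction \code{altDepth/depth} (0 when depth is 0).
#' @slot avgAltBaseQuality mean phred base quality of alt reads.
#' @slot avgMapQuality mean phred mapping quality of retained reads.
#' @slot altForwardFraction fraction of alt reads on the forward strand
#'   (\code{NA} when altDepth is 0).
#' @slot otherFraction fraction of retained reads supporting a third allele.
#' @export
setClass("AlleleSummary",
    representation(depth = "integer", altAllele = "character",
                   altDepth = "integer", altFraction = "numeric",
                   avgAltBaseQuality = "numeric", avgMapQuality = "numeric",
                   altForwardFraction = "numeric", otherFraction = "numeric"),
    validity = function(object) {
        if (object@altDepth > object@depth)
            return("altDepth cannot exceed depth")
        if (object@depth > 0 &&
            abs(object@altFraction - object@altDepth / object@depth) > 1e-9)
            return("altFraction inconsistent with altDepth/depth")
        frac <- c(object@altFraction, object@otherFraction)
        if (any(frac < -1e-9 | frac > 1 + 1e-9))
            return("fractions must lie in [0,1]")
        TRUE
    })

AlleleSummary <- function(depth, altAllele, altDepth, altFraction,
                          avgAltBaseQuality, avgMapQuality,
                          altForwardFraction, otherFraction) {
    new("AlleleSummary", depth = as.integer(depth),
        altAllele = as.character(altAllele), altDepth = as.integer(altDepth),
        altFraction = as.numeric(altFraction),
        avgAltBaseQuality = as.numeric(avgAltBaseQuality),
        avgMapQuality = as.numeric(avgMapQuality),
        altForwardFraction = as.numeric(altForwardFraction),
        otherFraction = as.numeric(otherFraction))
}

#' @describeIn AlleleSummary filtered depth.
#' @param x,object an \code{AlleleSummary}.
#' @export
summaryDepth <- function(x) x@depth

#' @describeIn AlleleSummary chosen alternative allele (\code{NA} if none).
#' @export
altAllele <- function(x) x@altAllele

#' @describeIn AlleleSummary alt-supporting read count.
#' @export
altDepth <- function(x) x@altDepth

#' @describeIn AlleleSummary alt allele fraction.
#' @export
altFraction <- function(x) x@altFraction

setMethod("show", "AlleleSummary", function(object) {
    cat(sprintf(
        "AlleleSummary depth=%d alt=%s altDepth=%d altFrac=%.3f baq=%.1f mq=%.1f fwd=%s other=%.3f\n",
        object@depth, ifelse(is.na(object@altAllele), ".", object@altAllele),
        object@altDepth, object@altFraction,
        object@avgAltBaseQuality, object@avgMapQuality,
        ifelse(is.na(object@altForwardFraction), ".",
               sprintf("%.2f", object@altForwardFraction)),
        object@otherFraction))
})

#' A somatic or germline variant call
#'
#' Carries the site, alleles, call category (germline/somatic), the method of
#' origin (DOM = DNA-only method, TBM = triple-sample method, or both), the
#' post-merge label (RNA_Confirmation / RNA_Rescue / DNA_only), the per-role
#' allele summaries and the ordered list of failed filter names (empty when
#' the call passes).
#'
#' @slot chrom chromosome.
#' @slot pos 0-based position (VCF output is 1-based).
#' @slot ref,alt reference and alternative alleles.
#' @slot category \code{"germline"} or \code{"somatic"}.
#' @slot origin \code{"DOM"}, \code{"TBM"} or \code{"both"}.
#' @slot label \code{"RNA_Confirmation"}, \code{"RNA_Rescue"},
#'   \code{"DNA_only"} or \code{"none"} (pre-merge / germline).
#' @slot summaries named list of \code{AlleleSummary} per sample role.
#' @slot failedFilters ordered character vector of failed filter names.
#' @export
setClass("VariantCall",
    representation(chrom = "character", pos = "integer", ref = "character",
                   alt = "character", category = "character",
                   origin = "character", label = "character",
                   summaries = "list", failedFilters = "character"),
    validity = function(object) {
        if (!(object@category %in% c("germline", "somatic")))
            return("category must be germline or somatic")
        if (!(object@origin %in% c("DOM", "TBM", "both")))
            return("origin must be DOM, TBM or both")
        if (!(object@label %in% c("RNA_Confirmation", "RNA_Rescue",
                                  "DNA_only", "none")))
            return("invalid label")
        if (object@origin == "both" && object@label != "RNA_Confirmation")
            return("origin 'both' implies label RNA_Confirmation")
        TRUE
    })

VariantCall <- function(chrom, pos, ref, alt, category, origin,
                        label = "none", summaries = list(),
                        failedFilters = character(0)) {
    new("VariantCall", chrom = as.character(chrom), pos = as.integer(pos),
        ref = ref, alt = alt, category = category, origin = origin,
        label = label, summaries = summaries,
        failedFilters = as.character(failedFilters))
}

#' @describeIn VariantCall \code{TRUE} when no filter failed.
#' @param x,object a \code{VariantCall}.
#' @export
callPassed <- function(x) length(x@failedFilters) == 0L

#' @describeIn VariantCall the VCF FILTER field: \code{"PASS"} or the failed
#'   filter names joined with \code{";"}.
#' @export
filterField <- function(x) {
    if (callPassed(x)) "PASS" else paste(x@failedFilters, collapse = ";")
}

#' @describeIn VariantCall post-merge label accessor.
#' @export
callLabel <- function(x) x@label

#' @describeIn VariantCall call category accessor.
#' @export
callCategory <- function(x) x@category

#' @describeIn VariantCall method-of-origin accessor.
#' @export
callOrigin <- function(x) x@origin

#' @describeIn VariantCall per-role \code{AlleleSummary} list.
#' @export
callSummaries <- function(x) x@summaries

setMethod("show", "VariantCall", function(object) {
    cat(sprintf("VariantCall %s:%d %s>%s %s/%s label=%s filter=%s\n",
                object@chrom, object@pos, object@ref, object@alt,
                object@category, object@origin, object@label,
                filterField(object)))
})
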