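#' Lenient candidate-detection parameters
#'
#' The initial variant scan is deliberately permissive: a minimum overall
#' depth of four bases, a minimum variant depth of two bases, and phred
#' floors of 10 on both base quality and mapping quality. These defaults give
#' a broad baseline set of candidates for the downstream filter chains to
#' prune.
#'
#' @param minTotalDepth minimum filtered depth at the site.
#' @param minVariantDepth minimum reads supporting the alternative allele.
#' @param minBaseQual,minMapQual phred floors applied before counting.
#' @return A named list of class \code{DetectionParams}.
#' @export
detectionParams <- function(minTotalDepth = 4L, minVariantDepth = 2L,
                            minBaseQual = 10L, minMapQual = 10L) {
    stopifnot(minTotalDepth >= 0L, minVariantDepth >= 0L,
              minVariantDepth <= minTotalDepth,
              minBaseQual >= 0L, minMapQual >= 0L)
    structure(list(minTotalDepth = as.integer(minTotalDepth),
                   minVariantDepth = as.integer(minVariantDepth),
                   minBaseQual = as.integer(minBaseQual),
                   minMapQual = as.integer(minMapQual)),
              class = "DetectionParams")
}

#' Detect a candidate variant in one sample at a column
#'
#' Summarizes the given role's observations under the detection quality
#' floors and reports the \code{\link{AlleleSummary-class}} when the filtered
#' depth reaches \code{minTotalDepth} and the alternative-allele depth
#' reaches \code{minVariantDepth}; otherwise \code{NULL}. Candidates are
#' detected independently per role; the DNA-only method consumes the
#' normal/tumor DNA candidates while the triple-sample method consumes all
#' three.
#'
#' @param column a \code{\link{PileupColumn-class}}.
#' @param role sample role to examine.
#' @param params a \code{\link{detectionParams}} list.
#' @param altAllele optionally force the tested alternative allele.
#' @return An \code{AlleleSummary} or \code{NULL}.
#' @export
detectCandidate <- function(column, role, params = detectionParams(),
                            altAllele = NULL) {
    obs <- roleObservations(column, role)
    s <- summarizeColumn(obs, columnRef(column),
                         minBaseQual = params$minBaseQual,
                         minMapQual = params$minMapQual,
                         altAllele = altAllele)
    if (s@depth >= params$minTotalDepth &&
        s@altDepth >= params$minVariantDepth)
        s
    else
        NULL
}
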