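VALIDATION_STATUSES <- c("SomaticLow", "SomaticMed", "SomaticHigh",
                         "GermlineLOH", "NotValidated", "Ambiguous")

#' Classify a call against deep-resequencing validation data
#'
#' Implements the validation grid used for the endometrial recapture data.
#' At least \code{minDepth} reads are required in both the tumor and normal
#' validation data, otherwise the call is Ambiguous. With adequate depth:
#' normal VAF >= 3\% is Germline/LOH regardless of the tumor; normal VAF
#' exactly 0 with tumor VAF 0 is Not Validated, otherwise Somatic Low
#' (< 8\%), Med (>= 8\%, < 20\%) or High (>= 20\%); normal VAF strictly
#' between 0 and 3\% is Not Validated at tumor VAF 0, Ambiguous below 8\%
#' (variant present at low levels in both), Somatic Med below 20\% and
#' Somatic High at or above 20\%.
#'
#' @param normalVaf,tumorVaf validation VAFs in [0, 1]; a normal VAF of
#'   exactly 0 means zero alt reads.
#' @param normalDepth,tumorDepth validation read depths.
#' @param minDepth depth below which the call is Ambiguous.
#' @return One of \code{"SomaticLow"}, \code{"SomaticMed"},
#'   \code{"SomaticHigh"}, \code{"GermlineLOH"}, \code{"NotValidated"},
#'   \code{"Ambiguous"} (vectorized).
#' @export
classifyValidation <- function(normalVaf, tumorVaf, normalDepth, tumorDepth,
                               minDepth = 10L) {
    n <- max(length(normalVaf), length(tumorVaf), length(normalDepth),
             length(tumorDepth))
    normalVaf <- rep_len(normalVaf, n); tumorVaf <- rep_len(tumorVaf, n)
    normalDepth <- rep_len(normalDepth, n)
    tumorDepth <- rep_len(tumorDepth, n)
    vapply(seq_len(n), function(i) {
        if (normalDepth[i] < minDepth || tumorDepth[i] < minDepth)
            return("Ambiguous")
        nv <- normalVaf[i]; tv <- tumorVaf[i]
        if (nv >= 0.03) return("GermlineLOH")
        if (nv == 0) {
            if (tv == 0) return("NotValidated")
            if (tv < 0.08) return("SomaticLow")
            if (tv < 0.20) return("SomaticMed")
            return("SomaticHigh")
        }
        # 0 < nv < 3%
        if (tv == 0) return("NotValidated")
        if (tv < 0.08) return("Ambiguous")
        if (tv < 0.20) return("SomaticMed")
        "SomaticHigh"
    }, character(1))
}

#' Database rescue of unvalidated RNA-rescued calls
#'
#' An RNA-rescued call that failed resequencing validation but sits at a
#' position catalogued as a confirmed somatic mutation (a COSMIC-style
#' position list) is considered validated (as Somatic Low, the
#' validated-by-database grade). All other statuses and labels pass through
#' unchanged.
#'
#' @param status a validation status from \code{\link{classifyValidation}}.
#' @param call the \code{\link{VariantCall-class}} the status belongs to.
#' @param cosmic a position-mode \code{\link{RegionSet-class}} of confirmed
#'   somatic sites.
#' @return The (possibly upgraded) status.
#' @export
cosmicRescue <- function(status, call, cosmic) {
    if (status == "NotValidated" && callLabel(call) == "RNA_Rescue" &&
        containsPos(cosmic, call@chrom, call@pos))
        return("SomaticLow")
    status
}

#' Precision accounting per call group
#'
#' For the whole call set and for the DOM, TBM, RNA-confirmation and
#' RNA-rescue subsets, tabulates validated (Somatic Low/Med/High),
#' not-validated, germline/LOH and ambiguous counts, and the precision
#' \code{validated / (validated + notValidated + germline)}. Ambiguous calls
#' are excluded from the denominator; a group with an empty denominator
#' reports \code{NA} precision.
#'
#' @param status character vector of validation statuses.
#' @param origin character vector of call origins (\code{DOM}, \code{TBM},
#'   \code{both}).
#' @param label character vector of merge labels.
#' @return A \code{data.frame}, one row per group.
#' @export
precisionReport <- function(status, origin, label) {
    stopifnot(length(status) == length(origin),
              length(status) == length(label))
    groups <- list(
        all = rep(TRUE, length(status)),
        DOM = origin %in% c("DOM", "both"),
        TBM = origin %in% c("TBM", "both"),
        RNA_Confirmation = label == "RNA_Confirmation",
        RNA_Rescue = label == "RNA_Rescue")
    rows <- lapply(names(groups), function(g) {
        s <- status[groups[[g]]]
        validated <- sum(s %in% c("SomaticLow", "SomaticMed", "SomaticHigh"))
        notValidated <- sum(s == "NotValidated")
        germline <- sum(s == "GermlineLOH")
        ambiguous <- sum(s == "Ambiguous")
        denom <- validated + notValidated + germline
        data.frame(group = g, n = length(s), validated = validated,
                   notValidated = notValidated, germline = germline,
                   ambiguous = ambiguous,
                   precision = if (denom > 0) validated / denom else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Validate a call set against a validation-observation table
#'
#' @param calls list of labeled \code{\link{VariantCall-class}} objects.
#' @param validation \code{data.frame} with columns \code{chrom},
#'   \code{pos1} (1-based), \code{normalDepth}, \code{normalAlt},
#'   \code{tumorDepth}, \code{tumorAlt}. Calls without a matching row are
#'   Ambiguous (no validation coverage).
#' @param cosmic optional position-mode \code{\link{RegionSet-class}} for
#'   the database-rescue rule.
#' @param minDepth depth floor of \code{\link{classifyValidation}}.
#' @return A \code{data.frame} with one row per call: site, alleles, label,
#'   origin and validation status; plus the precision table as attribute
#'   \code{"precision"}.
#' @export
runValidate <- function(calls, validation, cosmic = NULL, minDepth = 10L) {
    key <- paste(normChrom(validation$chrom), validation$pos1)
    rows <- lapply(calls, function(x) {
        i <- match(paste(normChrom(x@chrom), x@pos + 1L), key)
        if (is.na(i)) {
            status <- "Ambiguous"
        } else {
            nd <- validation$normalDepth[i]; td <- validation$tumorDepth[i]
            nv <- if (nd > 0) validation$normalAlt[i] / nd else 0
            tv <- if (td > 0) validation$tumorAlt[i] / td else 0
            status <- classifyValidation(nv, tv, nd, td, minDepth)
            if (!is.null(cosmic))
                status <- cosmicRescue(status, x, cosmic)
        }
        data.frame(chrom = x@chrom, pos1 = x@pos + 1L, ref = x@ref,
                   alt = x@alt, origin = x@origin, label = x@label,
                   status = status, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(chrom = character(0), pos1 = integer(0),
                          ref = character(0), alt = character(0),
                          origin = character(0), label = character(0),
                          status = character(0), stringsAsFactors = FALSE)
    attr(out, "precision") <- precisionReport(out$status, out$origin,
                                              out$label)
    out
}
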