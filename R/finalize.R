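#' Parameters of the perfect-read support filter
#'
#' The final filter on merged somatic calls. A "perfect" read has mapping
#' quality >= 10, base quality of the observed allele >= 10, every flanking
#' base quality (five up- and five down-stream) >= 10, is properly paired,
#' carries fewer than four mismatches against the reference over its whole
#' length, and needs no insertion or deletion to be mapped. Each somatic
#' mutation must be supported by at least four perfect reads, and no more
#' than 90\% of the total perfect reads (reference plus alternative) at the
#' site may come from one strand.
#'
#' @param minMapQual,minAltBaseQual,minFlankQual phred floors.
#' @param maxMismatches exclusive mismatch ceiling (fewer than 4 passes).
#' @param requireProperPair,forbidIndelAlignment logical criteria.
#' @param minPerfectSupport required perfect alt-supporting reads.
#' @param maxStrandFraction majority-strand ceiling over all perfect reads.
#' @return A named list of class \code{PerfectReadParams}.
#' @export
perfectReadParams <- function(minMapQual = 10L, minAltBaseQual = 10L,
                              minFlankQual = 10L, maxMismatches = 4L,
                              requireProperPair = TRUE,
                              forbidIndelAlignment = TRUE,
                              minPerfectSupport = 4L,
                              maxStrandFraction = 0.90) {
    stopifnot(minMapQual >= 0L, minAltBaseQual >= 0L, minFlankQual >= 0L,
              maxMismatches >= 0L, minPerfectSupport >= 0L,
              maxStrandFraction >= 0, maxStrandFraction <= 1)
    structure(list(minMapQual = as.integer(minMapQual),
                   minAltBaseQual = as.integer(minAltBaseQual),
                   minFlankQual = as.integer(minFlankQual),
                   maxMismatches = as.integer(maxMismatches),
                   requireProperPair = requireProperPair,
                   forbidIndelAlignment = forbidIndelAlignment,
                   minPerfectSupport = as.integer(minPerfectSupport),
                   maxStrandFraction = maxStrandFraction),
              class = "PerfectReadParams")
}

#' Is an observation a "perfect" read?
#'
#' Vectorized over the rows of an observation table; see
#' \code{\link{perfectReadParams}} for the six criteria.
#'
#' @param obs observation \code{data.frame} rows.
#' @param p a \code{\link{perfectReadParams}} list.
#' @return Logical vector, one element per row.
#' @export
isPerfectRead <- function(obs, p = perfectReadParams()) {
    if (nrow(obs) == 0L) return(logical(0))
    flankOk <- vapply(strsplit(obs$flankQuals, ","), function(fq) {
        fq <- suppressWarnings(as.integer(fq[fq != ""]))
        length(fq) == 0L || all(fq >= p$minFlankQual)
    }, logical(1))
    ok <- obs$mapQual >= p$minMapQual &
        obs$baseQual >= p$minAltBaseQual &
        flankOk &
        obs$mismatchCount < p$maxMismatches
    if (p$requireProperPair) ok <- ok & obs$properlyPaired
    if (p$forbidIndelAlignment) ok <- ok & !obs$hasIndel
    ok
}

perfectSupportInRole <- function(column, role, ref, alt, p) {
    obs <- roleObservations(column, role)
    perfect <- isPerfectRead(obs, p)
    failed <- character(0)
    nAltPerfect <- sum(perfect & obs$base == alt)
    if (nAltPerfect < p$minPerfectSupport)
        failed <- c(failed, "minPerfectSupport")
    totalMask <- perfect & obs$base %in% c(ref, alt)
    if (sum(totalMask) > 0L) {
        f <- mean(obs$strand[totalMask] == "+")
        if (max(f, 1 - f) > p$maxStrandFraction)
            failed <- c(failed, "perfectStrandBias")
    }
    verdict(failed)
}

#' Perfect-read support filter on a merged call
#'
#' Counts perfect alt-supporting reads in the call's evidence role — tumor
#' DNA for DNA-only calls, tumor RNA for RNA-rescued calls — and fails the
#' call when fewer than four are found; it then re-checks strand balance over
#' all perfect reads (reference plus alternative) in that role. Calls made
#' by both methods (RNA confirmation) pass when either evidence role passes.
#'
#' @param call a merged somatic \code{\link{VariantCall-class}}.
#' @param column the \code{\link{PileupColumn-class}} at the call site.
#' @param p a \code{\link{perfectReadParams}} list.
#' @return A verdict list; failures are \code{"minPerfectSupport"} and/or
#'   \code{"perfectStrandBias"}.
#' @export
readSupportFilter <- function(call, column, p = perfectReadParams()) {
    ref <- call@ref; alt <- call@alt
    roles <- switch(call@label,
                    DNA_only = "tumorDNA",
                    RNA_Rescue = "tumorRNA",
                    RNA_Confirmation = c("tumorDNA", "tumorRNA"),
                    "tumorDNA")
    first <- NULL
    for (role in roles) {
        v <- perfectSupportInRole(column, role, ref, alt, p)
        if (v$passed) return(v)
        if (is.null(first)) first <- v
    }
    first
}

#' Merge the calls of the two methods
#'
#' Passing somatic calls sharing site and alternative allele are merged into
#' a single call of origin \code{"both"}, labeled RNA confirmation; calls
#' unique to the triple-sample method become RNA rescues; calls unique to
#' the DNA-only method are labeled DNA-only. Calls at one site with
#' different alternative alleles are both kept (a conflict message is
#' emitted). The output is sorted by chromosome, position and allele, one
#' record per site/allele.
#'
#' @param domCalls,tbmCalls lists of passing somatic
#'   \code{\link{VariantCall-class}} objects.
#' @return A sorted list of labeled \code{VariantCall}s.
#' @export
mergeCalls <- function(domCalls, tbmCalls) {
    somatic <- function(calls)
        Filter(function(x) x@category == "somatic" && callPassed(x), calls)
    domCalls <- somatic(domCalls); tbmCalls <- somatic(tbmCalls)
    keyOf <- function(x) paste(x@chrom, x@pos, x@alt, sep = ":")
    siteOf <- function(x) paste(x@chrom, x@pos, sep = ":")
    domKeys <- vapply(domCalls, keyOf, character(1))
    tbmKeys <- vapply(tbmCalls, keyOf, character(1))

    domSites <- vapply(domCalls, siteOf, character(1))
    tbmSites <- vapply(tbmCalls, siteOf, character(1))
    conflict <- intersect(domSites[!domKeys %in% tbmKeys],
                          tbmSites[!tbmKeys %in% domKeys])
    conflict <- intersect(conflict, intersect(domSites, tbmSites))
    for (s in conflict)
        message("allele conflict between methods at ", s,
                "; keeping both calls")

    out <- list()
    for (i in seq_along(domCalls)) {
        d <- domCalls[[i]]
        j <- match(domKeys[i], tbmKeys)
        if (!is.na(j)) {
            t <- tbmCalls[[j]]
            sums <- t@summaries
            sums[names(d@summaries)] <- d@summaries
            out[[length(out) + 1L]] <-
                VariantCall(d@chrom, d@pos, d@ref, d@alt, "somatic", "both",
                            label = "RNA_Confirmation", summaries = sums)
        } else {
            out[[length(out) + 1L]] <-
                VariantCall(d@chrom, d@pos, d@ref, d@alt, "somatic", "DOM",
                            label = "DNA_only", summaries = d@summaries)
        }
    }
    for (j in seq_along(tbmCalls)) {
        if (tbmKeys[j] %in% domKeys) next
        t <- tbmCalls[[j]]
        out[[length(out) + 1L]] <-
            VariantCall(t@chrom, t@pos, t@ref, t@alt, "somatic", "TBM",
                        label = "RNA_Rescue", summaries = t@summaries)
    }
    if (length(out) == 0L) return(out)
    ord <- order(vapply(out, function(x) x@chrom, character(1)),
                 vapply(out, function(x) x@pos, integer(1)),
                 vapply(out, function(x) x@alt, character(1)))
    out[ord]
}

#' Integer variant-allele-frequency percentage
#'
#' \code{round(100 * altDepth / depth)}, rounding halves away from zero —
#' the convention used when reporting read-support ratios like
#' \code{"20/40 (50\%)"}.
#'
#' @param altDepth alt-supporting read count.
#' @param depth total read count; must be positive.
#' @return Integer percentage.
#' @examples
#' formatVafPercent(31, 34)  # 91
#' formatVafPercent(20, 40)  # 50
#' @export
formatVafPercent <- function(altDepth, depth) {
    if (any(depth <= 0)) stop("depth must be positive")
    as.integer(floor(100 * altDepth / depth + 0.5))
}

vcfSampleField <- function(s) {
    if (is.null(s)) return(".")
    nOther <- as.integer(round(s@otherFraction * s@depth))
    nRef <- s@depth - s@altDepth - nOther
    fmt1 <- function(x) if (is.na(x)) "." else sprintf("%.4g", x)
    paste(s@depth, paste(nRef, s@altDepth, sep = ","),
          fmt1(if (s@depth > 0) s@altFraction else NA_real_),
          fmt1(s@avgAltBaseQuality), fmt1(s@avgMapQuality), sep = ":")
}

#' Write calls as VCF 4.2
#'
#' Positions are written 1-based; the FILTER column carries \code{PASS} or
#' the semicolon-joined failed-filter names; INFO carries the call category,
#' method of origin and merge label; per-sample FORMAT fields are
#' \code{DP} (filtered depth), \code{AD} (ref,alt depths), \code{AF} (alt
#' fraction), \code{ABQ} (mean alt base quality) and \code{AMQ} (mean
#' mapping quality). Output is deterministic: identical calls give a
#' byte-identical file.
#'
#' @param calls list of \code{\link{VariantCall-class}} objects.
#' @param outPath output file path.
#' @param sampleNames named character vector mapping sample roles to VCF
#'   sample column names.
#' @return \code{outPath}, invisibly.
#' @export
writeVCF <- function(calls, outPath,
                     sampleNames = c(normalDNA = "NORMAL_DNA",
                                     tumorDNA = "TUMOR_DNA",
                                     tumorRNA = "TUMOR_RNA")) {
    filters <- sort(unique(unlist(lapply(calls,
                                         function(x) x@failedFilters))))
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=triovar",
        "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Call category: germline or somatic\">",
        "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Calling method: DOM (DNA-only), TBM (triple-sample) or both\">",
        "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Merge label: RNA_Confirmation, RNA_Rescue, DNA_only or none\">",
        sprintf("##FILTER=<ID=%s,Description=\"Failed the %s filter\">",
                filters, filters),
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
        "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Reference and alternative read depths\">",
        "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
        "##FORMAT=<ID=ABQ,Number=1,Type=Float,Description=\"Mean alternative base quality (phred)\">",
        "##FORMAT=<ID=AMQ,Number=1,Type=Float,Description=\"Mean mapping quality (phred)\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", unname(sampleNames)), collapse = "\t"))
    lines <- vapply(calls, function(x) {
        info <- sprintf("CAT=%s;ORIGIN=%s;LABEL=%s", x@category, x@origin,
                        x@label)
        samples <- vapply(names(sampleNames), function(role)
            vcfSampleField(x@summaries[[role]]), character(1))
        paste(c(x@chrom, x@pos + 1L, ".", x@ref, x@alt, ".",
                filterField(x), info, "DP:AD:AF:ABQ:AMQ", samples),
              collapse = "\t")
    }, character(1))
    writeLines(c(hdr, lines), outPath)
    invisible(outPath)
}

#' Per-filter rejection report
#'
#' Attributes every rejected candidate to the first filter it failed and
#' tabulates counts per method. Totals per method reconcile with
#' (candidates - emitted calls).
#'
#' @param runCalls named list of call lists (e.g.
#'   \code{list(DOM = ..., TBM = ...)}), each containing passing and failing
#'   \code{\link{VariantCall-class}} objects (evaluate with
#'   \code{keepFailed = TRUE} to retain the failures).
#' @return A \code{data.frame} with columns \code{method}, \code{filter},
#'   \code{count}; zero rows when every candidate passed.
#' @export
filterReport <- function(runCalls) {
    rows <- lapply(names(runCalls), function(method) {
        firsts <- vapply(Filter(function(x) !callPassed(x),
                                runCalls[[method]]),
                         function(x) x@failedFilters[1], character(1))
        if (length(firsts) == 0L) return(NULL)
        tab <- table(firsts)
        data.frame(method = method, filter = names(tab),
                   count = as.integer(tab), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(method = character(0), filter = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
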