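#' Specification of one synthetic pileup column
#'
#' Drives the fully self-contained triplet generator: per-role depths and
#' true VAFs, phred base/mapping-quality distributions (normal, rounded and
#' clamped to [0, 60]), strand balance (probability of the forward strand),
#' an optional positional-bias mode placing a fraction of the alt reads in
#' the first or last third of the read, a Poisson mismatch-count mean, the
#' proper-pairing rate and the alleles.
#'
#' @param depth named integer vector of per-role depths.
#' @param trueVaf named numeric vector of per-role true VAFs.
#' @param baseQualMean,baseQualSd,mapQualMean,mapQualSd quality
#'   distributions.
#' @param strandBalance forward-strand probability.
#' @param positionalBias \code{"none"}, \code{"start"} or \code{"end"}.
#' @param positionalBiasFraction fraction of alt reads placed in the biased
#'   third when \code{positionalBias != "none"}.
#' @param mismatchMean Poisson mean of per-read mismatch counts.
#' @param properPairRate probability a read is properly paired.
#' @param refBase,altBase the two alleles.
#' @param readLength read length in bases.
#' @return A named list of class \code{SynthColumnSpec}.
#' @export
synthColumnSpec <- function(depth = c(normalDNA = 30L, tumorDNA = 30L,
                                      tumorRNA = 30L),
                            trueVaf = c(normalDNA = 0, tumorDNA = 0.3,
                                        tumorRNA = 0.3),
                            baseQualMean = 30, baseQualSd = 3,
                            mapQualMean = 40, mapQualSd = 5,
                            strandBalance = 0.5,
                            positionalBias = c("none", "start", "end"),
                            positionalBiasFraction = 1,
                            mismatchMean = 1, properPairRate = 1,
                            refBase = "A", altBase = "T",
                            readLength = 100L) {
    positionalBias <- match.arg(positionalBias)
    stopifnot(all(trueVaf >= 0 & trueVaf <= 1),
              strandBalance >= 0, strandBalance <= 1,
              properPairRate >= 0, properPairRate <= 1,
              positionalBiasFraction >= 0, positionalBiasFraction <= 1,
              refBase %in% c("A", "C", "G", "T"),
              altBase %in% c("A", "C", "G", "T"), refBase != altBase)
    structure(list(depth = depth, trueVaf = trueVaf,
                   baseQualMean = baseQualMean, baseQualSd = baseQualSd,
                   mapQualMean = mapQualMean, mapQualSd = mapQualSd,
                   strandBalance = strandBalance,
                   positionalBias = positionalBias,
                   positionalBiasFraction = positionalBiasFraction,
                   mismatchMean = mismatchMean,
                   properPairRate = properPairRate, refBase = refBase,
                   altBase = altBase, readLength = as.integer(readLength)),
              class = "SynthColumnSpec")
}

rquals <- function(n, mean, sd)
    pmin(60L, pmax(0L, as.integer(round(rnorm(n, mean, sd)))))

#' Generate one synthetic pileup column
#'
#' Per role, \code{round(trueVaf * depth)} alt observations (halves away
#' from zero) and reference observations for the rest, with qualities,
#' strands, offsets, mismatch counts and pairing flags drawn from the spec's
#' distributions. Deterministic under the session RNG state (seed before
#' calling).
#'
#' @param spec a \code{\link{synthColumnSpec}}.
#' @param chrom,pos site of the column (0-based position).
#' @return A \code{\link{PileupColumn-class}}.
#' @export
generateColumn <- function(spec, chrom = "chr1", pos = 0L) {
    rows <- lapply(names(spec$depth), function(role) {
        d <- spec$depth[[role]]
        if (d == 0L) return(NULL)
        vaf <- if (role %in% names(spec$trueVaf)) spec$trueVaf[[role]] else 0
        k <- as.integer(floor(vaf * d + 0.5))
        isAlt <- c(rep(TRUE, k), rep(FALSE, d - k))
        L <- spec$readLength
        offs <- sample.int(L, d, replace = TRUE) - 1L
        if (spec$positionalBias != "none" && k > 0L) {
            third <- L %/% 3L
            biased <- runif(k) < spec$positionalBiasFraction
            lo <- if (spec$positionalBias == "start") 0L else
                as.integer(ceiling(2 * L / 3))
            n1 <- sum(biased)
            if (n1 > 0L)
                offs[seq_len(k)][biased] <-
                    lo + sample.int(third, n1, replace = TRUE) - 1L
            # un-biased alt reads stay in the middle third
            n0 <- k - n1
            if (n0 > 0L)
                offs[seq_len(k)][!biased] <- as.integer(ceiling(L / 3)) +
                    sample.int(third, n0, replace = TRUE) - 1L
        }
        bq <- rquals(d, spec$baseQualMean, spec$baseQualSd)
        fm <- matrix(rquals(10L * d, spec$baseQualMean, spec$baseQualSd),
                     nrow = d)
        flanks <- do.call(paste, c(lapply(seq_len(10L),
                                          function(j) fm[, j]),
                                   list(sep = ",")))
        list(
            readId = sprintf("%s_%04d", role, seq_len(d)),
            base = ifelse(isAlt, spec$altBase, spec$refBase),
            baseQual = bq,
            mapQual = rquals(d, spec$mapQualMean, spec$mapQualSd),
            strand = ifelse(runif(d) < spec$strandBalance, "+", "-"),
            offsetInRead = offs, readLength = rep(L, d),
            properlyPaired = runif(d) < spec$properPairRate,
            mismatchCount = rpois(d, spec$mismatchMean),
            hasIndel = rep(FALSE, d), flankQuals = flanks,
            readSeq = rep(NA_character_, d),
            sampleRole = rep(role, d))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) {
        obs <- readObservations(base = character(0), baseQual = integer(0),
                                mapQual = integer(0))
    } else {
        obs <- as.data.frame(
            lapply(setNames(nm = OBS_COLUMNS), function(f)
                unlist(lapply(rows, `[[`, f), use.names = FALSE)),
            stringsAsFactors = FALSE)
    }
    PileupColumn(chrom, pos, spec$refBase, obs)
}

#' Generate a synthetic dataset with truth annotations
#'
#' Draws \code{nColumns} column specs from \code{specSampler}, generates the
#' columns, writes them in the pileup TSV dialect and writes a truth TSV
#' carrying each column's per-role true VAFs together with the outcome an
#' independently coded brute-force re-implementation of the two decision
#' procedures (\code{\link{referenceEvaluate}}) assigns to it.
#'
#' @param nColumns number of columns.
#' @param specSampler function \code{(i) -> SynthColumnSpec}; the default
#'   draws tumor DNA/RNA VAFs uniformly from {0, 0.05, ..., 0.5} over a
#'   depth grid.
#' @param seed RNG seed.
#' @param pileupPath,truthPath output paths.
#' @return Invisibly, a list with the generated \code{columns} and the
#'   \code{truth} table.
#' @export
generateDataset <- function(nColumns, specSampler = NULL, seed = 1L,
                            pileupPath, truthPath) {
    set.seed(seed)
    if (is.null(specSampler))
        specSampler <- function(i) {
            vaf <- sample(seq(0, 0.5, by = 0.05), 2L, replace = TRUE)
            synthColumnSpec(
                depth = c(normalDNA = sample(5:40, 1L),
                          tumorDNA = sample(5:40, 1L),
                          tumorRNA = sample(5:40, 1L)),
                trueVaf = c(normalDNA = 0, tumorDNA = vaf[1],
                            tumorRNA = vaf[2]))
        }
    columns <- vector("list", nColumns)
    truthRows <- vector("list", nColumns)
    for (i in seq_len(nColumns)) {
        spec <- specSampler(i)
        col <- generateColumn(spec, chrom = "chr1", pos = (i - 1L) * 100L)
        columns[[i]] <- col
        truthRows[[i]] <- data.frame(
            chrom = columnChrom(col), pos0 = columnPos(col),
            refBase = spec$refBase, altBase = spec$altBase,
            normalVaf = spec$trueVaf[["normalDNA"]],
            dnaVaf = spec$trueVaf[["tumorDNA"]],
            rnaVaf = spec$trueVaf[["tumorRNA"]],
            domOutcome = referenceEvaluate(col, "DOM"),
            tbmOutcome = referenceEvaluate(col, "TBM"),
            stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truthRows)
    writePileupTSV(columns, pileupPath)
    write.table(truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(columns = columns, truth = truth))
}

# ---------------------------------------------------------------------------
# Brute-force re-implementation of the two decision procedures, kept
# deliberately free of the summarizeColumn/applyThresholds/evaluate code
# path: everything is recomputed inline from the raw observation rows. It
# serves as the equivalence oracle for the main implementation and as the
# truth predicate of generateDataset. Annotation region filters and the
# remap check are outside its scope (synthetic columns carry neither).
# ---------------------------------------------------------------------------

#' Brute-force reference outcome for one column
#'
#' Recomputes, directly from the raw observation rows and independently of
#' the production code path, what the DNA-only or triple-sample procedure
#' should decide at a column (no annotation regions, no remap check).
#'
#' @param column a \code{\link{PileupColumn-class}}.
#' @param method \code{"DOM"} or \code{"TBM"}.
#' @return \code{"germline"}, \code{"somatic"} or \code{"none"}.
#' @export
referenceEvaluate <- function(column, method = c("DOM", "TBM")) {
    method <- match.arg(method)
    ref <- column@observations   # raw table
    refBase <- column@refBase
    pick <- function(role) {
        o <- ref[ref$sampleRole == role, , drop = FALSE]
        o[o$baseQual >= 10 & o$mapQual >= 10 & o$base != "N", ,
          drop = FALSE]
    }
    topAlt <- function(o) {
        best <- NA_character_; bestN <- 0L
        for (b in c("A", "C", "G", "T")) {
            if (b == refBase) next
            nb <- sum(o$base == b)
            if (nb > bestN) { best <- b; bestN <- nb }
        }
        best
    }
    countsFor <- function(o, alt) {
        d <- nrow(o)
        nAlt <- if (is.na(alt)) 0L else sum(o$base == alt)
        nRef <- sum(o$base == refBase)
        altRows <- if (is.na(alt)) o[0, ] else o[o$base == alt, ,
                                                 drop = FALSE]
        list(d = d, nAlt = nAlt, nOther = d - nRef - nAlt,
             baq = if (nAlt > 0) mean(altRows$baseQual) else NA_real_,
             fwd = if (nAlt > 0) sum(altRows$strand == "+") / nAlt
                   else NA_real_,
             altRows = altRows)
    }
    strandOk <- function(c) {
        if (c$nAlt < 4) return(TRUE)
        f <- c$fwd
        max(f, 1 - f) <= 0.90
    }

    nObs <- pick("normalDNA")
    tObs <- pick("tumorDNA")

    if (method == "DOM") {
        nAltBase <- topAlt(nObs)
        nc <- countsFor(nObs, nAltBase)
        if (nc$d >= 4 && nc$nAlt >= 2) {
            # germline test
            if (nc$d >= 10 && nc$nAlt >= 4 && nc$nAlt / nc$d >= 0.10 &&
                !is.na(nc$baq) && nc$baq >= 20 && strandOk(nc) &&
                nc$nOther / nc$d <= 0.02)
                return("germline")
        }
        tAltBase <- topAlt(tObs)
        tc <- countsFor(tObs, tAltBase)
        if (!(tc$d >= 4 && tc$nAlt >= 2)) return("none")
        ncf <- countsFor(nObs, tAltBase)
        normalOk <- ncf$d >= 10 &&
            (if (ncf$d > 0) ncf$nAlt / ncf$d else 0) <= 0.02 &&
            (if (ncf$d > 0) ncf$nOther / ncf$d else 0) <= 0.02
        tumorOk <- tc$d >= 10 && tc$nAlt >= 4 && tc$nAlt / tc$d >= 0.10 &&
            !is.na(tc$baq) && tc$baq >= 20 && strandOk(tc) &&
            tc$nOther / tc$d <= 0.02
        if (normalOk && tumorOk) return("somatic")
        return("none")
    }

    # TBM
    rObs <- pick("tumorRNA")
    rAltBase <- topAlt(rObs)
    rc <- countsFor(rObs, rAltBase)
    if (!(rc$d >= 4 && rc$nAlt >= 2)) return("none")
    ncf <- countsFor(nObs, rAltBase)
    dcf <- countsFor(tObs, rAltBase)
    normalOk <- ncf$d >= 10 &&
        (if (ncf$d > 0) ncf$nAlt / ncf$d else 0) <= 0.10 &&
        (if (ncf$d > 0) ncf$nOther / ncf$d else 0) <= 0.10
    dnaOk <- dcf$d >= 1 && dcf$nAlt >= 1 && !is.na(dcf$baq) &&
        dcf$baq >= 15 && strandOk(dcf) &&
        (if (dcf$d > 0) dcf$nOther / dcf$d else 0) <= 0.10
    rnaOk <- rc$d >= 10 && rc$nAlt >= 4 && rc$nAlt / rc$d >= 0.10 &&
        !is.na(rc$baq) && rc$baq >= 15 && strandOk(rc) &&
        rc$nOther / rc$d <= 0.02
    posOk <- TRUE
    if (rc$nAlt > 0) {
        rel <- rc$altRows$offsetInRead / rc$altRows$readLength
        fs <- sum(rel < 1 / 3) / rc$nAlt
        fe <- sum(rel >= 2 / 3) / rc$nAlt
        posOk <- fs < 0.95 && fe < 0.95
    }
    if (normalOk && dnaOk && rnaOk && posOk) return("somatic")
    "none"
}
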