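PILEUP_TSV_COLUMNS <- c("chrom", "pos0", "refBase", "sampleRole", "readId",
                        "base", "baseQual", "mapQual", "strand",
                        "offsetInRead", "readLength", "properlyPaired",
                        "mismatchCount", "hasIndel", "flankQuals", "readSeq")

#' Read a plain-text pileup table into pileup columns
#'
#' The pileup TSV dialect carries one read observation per row with a
#' mandatory header: \code{chrom, pos0, refBase, sampleRole, readId, base,
#' baseQual, mapQual, strand(+/-), offsetInRead, readLength,
#' properlyPaired(0/1), mismatchCount, hasIndel(0/1), flankQuals
#' (comma-joined), readSeq ("." if absent)}. Positions are 0-based. Rows
#' sharing \code{chrom} and \code{pos0} form one column; columns are returned
#' in file order.
#'
#' @param path path to the TSV file.
#' @return A list of \code{\link{PileupColumn-class}} objects (empty list for
#'   an empty file).
#' @seealso \code{\link{writePileupTSV}} for the inverse.
#' @export
readPileupTSV <- function(path) {
    if (!file.exists(path))
        stop("pileup file not found: ", path)
    tab <- tryCatch(
        read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "",
                   quote = "", check.names = FALSE),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(NULL)
            stop(e)
        })
    if (is.null(tab) || nrow(tab) == 0L) {
        if (!is.null(tab)) checkPileupHeader(names(tab))
        return(list())
    }
    checkPileupHeader(names(tab))
    line <- seq_len(nrow(tab)) + 1L  # account for the header line

    asInt <- function(col) {
        v <- suppressWarnings(as.integer(tab[[col]]))
        bad <- which(is.na(v) | tab[[col]] == "")
        if (length(bad))
            stop("parse error at line ", line[bad[1]],
                 ": field '", col, "' is not an integer")
        v
    }
    obs <- data.frame(
        readId = tab$readId,
        base = toupper(tab$base),
        baseQual = asInt("baseQual"),
        mapQual = asInt("mapQual"),
        strand = tab$strand,
        offsetInRead = asInt("offsetInRead"),
        readLength = asInt("readLength"),
        properlyPaired = asInt("properlyPaired") != 0L,
        mismatchCount = asInt("mismatchCount"),
        hasIndel = asInt("hasIndel") != 0L,
        flankQuals = tab$flankQuals,
        readSeq = ifelse(tab$readSeq == ".", NA_character_, tab$readSeq),
        sampleRole = tab$sampleRole,
        stringsAsFactors = FALSE
    )
    bad <- which(!(obs$base %in% VALID_BASES))
    if (length(bad))
        stop("parse error at line ", line[bad[1]], ": field 'base' value '",
             obs$base[bad[1]], "' is not one of A,C,G,T,N")
    bad <- which(!(toupper(tab$refBase) %in% VALID_BASES))
    if (length(bad))
        stop("parse error at line ", line[bad[1]],
             ": field 'refBase' value '", tab$refBase[bad[1]],
             "' is not one of A,C,G,T,N")
    bad <- which(!(obs$sampleRole %in% SAMPLE_ROLES))
    if (length(bad))
        stop("parse error at line ", line[bad[1]],
             ": field 'sampleRole' value '", obs$sampleRole[bad[1]], "'")
    bad <- which(!(obs$strand %in% c("+", "-")))
    if (length(bad))
        stop("parse error at line ", line[bad[1]], ": field 'strand'")

    key <- paste(tab$chrom, tab$pos0, sep = "\r")
    keys <- unique(key)   # file order
    lapply(keys, function(k) {
        idx <- which(key == k)
        PileupColumn(tab$chrom[idx[1]], as.integer(tab$pos0[idx[1]]),
                     toupper(tab$refBase[idx[1]]),
                     obs[idx, , drop = FALSE])
    })
}

checkPileupHeader <- function(nms) {
    missing <- setdiff(PILEUP_TSV_COLUMNS, nms)
    if (length(missing))
        stop("pileup TSV header is missing required field(s): ",
             paste(missing, collapse = ", "))
    invisible(TRUE)
}

#' Write pileup columns in the pileup TSV dialect
#'
#' @param columns list of \code{\link{PileupColumn-class}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePileupTSV <- function(columns, path) {
    rows <- lapply(columns, function(col) {
        obs <- col@observations
        if (nrow(obs) == 0L) return(NULL)
        data.frame(chrom = col@chrom, pos0 = col@pos, refBase = col@refBase,
                   sampleRole = obs$sampleRole, readId = obs$readId,
                   base = obs$base, baseQual = obs$baseQual,
                   mapQual = obs$mapQual, strand = obs$strand,
                   offsetInRead = obs$offsetInRead,
                   readLength = obs$readLength,
                   properlyPaired = as.integer(obs$properlyPaired),
                   mismatchCount = obs$mismatchCount,
                   hasIndel = as.integer(obs$hasIndel),
                   flankQuals = obs$flankQuals,
                   readSeq = ifelse(is.na(obs$readSeq), ".", obs$readSeq),
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        tab <- as.data.frame(setNames(
            replicate(length(PILEUP_TSV_COLUMNS), character(0),
                      simplify = FALSE), PILEUP_TSV_COLUMNS))
    write.table(tab[, PILEUP_TSV_COLUMNS], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Build pileup columns from coordinate-sorted BAM files
#'
#' Traverses one alignment file per sample role over a region and assembles a
#' \code{\link{PileupColumn-class}} per covered reference position. Each
#' aligned base contributes a read observation carrying its base and mapping
#' quality, strand, offset within the read, pairing flag, mismatch count and
#' indel flag. Mismatch counts come from the NM tag minus inserted/deleted
#' bases; when NM is absent they are recomputed from the MD tag; when both are
#' absent the count is 0 and a warning is emitted.
#'
#' @param bamPaths named list/vector mapping sample roles (\code{normalDNA},
#'   \code{tumorDNA}, \code{tumorRNA}) to indexed BAM paths. A missing role
#'   simply yields no observations for that role.
#' @param referenceFasta path to an (indexed or indexable) FASTA with the
#'   reference sequence, or a named \code{Biostrings::DNAStringSet}.
#' @param region a single-range \code{GenomicRanges::GRanges} (1-based, as
#'   usual for GRanges) delimiting the traversal.
#' @param singleEndProper treat single-end reads as properly paired
#'   (the convention for single-end RNA libraries); set \code{FALSE} to
#'   require the proper-pair flag regardless of pairing mode.
#' @return A list of \code{PileupColumn}, one per covered position, sorted by
#'   position. Positions are 0-based internally.
#' @export
readBamPileup <- function(bamPaths, referenceFasta, region,
                          singleEndProper = TRUE) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    rstart <- GenomicRanges::start(region)   # 1-based
    rend <- GenomicRanges::end(region)

    refSeq <- if (is(referenceFasta, "DNAStringSet")) {
        referenceFasta
    } else {
        if (!file.exists(paste0(referenceFasta, ".fai")))
            Rsamtools::indexFa(referenceFasta)
        Biostrings::readDNAStringSet(referenceFasta)
    }
    names(refSeq) <- sub("\\s.*$", "", names(refSeq))
    if (!chrom %in% names(refSeq))
        stop("chromosome ", chrom, " not present in the reference")
    refChars <- strsplit(toupper(as.character(
        Biostrings::subseq(refSeq[[chrom]], rstart, rend))), "")[[1]]

    perRole <- list()
    for (role in intersect(SAMPLE_ROLES, names(bamPaths))) {
        path <- bamPaths[[role]]
        if (!file.exists(paste0(path, ".bai")) &&
            !file.exists(sub("\\.bam$", ".bai", path)))
            stop("BAM index missing for ", path)
        param <- Rsamtools::ScanBamParam(
            which = region, what = c("qname", "flag", "rname", "strand",
                                     "pos", "mapq", "cigar", "seq", "qual"),
            tag = c("NM", "MD"))
        aln <- Rsamtools::scanBam(path, param = param)[[1]]
        perRole[[role]] <- bamRecordsToObservations(aln, role, rstart, rend,
                                                    singleEndProper)
    }
    obs <- do.call(rbind, unname(perRole))
    if (is.null(obs) || nrow(obs) == 0L)
        return(list())
    positions <- sort(unique(obs$.refpos))
    lapply(positions, function(p) {
        sub <- obs[obs$.refpos == p, setdiff(names(obs), ".refpos"),
                   drop = FALSE]
        rownames(sub) <- NULL
        PileupColumn(chrom, p - 1L, refChars[p - rstart + 1L], sub)
    })
}

# expand one role's BAM records into per-position observation rows
bamRecordsToObservations <- function(aln, role, rstart, rend,
                                     singleEndProper) {
    n <- length(aln$pos)
    if (n == 0L) return(NULL)
    nmWarned <- FALSE
    out <- vector("list", n)
    for (i in seq_len(n)) {
        if (is.na(aln$pos[i])) next
        cig <- aln$cigar[i]
        ops <- GenomicAlignments::explodeCigarOps(cig)[[1]]
        lens <- GenomicAlignments::explodeCigarOpLengths(cig)[[1]]
        quals <- as.integer(Biostrings::PhredQuality(aln$qual[i])[[1]])
        seqChars <- strsplit(as.character(aln$seq[i]), "")[[1]]
        readLen <- length(seqChars)
        hasIndel <- any(ops %in% c("I", "D"))

        nm <- aln$tag$NM[i]
        if (!is.null(nm) && !is.na(nm)) {
            indelBases <- sum(lens[ops %in% c("I", "D")])
            mm <- max(0L, as.integer(nm) - indelBases)
        } else {
            md <- aln$tag$MD[i]
            if (!is.null(md) && !is.na(md)) {
                mm <- mismatchesFromMD(md)
            } else {
                if (!nmWarned) {
                    warning("NM and MD tags absent for role ", role,
                            "; mismatch counts set to 0")
                    nmWarned <- TRUE
                }
                mm <- 0L
            }
        }
        flag <- aln$flag[i]
        paired <- bitwAnd(flag, 1L) != 0L
        proper <- if (paired) bitwAnd(flag, 2L) != 0L else singleEndProper

        refPos <- aln$pos[i]          # 1-based
        qryPos <- 1L
        refposv <- integer(0); offv <- integer(0)
        for (k in seq_along(ops)) {
            op <- ops[k]; L <- lens[k]
            if (op %in% c("M", "=", "X")) {
                refposv <- c(refposv, refPos:(refPos + L - 1L))
                offv <- c(offv, qryPos:(qryPos + L - 1L))
                refPos <- refPos + L; qryPos <- qryPos + L
            } else if (op %in% c("I", "S")) {
                qryPos <- qryPos + L
            } else if (op %in% c("D", "N")) {
                refPos <- refPos + L
            }
        }
        keep <- refposv >= rstart & refposv <= rend
        if (!any(keep)) next
        refposv <- refposv[keep]; offv <- offv[keep]
        flanks <- vapply(offv, function(q) {
            idx <- setdiff(max(1L, q - 5L):min(readLen, q + 5L), q)
            paste(quals[idx], collapse = ",")
        }, character(1))
        out[[i]] <- data.frame(
            readId = aln$qname[i], base = toupper(seqChars[offv]),
            baseQual = quals[offv], mapQual = as.integer(aln$mapq[i]),
            strand = as.character(aln$strand[i]),
            offsetInRead = offv - 1L, readLength = readLen,
            properlyPaired = proper, mismatchCount = mm,
            hasIndel = hasIndel, flankQuals = flanks,
            readSeq = as.character(aln$seq[i]), sampleRole = role,
            .refpos = refposv, stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

mismatchesFromMD <- function(md) {
    # mismatched reference bases appear as single letters outside ^-deletions
    toks <- regmatches(md, gregexpr("\\^[ACGTN]+|[ACGTN]|[0-9]+", md))[[1]]
    sum(grepl("^[ACGTN]$", toks))
}

#' Summarize the observations of one sample at a column
#'
#' Applies the base- and mapping-quality floors, drops N bases, and computes
#' the per-sample aggregate the filters consume: depth, the alternative
#' allele (highest filtered count among non-reference bases, ties broken
#' alphabetically A<C<G<T), its depth and fraction, mean alt base quality,
#' mean mapping quality, forward-strand fraction of alt reads and the
#' fraction of reads supporting a third allele.
#'
#' @param obs observation \code{data.frame} (see
#'   \code{\link{readObservations}}); may be empty.
#' @param refBase the reference base at the column.
#' @param minBaseQual,minMapQual phred floors; observations below either are
#'   excluded from every count.
#' @param altAllele optionally force the summarized alternative allele (used
#'   for cross-sample allele matching); default picks the top non-reference
#'   base.
#' @return An \code{\link{AlleleSummary-class}}.
#' @examples
#' obs <- readObservations(base = c(rep("A", 6), rep("T", 4)),
#'                         baseQual = 30, mapQual = 40,
#'                         strand = rep(c("+", "-"), 5))
#' summarizeColumn(obs, refBase = "A")
#' @export
summarizeColumn <- function(obs, refBase, minBaseQual = 10L,
                            minMapQual = 10L, altAllele = NULL) {
    refBase <- toupper(refBase)
    base <- obs$base; bq <- obs$baseQual; mq <- obs$mapQual
    strand <- obs$strand
    keep <- bq >= minBaseQual & mq >= minMapQual & base != "N"
    base <- base[keep]; bq <- bq[keep]; mq <- mq[keep]
    strand <- strand[keep]
    depth <- length(base)
    if (is.null(altAllele)) {
        counts <- c(A = sum(base == "A"), C = sum(base == "C"),
                    G = sum(base == "G"), T = sum(base == "T"))
        if (refBase %in% names(counts)) counts[[refBase]] <- 0L
        # which.max over the A,C,G,T order breaks ties alphabetically
        altAllele <- if (max(counts) > 0L) names(counts)[which.max(counts)]
                     else NA_character_
    } else {
        altAllele <- toupper(altAllele)
    }
    isAlt <- !is.na(altAllele) & base == altAllele
    nAlt <- sum(isAlt)
    nRef <- sum(base == refBase)
    AlleleSummary(
        depth = depth,
        altAllele = altAllele,
        altDepth = nAlt,
        altFraction = if (depth > 0L) nAlt / depth else 0,
        avgAltBaseQuality = if (nAlt > 0L) mean(bq[isAlt]) else NA_real_,
        avgMapQuality = if (depth > 0L) mean(mq) else NA_real_,
        altForwardFraction = if (nAlt > 0L) mean(strand[isAlt] == "+") else NA_real_,
        otherFraction = if (depth > 0L) (depth - nRef - nAlt) / depth else 0)
}
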