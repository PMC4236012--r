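test_that("allele summary matches a hand count", {
    # 10 observations: 6 ref A, 4 alt T, 2 of the 4 alt reads forward
    obs <- readObservations(
        base = c(rep("A", 6), rep("T", 4)), baseQual = 30, mapQual = 40,
        strand = c(rep("+", 6), "+", "+", "-", "-"))
    s <- summarizeColumn(obs, "A")
    expect_equal(summaryDepth(s), 10L)
    expect_equal(altAllele(s), "T")
    expect_equal(altDepth(s), 4L)
    expect_equal(altFraction(s), 0.4)
    expect_equal(s@altForwardFraction, 0.5)
    expect_equal(s@otherFraction, 0)
})

test_that("all-reference and below-threshold observations summarize sanely", {
    refOnly <- readObservations(base = rep("A", 10), baseQual = 30,
                                mapQual = 40)
    s <- summarizeColumn(refOnly, "A")
    expect_true(is.na(altAllele(s)))
    expect_equal(altDepth(s), 0L)

    lowQ <- readObservations(base = rep("T", 4), baseQual = 5, mapQual = 40)
    s2 <- summarizeColumn(lowQ, "A", minBaseQual = 10)
    expect_equal(summaryDepth(s2), 0L)
    expect_equal(altDepth(s2), 0L)

    empty <- readObservations(base = character(0), baseQual = integer(0),
                              mapQual = integer(0))
    s3 <- summarizeColumn(empty, "A")
    expect_equal(summaryDepth(s3), 0L)
    expect_equal(altFraction(s3), 0)
})

test_that("N bases are excluded from depth and the alt tie-break is A<C<G<T", {
    obs <- readObservations(base = c("A", "A", "N", "G", "C"), baseQual = 30,
                            mapQual = 40)
    s <- summarizeColumn(obs, "A")
    expect_equal(summaryDepth(s), 4L)  # N dropped
    expect_equal(altAllele(s), "C")    # C and G tie at 1; C wins
})

test_that("summarize agrees with a naive recount and is permutation invariant", {
    set.seed(101)
    for (i in 1:60) {
        n <- sample(0:40, 1)
        obs <- readObservations(
            base = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                          prob = c(.5, .15, .15, .15, .05)),
            baseQual = sample(0:45, max(n, 1), replace = TRUE)[seq_len(n)],
            mapQual = sample(0:60, max(n, 1), replace = TRUE)[seq_len(n)],
            strand = sample(c("+", "-"), max(n, 1),
                            replace = TRUE)[seq_len(n)])
        s <- summarizeColumn(obs, "A", 10, 10)

        # naive recount
        k <- obs[obs$baseQual >= 10 & obs$mapQual >= 10 & obs$base != "N", ]
        cnt <- vapply(c("C", "G", "T"), function(b) sum(k$base == b),
                      integer(1))
        expect_equal(summaryDepth(s), nrow(k))
        if (any(cnt > 0)) {
            expect_equal(altAllele(s), names(cnt)[which.max(cnt)])
            expect_equal(altDepth(s), max(cnt))
        } else {
            expect_equal(altDepth(s), 0L)
        }
        expect_equal(s@otherFraction * max(1, nrow(k)),
                     nrow(k) - sum(k$base == "A") -
                         if (any(cnt > 0)) max(cnt) else 0)

        # permutation invariance
        perm <- obs[sample(nrow(obs)), , drop = FALSE]
        s2 <- summarizeColumn(perm, "A", 10, 10)
        expect_equal(summaryDepth(s2), summaryDepth(s))
        expect_equal(altDepth(s2), altDepth(s))
        expect_equal(s2@avgAltBaseQuality, s@avgAltBaseQuality)
        expect_equal(s2@altForwardFraction, s@altForwardFraction)
    }
})

test_that("depth is monotone non-increasing in the quality floors", {
    set.seed(7)
    obs <- readObservations(base = sample(c("A", "T"), 30, replace = TRUE),
                            baseQual = sample(0:40, 30, replace = TRUE),
                            mapQual = sample(0:40, 30, replace = TRUE))
    depths <- vapply(seq(0, 40, by = 5), function(q)
        summaryDepth(summarizeColumn(obs, "A", q, q)), integer(1))
    expect_true(all(diff(depths) <= 0))
})

test_that("pileup TSV round-trips and reports malformed input precisely", {
    col <- mkTriplet(pos = 41L)
    tmp <- tempfile(fileext = ".tsv")
    writePileupTSV(list(col), tmp)
    back <- readPileupTSV(tmp)
    expect_length(back, 1)
    expect_equal(columnPos(back[[1]]), 41L)
    expect_equal(columnRef(back[[1]]), "A")
    expect_equal(nrow(roleObservations(back[[1]])),
                 nrow(roleObservations(col)))
    s0 <- summarizeColumn(roleObservations(col, "tumorDNA"), "A")
    s1 <- summarizeColumn(roleObservations(back[[1]], "tumorDNA"), "A")
    expect_equal(altDepth(s1), altDepth(s0))
    expect_equal(s1@avgAltBaseQuality, s0@avgAltBaseQuality)

    # empty file with header only: empty stream, no error
    writePileupTSV(list(), tmp)
    expect_length(readPileupTSV(tmp), 0)

    # corrupt one observed base to Z: parse error naming the line
    writePileupTSV(list(col), tmp)
    lines <- readLines(tmp)
    f <- strsplit(lines[3], "\t")[[1]]
    f[6] <- "Z"
    lines[3] <- paste(f, collapse = "\t")
    writeLines(lines, tmp)
    expect_error(readPileupTSV(tmp), "line 3.*base")

    # missing required column
    writeLines(c("chrom\tpos0", "chr1\t5"), tmp)
    expect_error(readPileupTSV(tmp), "refBase")
})

test_that("BAM pileup traversal recovers per-read detail", {
    refseq <- paste(rep("ACGTTGCA", 8), collapse = "")   # 64 bp
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">chr1", refseq), fa)

    readFrom <- function(start, len) substr(refseq, start, start + len - 1)
    q30 <- paste(rep("?", 10), collapse = "")  # phred 30
    sam <- c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chr1\tLN:64",
        # proper pair, NM=0
        paste("n1", "99", "chr1", "5", "60", "10M", "=", "30", "35",
              readFrom(5, 10), q30, "NM:i:0", sep = "\t"),
        # tumor DNA read with a T mismatch at reference position 9 and NM=1
        paste("t1", "99", "chr1", "5", "60", "10M", "=", "30", "35",
              paste0(substr(readFrom(5, 10), 1, 4), "T",
                     substr(readFrom(5, 10), 6, 10)),
              q30, "NM:i:1", sep = "\t"),
        # single-end RNA read spanning a 2-base deletion
        paste("r1", "0", "chr1", "5", "60", "4M2D6M", "*", "0", "0",
              paste0(readFrom(5, 4), readFrom(11, 6)), q30, "NM:i:2",
              sep = "\t"))
    samPath <- tempfile(fileext = ".sam")
    bams <- list()
    for (role in c("normalDNA", "tumorDNA", "tumorRNA")) {
        writeLines(sam[c(1, 2, 2 + match(role, c("normalDNA", "tumorDNA",
                                                 "tumorRNA")))], samPath)
        dest <- tempfile()
        bams[[role]] <- suppressMessages(
            Rsamtools::asBam(samPath, dest, overwrite = TRUE))
    }
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 14))
    cols <- readBamPileup(bams, fa, region)
    expect_true(length(cols) > 0)
    # position 9 (1-based) = internal pos 8: tumor read carries T
    pos8 <- Filter(function(c) columnPos(c) == 8L, cols)[[1]]
    tObs <- roleObservations(pos8, "tumorDNA")
    expect_equal(tObs$base, "T")
    expect_equal(tObs$mismatchCount, 1L)
    expect_equal(tObs$offsetInRead, 4L)
    nObs <- roleObservations(pos8, "normalDNA")
    expect_equal(nObs$base, substr(refseq, 9, 9))
    expect_true(nObs$properlyPaired)

    # deletion-spanning single-end RNA read: indel flag set, single-end
    # convention counts it as properly paired
    rObs <- roleObservations(pos8, "tumorRNA")
    expect_equal(nrow(rObs), 0L)  # pos 9..10 are deleted in r1
    pos11 <- Filter(function(c) columnPos(c) == 10L, cols)[[1]]
    rObs2 <- roleObservations(pos11, "tumorRNA")
    expect_true(rObs2$hasIndel)
    expect_true(rObs2$properlyPaired)
    colsStrict <- readBamPileup(bams["tumorRNA"], fa, region,
                                singleEndProper = FALSE)
    pos11s <- Filter(function(c) columnPos(c) == 10L, colsStrict)[[1]]
    expect_false(roleObservations(pos11s, "tumorRNA")$properlyPaired)
})
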