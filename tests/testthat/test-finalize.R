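perfectObs <- function(n = 1, base = "T", mapQual = 10L, baseQual = 10L,
                       flank = 10L, paired = TRUE, mismatches = 3L,
                       indel = FALSE, strand = "+") {
    readObservations(base = base, baseQual = baseQual, mapQual = mapQual,
                     strand = strand, properlyPaired = paired,
                     mismatchCount = mismatches, hasIndel = indel,
                     flankQuals = paste(rep(flank, 10), collapse = ","),
                     sampleRole = "tumorDNA")[rep(1, n), , drop = FALSE]
}

test_that("the six perfect-read criteria sit exactly at their boundaries", {
    expect_true(isPerfectRead(perfectObs()))             # all at the floor
    expect_false(isPerfectRead(perfectObs(mapQual = 9L)))
    expect_false(isPerfectRead(perfectObs(baseQual = 9L)))
    expect_false(isPerfectRead(perfectObs(flank = 9L)))
    expect_false(isPerfectRead(perfectObs(paired = FALSE)))
    expect_false(isPerfectRead(perfectObs(mismatches = 4L)))  # "fewer than 4"
    expect_true(isPerfectRead(perfectObs(mismatches = 3L)))
    expect_false(isPerfectRead(perfectObs(indel = TRUE)))
    # flank qualities missing near a read end are not penalized
    o <- perfectObs(); o$flankQuals <- "10,10,10"
    expect_true(isPerfectRead(o))
    o$flankQuals <- ""
    expect_true(isPerfectRead(o))
})

mkCallAt <- function(col, label) {
    new("VariantCall", chrom = columnChrom(col), pos = columnPos(col),
        ref = columnRef(col), alt = "T", category = "somatic",
        origin = switch(label, DNA_only = "DOM", RNA_Rescue = "TBM",
                        "both"),
        label = label, summaries = list(), failedFilters = character(0))
}

test_that("read support needs four perfect alt reads and balanced strands", {
    mkCol <- function(nAltPerfect, nRefPerfect = 4, altStrand = NULL) {
        obs <- rbind(
            mkRoleObs("tumorDNA", nRefPerfect, nAltPerfect,
                      mapQual = 40, baseQual = 30, altStrand = altStrand),
            mkRoleObs("normalDNA", 10, 0))
        PileupColumn("chr1", 5L, "A", obs)
    }
    colPass <- mkCol(4)
    expect_true(readSupportFilter(mkCallAt(colPass, "DNA_only"),
                                  colPass)$passed)
    col3 <- mkCol(3)
    v <- readSupportFilter(mkCallAt(col3, "DNA_only"), col3)
    expect_false(v$passed)
    expect_equal(v$failedFilters, "minPerfectSupport")

    # 5 perfect alt reads but every perfect read on the forward strand
    obs <- mkRoleObs("tumorDNA", 0, 5, mapQual = 40, baseQual = 30,
                     strand = rep("+", 5))
    colBias <- PileupColumn("chr1", 5L, "A", obs)
    v2 <- readSupportFilter(mkCallAt(colBias, "DNA_only"), colBias)
    expect_false(v2$passed)
    expect_true("perfectStrandBias" %in% v2$failedFilters)

    # imperfect reads do not count toward support
    colImp <- PileupColumn("chr1", 5L, "A",
                           mkRoleObs("tumorDNA", 4, 4, mapQual = 5))
    expect_false(readSupportFilter(mkCallAt(colImp, "DNA_only"),
                                   colImp)$passed)

    # an RNA-rescued call draws its support from the RNA
    colRna <- PileupColumn("chr1", 5L, "A", rbind(
        mkRoleObs("tumorDNA", 5, 1), mkRoleObs("tumorRNA", 6, 6)))
    expect_true(readSupportFilter(mkCallAt(colRna, "RNA_Rescue"),
                                  colRna)$passed)
    expect_false(readSupportFilter(mkCallAt(colRna, "DNA_only"),
                                   colRna)$passed)
    # a call made by both methods passes if either role passes
    expect_true(readSupportFilter(mkCallAt(colRna, "RNA_Confirmation"),
                                  colRna)$passed)
})

somCall <- function(pos, alt = "T", origin = "DOM") {
    new("VariantCall", chrom = "chr1", pos = as.integer(pos), ref = "A",
        alt = alt, category = "somatic", origin = origin, label = "none",
        summaries = list(), failedFilters = character(0))
}

test_that("merge labels shared, rescue-only and DNA-only calls", {
    dom <- list(somCall(10), somCall(30))
    tbm <- list(somCall(10, origin = "TBM"), somCall(50, origin = "TBM"))
    m <- mergeCalls(dom, tbm)
    expect_length(m, 3)
    labels <- setNames(vapply(m, callLabel, character(1)),
                       vapply(m, function(x) x@pos, integer(1)))
    expect_equal(labels[["10"]], "RNA_Confirmation")
    expect_equal(callOrigin(m[[1]]), "both")
    expect_equal(labels[["30"]], "DNA_only")
    expect_equal(labels[["50"]], "RNA_Rescue")

    # empty rescue path: everything DNA-only
    m2 <- mergeCalls(dom, list())
    expect_true(all(vapply(m2, callLabel, character(1)) == "DNA_only"))

    # commutative in input order, idempotent under re-sorting
    mShuf <- mergeCalls(rev(dom), rev(tbm))
    expect_equal(vapply(mShuf, function(x) paste(x@pos, callLabel(x)),
                        character(1)),
                 vapply(m, function(x) paste(x@pos, callLabel(x)),
                        character(1)))

    # same site, different alt: both kept, conflict reported
    expect_message(m3 <- mergeCalls(list(somCall(10, "T")),
                                    list(somCall(10, "G", "TBM"))),
                   "conflict")
    expect_length(m3, 2)
})

test_that("integer VAF percentages round half away from zero", {
    expect_equal(formatVafPercent(20, 40), 50L)
    expect_equal(formatVafPercent(31, 34), 91L)
    expect_equal(formatVafPercent(4, 64), 6L)
    expect_equal(formatVafPercent(6, 10), 60L)
    expect_equal(formatVafPercent(0, 10), 0L)
    expect_equal(formatVafPercent(1, 8), 13L)   # 12.5 rounds up
    expect_error(formatVafPercent(1, 0), "positive")
})

test_that("VCF output is 1-based, declared, and round-trips", {
    col <- mkTriplet(normal = c(30, 0), tumorDna = c(18, 12),
                     tumorRna = c(12, 8), baseQual = 25, pos = 99L)
    dom <- domEvaluate(col); tbm <- tbmEvaluate(col)
    calls <- mergeCalls(list(dom), list(tbm))
    tmp <- tempfile(fileext = ".vcf")
    writeVCF(calls, tmp)
    lines <- readLines(tmp)
    dataLines <- grep("^#", lines, invert = TRUE, value = TRUE)
    expect_length(dataLines, 1)
    f <- strsplit(dataLines, "\t")[[1]]
    expect_equal(f[2], "100")          # internal 99 -> VCF 100
    expect_equal(f[7], "PASS")
    expect_match(f[8], "LABEL=RNA_Confirmation")

    # zero calls: header-only file
    tmp2 <- tempfile(fileext = ".vcf")
    writeVCF(list(), tmp2)
    expect_true(all(grepl("^#", readLines(tmp2))))

    # byte-identical across reruns
    tmp3 <- tempfile(fileext = ".vcf")
    writeVCF(calls, tmp3)
    expect_identical(readLines(tmp), readLines(tmp3))

    skip_if_not_installed("VariantAnnotation")
    vcf <- VariantAnnotation::readVcf(tmp, genome = "test")
    rr <- SummarizedExperiment::rowRanges(vcf)
    expect_equal(as.character(GenomicRanges::seqnames(rr)), "chr1")
    expect_equal(GenomicRanges::start(rr), 100L)
    expect_equal(as.character(rr$REF), "A")
    expect_equal(as.character(unlist(rr$ALT)), "T")
    expect_equal(as.character(VariantAnnotation::info(vcf)$LABEL),
                 "RNA_Confirmation")
})

test_that("rejection accounting attributes each candidate once", {
    set.seed(61)
    cols <- replicate(60, generateColumn(randomColumnSpec()),
                      simplify = FALSE)
    res <- runCall(cols)
    rep <- res$report
    for (method in c("DOM", "TBM")) {
        calls <- res[[paste0(tolower(substr(method, 1, 1)),
                             tolower(substr(method, 2, 3)), "Calls")]]
        nFailed <- sum(!vapply(calls, callPassed, logical(1)))
        expect_equal(sum(rep$count[rep$method == method]), nFailed)
    }
    # a candidate failing several filters appears once, under the first
    col <- mkPair(normal = c(29, 1), tumorDna = c(6, 3), baseQual = 25)
    v <- domEvaluate(col, keepFailed = TRUE)
    expect_gt(length(v@failedFilters), 1)
    r1 <- filterReport(list(DOM = list(v)))
    expect_equal(sum(r1$count), 1L)
    expect_equal(r1$filter, v@failedFilters[1])
    # all passing: empty table
    expect_equal(nrow(filterReport(list(DOM = list()))), 0L)
})
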