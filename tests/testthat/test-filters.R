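test_that("threshold sets reproduce the somatic tumor support row", {
    row <- thresholdSet(minTotalDepth = 10, minAltDepth = 4,
                        minAltFraction = 0.10, minAvgAltBaseQual = 20,
                        maxAltStrandFraction = 0.90,
                        maxOtherFraction = 0.02)
    s <- mkSummary(depth = 10, altDepth = 4, avgAltBaseQuality = 25,
                   altForwardFraction = 0.5)
    expect_true(applyThresholds(s, row)$passed)

    s9 <- mkSummary(depth = 9, altDepth = 4, avgAltBaseQuality = 25)
    v <- applyThresholds(s9, row, prefix = "somaticTumor")
    expect_false(v$passed)
    expect_equal(v$failedFilters, "somaticTumor.minTotalDepth")

    # an empty set constrains nothing
    expect_true(applyThresholds(mkSummary(3, 1, NA), thresholdSet())$passed)
})

test_that("threshold verdicts equal an independent predicate conjunction", {
    set.seed(23)
    row <- thresholdSet(minTotalDepth = 10, minAltDepth = 4,
                        minAltFraction = 0.10, minAvgAltBaseQual = 17,
                        maxAltStrandFraction = 0.90, maxAltFraction = 0.45,
                        maxOtherFraction = 0.02)
    for (i in 1:10000) {
        d <- sample(0:30, 1)
        a <- if (d > 0) sample(0:d, 1) else 0
        o <- if (d - a > 0) sample(0:(d - a), 1) else 0
        fwd <- if (a > 0) sample(0:a, 1) / a else NA_real_
        baq <- if (a > 0) sample(5:40, 1) else NA_real_
        s <- mkSummary(d, a, baq, altForwardFraction = fwd, otherCount = o)

        altFrac <- if (d > 0) a / d else 0
        othFrac <- if (d > 0) o / d else 0
        want <- d >= 10 && a >= 4 && altFrac >= 0.10 &&
            (!is.na(baq) && baq >= 17) &&
            !(a >= 4 && !is.na(fwd) && max(fwd, 1 - fwd) > 0.90) &&
            altFrac <= 0.45 && othFrac <= 0.02
        expect_identical(applyThresholds(s, row)$passed, want)
    }
})

test_that("strand bias needs four alt reads and a strict 90% majority", {
    # 4 alt reads all forward: 1.0 > 0.90 fails
    expect_false(strandBiasFilter(mkSummary(20, 4,
                                            altForwardFraction = 1))$passed)
    # 3 alt reads all forward: below the guard, not applied
    expect_true(strandBiasFilter(mkSummary(20, 3,
                                           altForwardFraction = 1))$passed)
    # 9 of 10 forward is exactly 0.90: passes (strict inequality)
    expect_true(strandBiasFilter(mkSummary(20, 10,
                                           altForwardFraction = 0.9))$passed)
    # symmetric on the reverse strand
    expect_false(strandBiasFilter(mkSummary(20, 10,
                                            altForwardFraction = 0.05))$passed)
    # strand-flip symmetry on random summaries
    set.seed(3)
    for (i in 1:50) {
        a <- sample(1:20, 1)
        f <- sample(0:a, 1) / a
        expect_equal(strandBiasFilter(mkSummary(30, a, altForwardFraction = f))$passed,
                     strandBiasFilter(mkSummary(30, a, altForwardFraction = 1 - f))$passed)
    }
})

test_that("positional bias fails at 95% of alt reads in an outer third", {
    atOffset <- function(offs, len = 100L)
        readObservations(base = "T", baseQual = 30, mapQual = 40,
                         offsetInRead = offs, readLength = len)
    # 19 of 20 at the read start: 0.95 >= 0.95 fails
    obs <- atOffset(c(rep(5L, 19), 50L))
    expect_false(positionalBiasFilter(obs)$passed)
    # all in the middle third passes
    expect_true(positionalBiasFilter(atOffset(rep(45L, 20)))$passed)
    # 94 of 100 at the start: 0.94 < 0.95 passes
    expect_true(positionalBiasFilter(atOffset(c(rep(2L, 94),
                                                rep(50L, 6))))$passed)
    # end-of-read bias fails too (offset/length >= 2/3)
    expect_false(positionalBiasFilter(atOffset(c(rep(70L, 19), 50L)))$passed)
    # no alt observations: trivially passes
    expect_true(positionalBiasFilter(atOffset(5L)[0, , drop = FALSE])$passed)

    # invariant under permutation and uniform read-length scaling
    set.seed(9)
    offs <- sample(0:99, 25, replace = TRUE)
    base <- positionalBiasFilter(atOffset(offs))$passed
    expect_equal(positionalBiasFilter(atOffset(sample(offs)))$passed, base)
    expect_equal(positionalBiasFilter(atOffset(offs * 3L, len = 300L))$passed,
                 base)
})

test_that("remap check drops reads that align better elsewhere", {
    home <- "ACGTACGTACGTACGTACGTGGCCTTAAGGCCTTAAGGCC"
    paralog <- home
    substr(paralog, 25, 30) <- "CAGTAC"   # diverged window
    ref <- Biostrings::DNAStringSet(c(home = home, paralog = paralog))
    aligner <- pairwiseRemapAligner(ref)

    goodRead <- substr(home, 15, 34)      # unique to home
    badRead <- substr(paralog, 15, 34)    # scores higher at the paralog
    mkAltObs <- function(seqs)
        readObservations(base = "T", baseQual = 30, mapQual = 40,
                         readSeq = seqs, readLength = nchar(seqs[1]),
                         offsetInRead = 10L)

    # 3 of 5 reads survive < 4 required
    obs <- mkAltObs(c(goodRead, goodRead, goodRead, badRead, badRead))
    expect_false(remapCheck(obs, "home", aligner, totalDepth = 20)$passed)
    # all unique to the locus
    obs2 <- mkAltObs(rep(goodRead, 5))
    expect_true(remapCheck(obs2, "home", aligner, totalDepth = 20)$passed)
    # 4 survivors out of 50 total: 0.08 < 0.10
    obs3 <- mkAltObs(rep(goodRead, 4))
    expect_false(remapCheck(obs3, "home", aligner, totalDepth = 50)$passed)
    # a missing read sequence counts as rejected
    obs4 <- mkAltObs(c(rep(goodRead, 3), NA))
    expect_warning(v <- remapCheck(obs4, "home", aligner, totalDepth = 10),
                   "no sequence")
    expect_false(v$passed)
})
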