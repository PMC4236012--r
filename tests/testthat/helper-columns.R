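# Observation/column builders shared across the suite.

mkRoleObs <- function(role, nRef, nAlt, ref = "A", alt = "T", baseQual = 30,
                      mapQual = 40, strand = NULL, offset = 50L,
                      readLength = 100L, properlyPaired = TRUE,
                      mismatchCount = 0L, hasIndel = FALSE,
                      flankQuals = paste(rep(30, 10), collapse = ","),
                      altStrand = NULL) {
    n <- nRef + nAlt
    if (is.null(strand))
        strand <- rep(c("+", "-"), length.out = n)
    if (!is.null(altStrand) && nAlt > 0)
        strand[nRef + seq_len(nAlt)] <- rep(altStrand, length.out = nAlt)
    readObservations(
        readId = sprintf("%s_%03d", role, seq_len(n)),
        base = c(rep(ref, nRef), rep(alt, nAlt)),
        baseQual = baseQual, mapQual = mapQual, strand = strand,
        offsetInRead = offset, readLength = readLength,
        properlyPaired = properlyPaired, mismatchCount = mismatchCount,
        hasIndel = hasIndel, flankQuals = flankQuals, sampleRole = role)
}

# triplet column: counts are c(ref, alt) per role
mkTriplet <- function(normal = c(20, 0), tumorDna = c(20, 8),
                      tumorRna = c(20, 8), ref = "A", alt = "T",
                      pos = 100L, chrom = "chr1", ...) {
    obs <- rbind(
        mkRoleObs("normalDNA", normal[1], normal[2], ref, alt, ...),
        mkRoleObs("tumorDNA", tumorDna[1], tumorDna[2], ref, alt, ...),
        mkRoleObs("tumorRNA", tumorRna[1], tumorRna[2], ref, alt, ...))
    PileupColumn(chrom, pos, ref, obs)
}

# pair column (no RNA)
mkPair <- function(normal = c(20, 0), tumorDna = c(20, 8), ref = "A",
                   alt = "T", pos = 100L, chrom = "chr1", ...) {
    obs <- rbind(
        mkRoleObs("normalDNA", normal[1], normal[2], ref, alt, ...),
        mkRoleObs("tumorDNA", tumorDna[1], tumorDna[2], ref, alt, ...))
    PileupColumn(chrom, pos, ref, obs)
}

mkSummary <- function(depth, altDepth, avgAltBaseQuality = 30,
                      avgMapQuality = 40, altForwardFraction = 0.5,
                      otherCount = 0, altAllele = "T") {
    new("AlleleSummary", depth = as.integer(depth),
        altAllele = altAllele, altDepth = as.integer(altDepth),
        altFraction = if (depth > 0) altDepth / depth else 0,
        avgAltBaseQuality = as.numeric(avgAltBaseQuality),
        avgMapQuality = as.numeric(avgMapQuality),
        altForwardFraction = as.numeric(altForwardFraction),
        otherFraction = if (depth > 0) otherCount / depth else 0)
}

randomColumnSpec <- function() {
    vaf <- sample(seq(0, 0.5, by = 0.05), 2, replace = TRUE)
    synthColumnSpec(
        depth = c(normalDNA = sample(5:40, 1), tumorDNA = sample(5:40, 1),
                  tumorRNA = sample(5:40, 1)),
        trueVaf = c(normalDNA = sample(c(0, 0, 0.02, 0.4), 1),
                    tumorDNA = vaf[1], tumorRNA = vaf[2]),
        strandBalance = sample(c(0.5, 0.95, 1), 1),
        baseQualMean = sample(c(12, 20, 30), 1),
        positionalBias = sample(c("none", "none", "start", "end"), 1))
}
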