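#' VAF samplers for the spike-in simulator
#'
#' Small constructors for the target-VAF distributions used when spiking
#' mutations in: a constant value, a uniform range, or a "capped" uniform
#' draw below a ceiling (the low-DNA-support regime).
#'
#' @param value,min,max,cap VAF values in [0, 1].
#' @return A function \code{(n) -> numeric} drawing n target VAFs.
#' @export
vafConstant <- function(value) {
    stopifnot(value >= 0, value <= 1)
    function(n) rep(value, n)
}

#' @rdname vafConstant
#' @export
vafUniform <- function(min = 0.01, max = 0.50) {
    stopifnot(min >= 0, max <= 1, min <= max)
    function(n) runif(n, min, max)
}

#' @rdname vafConstant
#' @export
vafBelow <- function(cap = 0.10, min = 0.01) {
    stopifnot(min >= 0, cap <= 1, min <= cap)
    function(n) runif(n, min, cap)
}

#' Specification of a spike-in experiment
#'
#' Defaults mirror the variable-DNA / constant-RNA experiment: DNA target
#' VAFs uniform over 1--50\%, RNA held at 25\%, and sites required to carry
#' at least 10 reads of depth in both tumor samples. For the
#' low-DNA/variable-RNA experiment use
#' \code{dnaVafSampler = vafBelow(0.10)} and
#' \code{rnaVafSampler = vafUniform(0.01, 0.50)}.
#'
#' @param dnaVafSampler,rnaVafSampler VAF samplers (see
#'   \code{\link{vafConstant}}).
#' @param minDnaDepth,minRnaDepth minimum tumor DNA/RNA depth for a site to
#'   be eligible.
#' @param seed RNG seed making locus selection and read choice reproducible.
#' @return A named list of class \code{SpikeInSpec}.
#' @export
spikeInSpec <- function(dnaVafSampler = vafUniform(0.01, 0.50),
                        rnaVafSampler = vafConstant(0.25),
                        minDnaDepth = 10L, minRnaDepth = 10L, seed = 1L) {
    structure(list(dnaVafSampler = dnaVafSampler,
                   rnaVafSampler = rnaVafSampler,
                   minDnaDepth = as.integer(minDnaDepth),
                   minRnaDepth = as.integer(minRnaDepth),
                   seed = as.integer(seed)),
              class = "SpikeInSpec")
}

isRefHomozygous <- function(column) {
    obs <- column@observations
    all(obs$base %in% c(columnRef(column), "N"))
}

#' Select spike-in loci
#'
#' Eligible loci are reference-homozygous in every sample role and carry at
#' least the required tumor DNA and RNA depths. \code{n} of them are chosen
#' reproducibly under the spec's seed; when fewer than \code{n} are eligible
#' all of them are returned with a warning.
#'
#' @param columns list of \code{\link{PileupColumn-class}}.
#' @param spec a \code{\link{spikeInSpec}}.
#' @param n number of loci to pick.
#' @return Integer indices into \code{columns}.
#' @export
selectSpikeLoci <- function(columns, spec, n) {
    eligible <- which(vapply(columns, function(col) {
        isRefHomozygous(col) &&
            nrow(roleObservations(col, "tumorDNA")) >= spec$minDnaDepth &&
            nrow(roleObservations(col, "tumorRNA")) >= spec$minRnaDepth
    }, logical(1)))
    if (length(eligible) < n) {
        warning("only ", length(eligible), " of the requested ", n,
                " spike-in loci are eligible; using all of them")
        return(eligible)
    }
    set.seed(spec$seed)
    sort(sample(eligible, n))
}

#' Spike a mutation into one sample at one column
#'
#' Picks \code{k = round(targetVaf * depth)} reads of the role without
#' replacement (halves round away from zero) and rewrites their base at the
#' locus to \code{alt}, preserving base qualities; the read sequence, when
#' present, is edited at the same offset. A target that rounds to zero reads
#' cannot be represented and is skipped with a report. Reads are edited in
#' place — no re-mapping is performed; a re-mapping hook can be layered on
#' top when operating on real alignments.
#'
#' Uses the current RNG state: seed the session (or rely on
#' \code{\link{runSpikein}}, which seeds from the spec) for reproducibility.
#'
#' @param column a reference-homozygous \code{\link{PileupColumn-class}}.
#' @param role sample role to edit.
#' @param alt the alternative base to introduce.
#' @param targetVaf desired variant allele fraction.
#' @return A list: \code{column} (modified), \code{achievedVaf}
#'   (\code{k/depth}, \code{NA} when skipped), \code{alteredReadIds},
#'   \code{skipped}.
#' @export
spikeMutation <- function(column, role, alt, targetVaf) {
    stopifnot(alt %in% c("A", "C", "G", "T"), alt != columnRef(column))
    idx <- which(column@observations$sampleRole == role)
    depth <- length(idx)
    k <- as.integer(floor(targetVaf * depth + 0.5))
    if (k == 0L || depth == 0L)
        return(list(column = column, achievedVaf = NA_real_,
                    alteredReadIds = character(0), skipped = TRUE))
    pick <- idx[sample.int(depth, k)]
    obs <- column@observations
    obs$base[pick] <- alt
    hasSeq <- !is.na(obs$readSeq[pick])
    if (any(hasSeq)) {
        for (i in pick[hasSeq]) {
            off <- obs$offsetInRead[i] + 1L
            substr(obs$readSeq[i], off, off) <- alt
        }
    }
    column@observations <- obs
    list(column = column, achievedVaf = k / depth,
         alteredReadIds = sort(obs$readId[pick]), skipped = FALSE)
}

#' Write spike-in truth records
#'
#' @param records a \code{data.frame} of truth rows (as produced by
#'   \code{\link{runSpikein}}): chrom, pos1, ref, alt, role, targetVaf,
#'   achievedVaf, alteredReadIds.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(records, path) {
    cols <- c("chrom", "pos1", "ref", "alt", "role", "targetVaf",
              "achievedVaf", "alteredReadIds")
    if (nrow(records) == 0L)
        records <- as.data.frame(setNames(
            replicate(length(cols), character(0), simplify = FALSE), cols))
    write.table(records[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Run a spike-in experiment over pileup columns
#'
#' Selects eligible loci, draws one target VAF per locus for the tumor DNA
#' and one for the tumor RNA, and introduces the same alternative base into
#' both roles at each locus. Everything is reproducible under the spec's
#' seed; non-spiked columns are returned untouched.
#'
#' @param columns list of \code{\link{PileupColumn-class}}.
#' @param spec a \code{\link{spikeInSpec}}.
#' @param n number of loci to spike.
#' @param truthPath optional path; when given the truth table is written
#'   there with \code{\link{writeTruth}}.
#' @return A list: \code{columns} (modified list), \code{truth}
#'   (\code{data.frame}, two rows per spiked locus, one per role).
#' @export
runSpikein <- function(columns, spec = spikeInSpec(), n, truthPath = NULL) {
    loci <- selectSpikeLoci(columns, spec, n)
    set.seed(spec$seed + 1L)
    dnaV <- spec$dnaVafSampler(length(loci))
    rnaV <- spec$rnaVafSampler(length(loci))
    truth <- list()
    for (j in seq_along(loci)) {
        i <- loci[j]
        col <- columns[[i]]
        ref <- columnRef(col)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        for (role in c("tumorDNA", "tumorRNA")) {
            tv <- if (role == "tumorDNA") dnaV[j] else rnaV[j]
            res <- spikeMutation(col, role, alt, tv)
            col <- res$column
            truth[[length(truth) + 1L]] <- data.frame(
                chrom = columnChrom(col), pos1 = columnPos(col) + 1L,
                ref = ref, alt = alt, role = role, targetVaf = tv,
                achievedVaf = res$achievedVaf,
                alteredReadIds = paste(res$alteredReadIds, collapse = ","),
                skipped = res$skipped, stringsAsFactors = FALSE)
        }
        columns[[i]] <- col
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth))
        truth <- data.frame(chrom = character(0), pos1 = integer(0),
                            ref = character(0), alt = character(0),
                            role = character(0), targetVaf = numeric(0),
                            achievedVaf = numeric(0),
                            alteredReadIds = character(0),
                            skipped = logical(0), stringsAsFactors = FALSE)
    if (!is.null(truthPath))
        writeTruth(truth, truthPath)
    list(columns = columns, truth = truth)
}
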