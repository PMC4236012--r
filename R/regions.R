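#' Named collection of genomic intervals or positions
#'
#' Backs the annotation filters: the accessible-genome blacklist, pseudogene
#' and gene-family intervals (interval mode) and dbSNP/COSMIC-style position
#' lists (position mode). Chromosome names are normalized by stripping a
#' leading \code{"chr"} so mixed naming conventions across input files still
#' match.
#'
#' @slot name filter-role name (e.g. \code{"blacklist"}).
#' @slot mode \code{"interval"} or \code{"position"}.
#' @slot ranges a \code{GenomicRanges::GRanges}; width-1 ranges in position
#'   mode. Stored 1-based (GRanges convention); constructors convert.
#' @export
setClass("RegionSet",
    representation(name = "character", mode = "character",
                   ranges = "GRanges"),
    validity = function(object) {
        if (!(object@mode %in% c("interval", "position")))
            return("mode must be 'interval' or 'position'")
        if (object@mode == "position" &&
            length(object@ranges) &&
            any(GenomicRanges::width(object@ranges) != 1L))
            return("position-mode RegionSet must have width-1 ranges")
        TRUE
    })

setMethod("show", "RegionSet", function(object) {
    cat(sprintf("RegionSet '%s' (%s mode, %d %s)\n", object@name,
                object@mode, length(object@ranges),
                if (object@mode == "interval") "intervals" else "positions"))
})

normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Load a BED file of filter intervals
#'
#' BED intervals are 0-based half-open; they are stored internally as a
#' 1-based \code{GRanges} with overlapping input intervals merged.
#'
#' @param path BED3+ file path.
#' @param name filter-role name attached to the set.
#' @return An interval-mode \code{\link{RegionSet-class}}.
#' @export
loadBED <- function(path, name = basename(path)) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    raw <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                               colClasses = "character", comment.char = "#",
                               quote = ""),
                    error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0L) {
        gr <- GenomicRanges::GRanges()
    } else {
        start0 <- suppressWarnings(as.numeric(raw[[2]]))
        end0 <- suppressWarnings(as.numeric(raw[[3]]))
        bad <- which(is.na(start0) | is.na(end0) | start0 >= end0 |
                     start0 < 0)
        if (length(bad))
            stop("invalid BED interval at line ", bad[1], " of ", path)
        gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
            normChrom(raw[[1]]),
            IRanges::IRanges(start = start0 + 1, end = end0)))
    }
    new("RegionSet", name = name, mode = "interval", ranges = gr)
}

#' Load a two-column chromosome/position list
#'
#' The text format carries one position per line: chromosome, then 1-based
#' position, whitespace-separated (dbSNP- and COSMIC-style site lists).
#'
#' @param path file path.
#' @param name filter-role name attached to the set.
#' @return A position-mode \code{\link{RegionSet-class}}.
#' @export
loadPositionList <- function(path, name = basename(path)) {
    if (!file.exists(path)) stop("position file not found: ", path)
    raw <- tryCatch(read.table(path, header = FALSE,
                               colClasses = "character", comment.char = "#"),
                    error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0L) {
        gr <- GenomicRanges::GRanges()
    } else {
        pos <- suppressWarnings(as.numeric(raw[[2]]))
        bad <- which(is.na(pos) | pos < 1)
        if (length(bad))
            stop("invalid position at line ", bad[1], " of ", path)
        gr <- unique(GenomicRanges::GRanges(
            normChrom(raw[[1]]), IRanges::IRanges(start = pos, width = 1)))
    }
    new("RegionSet", name = name, mode = "position", ranges = gr)
}

#' Build a RegionSet in code
#'
#' @param chrom chromosome names.
#' @param start0 0-based starts (interval mode) or 0-based positions
#'   (position mode).
#' @param end0 0-based half-open ends (interval mode only).
#' @param name filter-role name.
#' @param mode \code{"interval"} or \code{"position"}.
#' @return A \code{\link{RegionSet-class}}.
#' @export
regionSet <- function(chrom = character(0), start0 = integer(0),
                      end0 = integer(0), name = "regions",
                      mode = c("interval", "position")) {
    mode <- match.arg(mode)
    if (mode == "interval") {
        gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
            normChrom(chrom),
            IRanges::IRanges(start = start0 + 1, end = end0)))
    } else {
        gr <- unique(GenomicRanges::GRanges(
            normChrom(chrom), IRanges::IRanges(start = start0 + 1,
                                               width = 1)))
    }
    new("RegionSet", name = name, mode = mode, ranges = gr)
}

#' Does a set contain a position?
#'
#' @param set a \code{\link{RegionSet-class}} (or \code{NULL}, which never
#'   contains anything — absent annotation files disable their filter).
#' @param chrom chromosome name (with or without \code{"chr"} prefix).
#' @param pos 0-based position.
#' @return \code{TRUE} iff the position falls inside a stored interval
#'   (half-open semantics) or equals a stored position.
#' @export
containsPos <- function(set, chrom, pos) {
    if (is.null(set) || length(set@ranges) == 0L) return(FALSE)
    chrom <- normChrom(chrom)
    if (!chrom %in% GenomeInfoDb::seqlevels(set@ranges))
        return(FALSE)
    q <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start = pos + 1, width = 1))
    length(suppressWarnings(
        GenomicRanges::findOverlaps(q, set@ranges))) > 0L
}
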