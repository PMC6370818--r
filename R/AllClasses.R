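#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' CpGDyads: paired strand-resolved CpG measurements
#'
#' A \code{CpGDyads} object holds one CpG dyad per range: the plus-strand
#' cytosine at \code{start()} and the complementary minus-strand cytosine at
#' \code{start() + 1}. Each dyad carries the percent methylation level and the
#' read depth observed on each strand; the per-site Absolute Methylation
#' Difference (AMD) is \code{|plus_level - minus_level|} and is exposed by
#' \code{\link{siteAMD}}.
#'
#' The class extends \code{\link[GenomicRanges]{GRanges}} (each range has
#' width 2, covering both cytosines of the dyad), so all range machinery
#' (subsetting, \code{findOverlaps}, \code{seqnames}) applies.
#'
#' @slot elementMetadata required columns \code{plus_level},
#'   \code{minus_level} (percent, in [0,100]) and \code{plus_depth},
#'   \code{minus_depth} (non-negative read counts).
#'
#' @seealso \code{\link{pairDyads}} to build dyads from per-strand calls,
#'   \code{\link{siteAMD}}, \code{\link{geneProfiles}}.
#' @export
setClass("CpGDyads", contains = "GRanges")

.validCpGDyads <- function(object) {
    msg <- character()
    need <- c("plus_level", "minus_level", "plus_depth", "minus_depth")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    if (length(object)) {
        w <- GenomicRanges::width(object)
        if (any(w != 2L))
            msg <- c(msg, "every dyad range must have width 2 (plus C and minus C)")
        lv <- c(object$plus_level, object$minus_level)
        if (any(!is.finite(lv)) || any(lv < 0) || any(lv > 100))
            msg <- c(msg, "methylation levels must be finite and in [0, 100]")
        dp <- c(object$plus_depth, object$minus_depth)
        if (any(dp < 0))
            msg <- c(msg, "depths must be non-negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("CpGDyads", .validCpGDyads)

#' Construct a CpGDyads object
#'
#' @param chrom character vector of sequence names.
#' @param plus_pos 1-based position of the plus-strand cytosine; the
#'   minus-strand cytosine sits at \code{plus_pos + 1}.
#' @param plus_level,minus_level percent methylation per strand, in [0,100].
#' @param plus_depth,minus_depth read depth per strand.
#' @return A \code{\linkS4class{CpGDyads}} object.
#' @examples
#' CpGDyads("chr1", 100L, plus_level = 80, minus_level = 30,
#'          plus_depth = 10L, minus_depth = 10L)
#' @export
CpGDyads <- function(chrom = character(), plus_pos = integer(),
                     plus_level = numeric(), minus_level = numeric(),
                     plus_depth = integer(), minus_depth = integer()) {
    gr <- GRanges(chrom, IRanges(start = as.integer(plus_pos), width = 2L))
    mcols(gr) <- DataFrame(plus_level = as.numeric(plus_level),
                           minus_level = as.numeric(minus_level),
                           plus_depth = as.integer(plus_depth),
                           minus_depth = as.integer(minus_depth))
    new("CpGDyads", gr)
}

#' TheoreticalAMDNull: sampling-only expectation of the AMD
#'
#' Tabulates, for every (methylation bin, plus depth, minus depth) cell
#' observed in a sample, the exact expectation of the absolute difference
#' between two independent binomial methylation measurements -- the AMD that
#' finite sequencing depth produces even when no dyad is hemi-methylated.
#' The weight-summed expectation is the sample's aggregate theoretical AMD.
#'
#' @slot table data.frame with columns \code{bin} (bin label), \code{p}
#'   (bin representative proportion), \code{n1}, \code{n2} (per-strand
#'   depths), \code{weight} (fraction of dyads in the cell) and
#'   \code{expectation} (percent).
#' @slot aggregate numeric(1), the weight-summed expectation (percent).
#' @slot nSites integer(1), number of dyads the table was built from.
#'
#' @seealso \code{\link{theoreticalSiteNull}}, \code{\link{amdExcess}}.
#' @export
setClass("TheoreticalAMDNull",
    representation(table = "data.frame", aggregate = "numeric",
                   nSites = "integer"))

.validNull <- function(object) {
    msg <- character()
    tab <- object@table
    need <- c("bin", "p", "n1", "n2", "weight", "expectation")
    if (!all(need %in% names(tab)))
        return(paste("null table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tab)) {
        if (abs(sum(tab$weight) - 1) > 1e-8)
            msg <- c(msg, "cell weights must sum to 1")
        if (any(tab$expectation < 0 | tab$expectation > 100))
            msg <- c(msg, "expectations must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
}
setValidity("TheoreticalAMDNull", .validNull)
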