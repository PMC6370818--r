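#' Per-site Absolute Methylation Difference
#'
#' The AMD of a dyad is the absolute difference between the plus- and
#' minus-strand percent methylation levels; it is the hemi-methylation
#' enrichment statistic at single-CpG resolution.
#'
#' @param x a \code{\linkS4class{CpGDyads}} object.
#' @return numeric vector of AMDs in [0, 100], one per dyad.
#' @examples
#' d <- CpGDyads("chr1", c(100L, 300L), c(80, 100), c(30, 0),
#'               c(10L, 5L), c(10L, 5L))
#' siteAMD(d)   # 50, 100
#' @export
setGeneric("siteAMD", function(x) standardGeneric("siteAMD"))

#' @rdname siteAMD
#' @export
setMethod("siteAMD", "CpGDyads", function(x)
    abs(x$plus_level - x$minus_level))

#' Strand-level accessors for CpGDyads
#'
#' @param x a \code{\linkS4class{CpGDyads}} object.
#' @return numeric (levels, percent) or integer (depths) vector.
#' @name dyad-accessors
NULL

#' @rdname dyad-accessors
#' @export
setGeneric("plusLevel", function(x) standardGeneric("plusLevel"))
#' @rdname dyad-accessors
#' @export
setMethod("plusLevel", "CpGDyads", function(x) x$plus_level)
#' @rdname dyad-accessors
#' @export
setGeneric("minusLevel", function(x) standardGeneric("minusLevel"))
#' @rdname dyad-accessors
#' @export
setMethod("minusLevel", "CpGDyads", function(x) x$minus_level)
#' @rdname dyad-accessors
#' @export
setGeneric("plusDepth", function(x) standardGeneric("plusDepth"))
#' @rdname dyad-accessors
#' @export
setMethod("plusDepth", "CpGDyads", function(x) x$plus_depth)
#' @rdname dyad-accessors
#' @export
setGeneric("minusDepth", function(x) standardGeneric("minusDepth"))
#' @rdname dyad-accessors
#' @export
setMethod("minusDepth", "CpGDyads", function(x) x$minus_depth)

#' Pooled dyad methylation level
#'
#' Mean of the two strand levels: the dyad's methylation ignoring strand.
#' @param x a \code{\linkS4class{CpGDyads}} object.
#' @return numeric vector in [0, 100].
#' @export
setGeneric("dyadLevel", function(x) standardGeneric("dyadLevel"))
#' @rdname dyadLevel
#' @export
setMethod("dyadLevel", "CpGDyads", function(x)
    (x$plus_level + x$minus_level) / 2)

#' @describeIn TheoreticalAMDNull-class the aggregate (weight-summed)
#'   theoretical AMD, percent.
#' @param x a \code{TheoreticalAMDNull}.
#' @export
setGeneric("aggregateNull", function(x) standardGeneric("aggregateNull"))
#' @rdname TheoreticalAMDNull-class
#' @export
setMethod("aggregateNull", "TheoreticalAMDNull", function(x) x@aggregate)

#' @describeIn TheoreticalAMDNull-class the per-(bin, depth-pair) table.
#' @export
setGeneric("nullTable", function(x) standardGeneric("nullTable"))
#' @rdname TheoreticalAMDNull-class
#' @export
setMethod("nullTable", "TheoreticalAMDNull", function(x) x@table)

setMethod("show", "TheoreticalAMDNull", function(object) {
    cat("TheoreticalAMDNull on", object@nSites, "dyads;",
        nrow(object@table), "(bin, depth) cells\n")
    cat(sprintf("aggregate expected AMD: %.4f%%\n", object@aggregate))
})
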