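#' @importFrom stats dbinom rhyper setNames
NULL

#' Exact expectation of the absolute difference of two binomial proportions
#'
#' Computes 100 * E|X/n1 - Y/n2| for independent X ~ Binomial(n1, p) and
#' Y ~ Binomial(n2, p), by exact enumeration of all (n1+1)(n2+1) outcome
#' pairs weighted by the product of the binomial pmfs. This is the AMD a
#' CpG dyad with true methylation p and no hemi-methylation shows from
#' finite sequencing depth alone. No normal approximation is used anywhere:
#' approximation error is exactly the kind of bias the statistic measures.
#'
#' @param n1,n2 per-strand read depths (positive integers).
#' @param p true methylation proportion in [0, 1].
#' @return numeric(1), the expectation in percent. Symmetric in
#'   \code{(n1, n2)} and under \code{p <-> 1 - p}; equals
#'   \code{200 * p * (1 - p)} when \code{n1 == n2 == 1} and 0 when p is
#'   0 or 1.
#' @examples
#' exactAbsMeanDiffExpectation(1, 1, 0.5)       # 50
#' exactAbsMeanDiffExpectation(10, 10, 0.195)   # 13.7377...
#' @export
exactAbsMeanDiffExpectation <- function(n1, n2, p) {
    if (length(n1) != 1L || length(n2) != 1L || length(p) != 1L)
        stop("n1, n2 and p must be scalars")
    if (!is.finite(n1) || !is.finite(n2) || n1 != round(n1) || n2 != round(n2))
        stop("depths must be integers")
    if (n1 < 1 || n2 < 1)
        stop("depths must be >= 1")
    if (!is.finite(p) || p < 0 || p > 1)
        stop("p must lie in [0, 1]")
    if (p == 0 || p == 1)
        return(0)
    ## Exact summation over all (n1+1)(n2+1) outcomes, reorganised with
    ## cumulative sums so the cost is O(n1 + n2) instead of O(n1 n2):
    ## E|c - Y/n2| = c (2 F(k) - 1) - 2 S(k) + E[Y/n2],  k = floor(c n2),
    ## with F the cdf of Y and S(k) = sum_{y <= k} (y/n2) P(Y = y).
    x <- 0:n1
    wx <- dbinom(x, n1, p)
    wy <- dbinom(0:n2, n2, p)
    Fy <- cumsum(wy)
    Sy <- cumsum(wy * (0:n2) / n2)
    cx <- x / n1
    k <- pmin(floor(cx * n2), n2) + 1L          # index into Fy/Sy
    ex <- cx * (2 * Fy[k] - 1) - 2 * Sy[k] + p
    100 * sum(wx * ex)
}

## Vectorised, memoised front end over distinct (n1, n2, p) triples.
.expectationVec <- function(n1, n2, p) {
    key <- paste(pmin(n1, n2), pmax(n1, n2), signif(pmin(p, 1 - p), 12))
    u <- !duplicated(key)
    val <- vapply(which(u), function(i)
        exactAbsMeanDiffExpectation(n1[i], n2[i], p[i]), numeric(1))
    unname(val[match(key, key[u])])
}

#' Map methylation levels to the 102-bin scheme
#'
#' Bins are \{0\}, (0,1], (1,2], ..., (99,100), \{100\}: sites with level
#' exactly 0 or exactly 100 get their own bins (their sampling AMD is
#' exactly zero), interior levels fall into 100 unit-width bins. The bin
#' representative is the interval midpoint, and exactly 0 / 1 for the two
#' point bins.
#'
#' @param level percent methylation in [0, 100].
#' @return data.frame with \code{bin} (character label) and \code{p}
#'   (representative proportion).
#' @export
methylationBins <- function(level) {
    stopifnot(all(level >= 0 & level <= 100))
    k <- ceiling(level)           # (k-1, k] for interior levels
    k[level == 0] <- 0L
    bin <- ifelse(level == 0, "0",
           ifelse(level == 100, "100", sprintf("(%d,%d]", k - 1L, k)))
    p <- ifelse(level == 0, 0,
         ifelse(level == 100, 1, (k - 0.5) / 100))
    data.frame(bin = bin, p = p, stringsAsFactors = FALSE)
}

#' Theoretical site-level AMD null for a sample
#'
#' Assume no hemi-methylation: the two strands are then two independent
#' binomial measurements of one underlying methylation level. Dyads are
#' binned by their pooled level (mean of the strand levels) into the
#' 102-bin scheme; within each bin the observed per-strand depth pairs are
#' tabulated, and each (bin, n1, n2) cell contributes its exact expected
#' absolute difference (\code{\link{exactAbsMeanDiffExpectation}} at the
#' bin representative) weighted by its fraction of dyads. The weight-summed
#' expectation is the sample's aggregate theoretical AMD.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @return A \code{\linkS4class{TheoreticalAMDNull}}.
#' @export
theoreticalSiteNull <- function(dyads) {
    if (!length(dyads))
        stop("no dyads: cannot build a null")
    bins <- methylationBins(dyadLevel(dyads))
    dt <- data.table(bin = bins$bin, p = bins$p,
                     n1 = pmin(dyads$plus_depth, dyads$minus_depth),
                     n2 = pmax(dyads$plus_depth, dyads$minus_depth))
    cells <- dt[, list(count = .N), by = c("bin", "p", "n1", "n2")]
    cells$weight <- cells$count / sum(cells$count)
    cells$expectation <- .expectationVec(cells$n1, cells$n2, cells$p)
    tab <- as.data.frame(cells[, c("bin", "p", "n1", "n2", "weight",
                                   "expectation")])
    new("TheoreticalAMDNull", table = tab,
        aggregate = sum(tab$weight * tab$expectation),
        nSites = length(dyads))
}

#' Per-dyad null expectation of the site AMD
#'
#' The expectation each dyad contributes to the theoretical null: the
#' exact expected absolute difference at the dyad's methylation-bin
#' representative and observed per-strand depths. The per-dyad excess
#' (observed AMD minus this value) is the site-resolution hemi-methylation
#' signal used e.g. to regress against a known truth.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @return numeric vector, one expectation (percent) per dyad.
#' @export
siteNullExpectation <- function(dyads) {
    bins <- methylationBins(dyadLevel(dyads))
    .expectationVec(dyads$plus_depth, dyads$minus_depth, bins$p)
}

#' Theoretical gene-level AMD null
#'
#' A gene's TSS window is treated as one pooled CpG site: its methylation
#' is the window average and its depth the summed depth of all CpGs. The
#' pooled depth is split evenly between two virtual strands (rounded to the
#' nearest integer, floor 1) and the exact expectation evaluated there.
#' Pooling depth shrinks the null sharply relative to single sites.
#'
#' @param profiles data.frame from \code{\link{geneProfiles}} (columns
#'   \code{gene_level}, \code{total_depth}), or a single profile row.
#' @return numeric vector of expected gene AMDs (percent), NA for
#'   unmeasured genes.
#' @export
theoreticalGeneNull <- function(profiles) {
    lev <- profiles$gene_level
    dep <- profiles$total_depth
    out <- rep(NA_real_, length(lev))
    ok <- !is.na(lev) & !is.na(dep)
    if (any(dep[ok] < 2))
        stop("total_depth must be >= 2 to split across two strands")
    n <- pmax(1L, as.integer(round(dep[ok] / 2)))
    out[ok] <- .expectationVec(n, n, lev[ok] / 100)
    out
}

#' Per-gene methylation profiles over TSS windows
#'
#' For each gene, the dyads whose plus-strand cytosine lies inside the
#' gene's TSS window are collected (deduplicated by position), each
#' strand's levels are averaged (unweighted), and the gene AMD is the
#' absolute difference of the two strand means. Averaging before taking
#' the absolute value means site AMDs of opposite orientation cancel: the
#' gene AMD measures coherent strand asymmetry, not per-site noise.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @param genes TSS-window \code{GRanges} from
#'   \code{\link{readGeneAnnotation}} (metadata column \code{gene_id}).
#' @return data.frame with one row per gene: \code{gene_id}, \code{n_cpg},
#'   \code{plus_mean}, \code{minus_mean}, \code{gene_level},
#'   \code{gene_amd}, \code{total_depth}, \code{measured}. Genes with no
#'   covered dyad are flagged \code{measured = FALSE} with NA statistics
#'   (not zero), and are excluded downstream.
#' @export
geneProfiles <- function(dyads, genes) {
    pos <- GRanges(GenomicRanges::seqnames(dyads),
                   IRanges(GenomicRanges::start(dyads), width = 1L))
    hits <- GenomicRanges::findOverlaps(pos, genes, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ## deduplicate by dyad position within each gene
    key <- paste(si, as.character(GenomicRanges::seqnames(dyads))[qi],
                 GenomicRanges::start(dyads)[qi])
    keep <- !duplicated(key)
    qi <- qi[keep]; si <- si[keep]

    dt <- data.table(gene = si,
                     plus = dyads$plus_level[qi],
                     minus = dyads$minus_level[qi],
                     depth = dyads$plus_depth[qi] + dyads$minus_depth[qi])
    agg <- dt[, list(n_cpg = .N, plus_mean = mean(plus),
                     minus_mean = mean(minus),
                     total_depth = sum(depth)), by = "gene"]
    out <- data.frame(gene_id = genes$gene_id,
                      n_cpg = 0L, plus_mean = NA_real_, minus_mean = NA_real_,
                      gene_level = NA_real_, gene_amd = NA_real_,
                      total_depth = NA_real_, measured = FALSE,
                      stringsAsFactors = FALSE)
    out$n_cpg[agg$gene] <- agg$n_cpg
    out$plus_mean[agg$gene] <- agg$plus_mean
    out$minus_mean[agg$gene] <- agg$minus_mean
    out$gene_level[agg$gene] <- (agg$plus_mean + agg$minus_mean) / 2
    out$gene_amd[agg$gene] <- abs(agg$plus_mean - agg$minus_mean)
    out$total_depth[agg$gene] <- agg$total_depth
    out$measured[agg$gene] <- TRUE
    out
}

#' Average AMD tables across samples
#'
#' Entities (sites or genes) present in every sample are kept and their
#' AMDs averaged arithmetically; anything missing from any sample is
#' dropped, mirroring the G1 / G2-M averaging used to represent a cycling
#' population.
#'
#' @param amd_tables list of data.frames, each with columns \code{id} and
#'   \code{amd}.
#' @return data.frame with \code{id} and the across-sample mean \code{amd}.
#' @export
combineSampleAMDs <- function(amd_tables) {
    stopifnot(length(amd_tables) >= 1L)
    ids <- Reduce(intersect, lapply(amd_tables, function(t) t$id))
    if (!length(ids))
        stop("no entities shared across all samples")
    m <- vapply(amd_tables, function(t) t$amd[match(ids, t$id)],
                numeric(length(ids)))
    m <- matrix(m, nrow = length(ids))
    data.frame(id = ids, amd = rowMeans(m), stringsAsFactors = FALSE)
}

#' Observed AMD excess over the sampling null, with a permutation test
#'
#' The aggregate excess is the mean observed site AMD minus the aggregate
#' theoretical AMD. Significance is assessed by reshuffling read-to-strand
#' assignment within each dyad: conditional on a dyad's total methylated
#' reads and per-strand depths, the plus-strand count under the
#' no-hemi-methylation null is exactly hypergeometric, so resampled
#' pseudo-strand AMDs form an exact conditional null for the mean AMD.
#' Genuine strand asymmetry is destroyed by the reshuffle, inflating the
#' observed mean above the permutation distribution.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @param null optional precomputed \code{\linkS4class{TheoreticalAMDNull}};
#'   built from \code{dyads} when missing.
#' @param n_perm number of permutations (default 999).
#' @return list with \code{mean_observed}, \code{null_aggregate},
#'   \code{excess} (percent), \code{p_value} (one-sided, add-one
#'   corrected), \code{n_perm}, and \code{bin_excess}, a per-bin table of
#'   observed vs expected AMD. Randomness comes from the R session RNG:
#'   call \code{set.seed()} for reproducible p-values.
#' @export
amdExcess <- function(dyads, null = theoreticalSiteNull(dyads),
                      n_perm = 999L) {
    amd <- siteAMD(dyads)
    obs <- mean(amd)
    agg <- aggregateNull(null)

    n1 <- dyads$plus_depth
    n2 <- dyads$minus_depth
    meth_total <- round(dyads$plus_level * n1 / 100) +
                  round(dyads$minus_level * n2 / 100)
    nd <- length(dyads)
    perm_means <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
        x1 <- rhyper(nd, meth_total, n1 + n2 - meth_total, n1)
        perm_means[b] <- mean(abs(100 * x1 / n1 -
                                  100 * (meth_total - x1) / n2))
    }
    p <- (1 + sum(perm_means >= obs)) / (n_perm + 1)

    bins <- methylationBins(dyadLevel(dyads))
    obs_bin <- data.table(bin = bins$bin, amd = amd)[
        , list(mean_observed = mean(amd), n = .N), by = "bin"]
    exp_bin <- data.table(nullTable(null))[
        , list(expected = sum(weight * expectation) / sum(weight)), by = "bin"]
    be <- merge(as.data.frame(obs_bin), as.data.frame(exp_bin), by = "bin")
    be$excess <- be$mean_observed - be$expected

    list(mean_observed = obs, null_aggregate = agg, excess = obs - agg,
         p_value = p, n_perm = as.integer(n_perm), bin_excess = be)
}

#' Global methylation fraction from HPLC nucleoside amounts
#'
#' @param dc_amount amount of 2'-deoxycytidine.
#' @param mdc_amount amount of 5-methyl-2'-deoxycytidine.
#' @return percent methylation, 100 * mdc / (dc + mdc).
#' @examples
#' hplcMethylationFraction(80, 20)  # 20
#' @export
hplcMethylationFraction <- function(dc_amount, mdc_amount) {
    if (any(dc_amount < 0) || any(mdc_amount < 0))
        stop("amounts must be non-negative")
    if (any(dc_amount + mdc_amount == 0))
        stop("dC and 5mdC cannot both be zero")
    100 * mdc_amount / (dc_amount + mdc_amount)
}
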