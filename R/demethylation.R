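#' @importFrom stats cor.test phyper wilcox.test runif complete.cases
NULL

#' Build a condition-by-entity methylation matrix
#'
#' @param tables named list of data.frames, one per condition, each with
#'   columns \code{id} and \code{level} (percent). Names are condition
#'   keys, conventionally \code{"system:perturbation"} (e.g.
#'   \code{"MEF:control"}).
#' @return numeric matrix, rows = union of entity ids, columns =
#'   condition keys; unmeasured cells are NA.
#' @export
buildConditionMatrix <- function(tables) {
    stopifnot(length(tables) >= 1L, !is.null(names(tables)))
    ids <- sort(unique(unlist(lapply(tables, function(t) t$id))))
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(tables),
                dimnames = list(ids, names(tables)))
    for (k in names(tables)) {
        t <- tables[[k]]
        m[match(t$id, ids), k] <- t$level
    }
    m
}

.condKey <- function(system, perturbation) paste0(system, ":", perturbation)

#' Per-entity demethylation induced by a perturbation
#'
#' Delta = level(control) - level(perturbed), so positive values are
#' demethylation. Only entities measured in both conditions enter.
#'
#' @param matrix condition matrix from \code{\link{buildConditionMatrix}}.
#' @param system system label (e.g. \code{"MEF"}).
#' @param perturbation perturbation label (e.g. \code{"Tet1"}).
#' @param control control label (default \code{"control"}).
#' @return data.frame with \code{id} and \code{delta} (percentage points);
#'   attribute \code{mean_delta} carries the summary mean.
#' @export
demethylationDelta <- function(matrix, system, perturbation,
                               control = "control") {
    kc <- .condKey(system, control)
    kp <- .condKey(system, perturbation)
    for (k in c(kc, kp))
        if (!k %in% colnames(matrix))
            stop("condition not present in matrix: ", k)
    ok <- complete.cases(matrix[, c(kc, kp), drop = FALSE])
    out <- data.frame(id = rownames(matrix)[ok],
                      delta = matrix[ok, kc] - matrix[ok, kp],
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "mean_delta") <- mean(out$delta)
    out
}

#' Entities demethylated more than average
#'
#' The selection rule behind "demethylated by X": entities whose delta is
#' strictly greater than the mean delta over all measured entities. An
#' absolute-threshold alternative is available via \code{threshold}.
#'
#' @param deltas data.frame with \code{id} and \code{delta}.
#' @param threshold if non-NULL, select \code{delta > threshold}
#'   (percentage points) instead of the above-average rule.
#' @return character vector of selected ids.
#' @examples
#' d <- data.frame(id = c("a", "b", "c"), delta = c(10, 20, 30))
#' selectAboveAverage(d)   # "c" only: the mean (20) is excluded
#' @export
selectAboveAverage <- function(deltas, threshold = NULL) {
    stopifnot(nrow(deltas) > 0L)
    cut <- if (is.null(threshold)) mean(deltas$delta) else threshold
    deltas$id[deltas$delta > cut]
}

#' Overlap statistics between two target sets
#'
#' @param set_a,set_b character vectors of entity ids.
#' @param universe all measurable entities (both sets must be subsets).
#' @return list with \code{frac_a_in_b}, \code{frac_b_in_a} (NA with a
#'   warning when the denominator set is empty), \code{jaccard},
#'   \code{n_overlap} and \code{p_hyper}, the one-sided hypergeometric
#'   p-value for over-representation of the overlap given the universe.
#'   The overlap fractions do not depend on the universe; the
#'   hypergeometric p does.
#' @export
overlapStats <- function(set_a, set_b, universe) {
    set_a <- unique(set_a); set_b <- unique(set_b)
    if (!all(set_a %in% universe) || !all(set_b %in% universe))
        stop("both sets must be subsets of the universe")
    n_ab <- length(intersect(set_a, set_b))
    un <- length(union(set_a, set_b))
    fa <- if (length(set_a)) n_ab / length(set_a) else {
        warning("empty set_a: fraction undefined"); NA_real_ }
    fb <- if (length(set_b)) n_ab / length(set_b) else {
        warning("empty set_b: fraction undefined"); NA_real_ }
    N <- length(unique(universe))
    p <- phyper(n_ab - 1L, length(set_b), N - length(set_b),
                length(set_a), lower.tail = FALSE)
    list(frac_a_in_b = fa, frac_b_in_a = fb,
         jaccard = if (un) n_ab / un else NA_real_,
         n_overlap = n_ab, p_hyper = p)
}

#' Targets shared by every experimental system
#'
#' @param sets list (length >= 2) of id vectors, one per system.
#' @return character vector: the strict intersection.
#' @export
consistentTargets <- function(sets) {
    stopifnot(length(sets) >= 2L)
    Reduce(intersect, sets)
}

#' Correlation between two per-entity change tables
#'
#' @param deltas_a,deltas_b data.frames with \code{id} and a numeric
#'   second column (\code{delta} or \code{log2fc}).
#' @param method \code{"pearson"} (default, matching linear-fit scatter
#'   summaries) or \code{"spearman"}.
#' @return list with \code{estimate}, \code{p_value}, \code{n}; estimate
#'   is NA (flagged via warning) when either vector is constant.
#' @export
deltaCorrelation <- function(deltas_a, deltas_b,
                             method = c("pearson", "spearman")) {
    method <- match.arg(method)
    ids <- intersect(deltas_a$id, deltas_b$id)
    if (length(ids) < 3L)
        stop("need at least 3 shared entities")
    a <- deltas_a[[2]][match(ids, deltas_a$id)]
    b <- deltas_b[[2]][match(ids, deltas_b$id)]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
        warning("constant vector: correlation undefined")
        return(list(estimate = NA_real_, p_value = NA_real_,
                    n = length(ids)))
    }
    ct <- cor.test(a, b, method = method, exact = FALSE)
    list(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = length(ids))
}

#' Demethylation as a function of hemi-methylation enrichment
#'
#' Entities are sorted by AMD (stable, ties broken by id for
#' reproducibility) and split into \code{n_groups} equal-count groups
#' (any remainder spread over the first groups); per-group mean AMD and
#' mean delta are returned in AMD order.
#'
#' @param amds data.frame with \code{id}, \code{amd}.
#' @param deltas data.frame with \code{id}, \code{delta}.
#' @param n_groups number of groups (site analyses conventionally use 14,
#'   gene analyses 20).
#' @return data.frame with \code{group}, \code{n}, \code{mean_amd},
#'   \code{mean_delta}.
#' @export
amdResponseCurve <- function(amds, deltas, n_groups) {
    ids <- intersect(amds$id, deltas$id)
    if (n_groups > length(ids))
        stop("n_groups exceeds the number of shared entities")
    if (n_groups < 2L)
        stop("need at least 2 groups")
    a <- amds$amd[match(ids, amds$id)]
    d <- deltas$delta[match(ids, deltas$id)]
    o <- order(a, ids)
    a <- a[o]; d <- d[o]
    n <- length(ids)
    base <- n %/% n_groups
    sizes <- rep(base, n_groups)
    extra <- n - base * n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    grp <- rep(seq_len(n_groups), times = sizes)
    data.frame(group = seq_len(n_groups), n = sizes,
               mean_amd = as.numeric(tapply(a, grp, mean)),
               mean_delta = as.numeric(tapply(d, grp, mean)))
}

#' Compare the top AMD quantile with the rest
#'
#' @param amds,deltas as in \code{\link{amdResponseCurve}}.
#' @param q top fraction by AMD (default 0.2: top 20\% vs remaining 80\%).
#' @return list with \code{mean_top}, \code{mean_rest},
#'   \code{difference}, \code{p_value} (two-sided Wilcoxon rank-sum),
#'   \code{n_top}, \code{n_rest}.
#' @export
topQuantileComparison <- function(amds, deltas, q = 0.2) {
    stopifnot(q > 0, q < 1)
    ids <- intersect(amds$id, deltas$id)
    a <- amds$amd[match(ids, amds$id)]
    d <- deltas$delta[match(ids, deltas$id)]
    o <- order(a, ids)                 # ascending; top-q is the tail
    n_top <- max(1L, round(q * length(ids)))
    top <- rev(o)[seq_len(n_top)]
    rest <- setdiff(seq_along(ids), top)
    p <- if (length(rest)) wilcox.test(d[top], d[rest])$p.value else NA_real_
    list(mean_top = mean(d[top]), mean_rest = mean(d[rest]),
         difference = mean(d[top]) - mean(d[rest]), p_value = p,
         n_top = length(top), n_rest = length(rest))
}

#' Change in hemi-methylation abundance across conditions
#'
#' Mean AMD per condition over the entities shared by all tables, with
#' pairwise differences against the control and paired sign-flip
#' permutation p-values (within each shared entity, the condition and
#' control AMDs are exchanged with probability 1/2).
#'
#' @param amd_tables named list of data.frames (\code{id}, \code{amd});
#'   one element must be the control.
#' @param control name of the control element (default
#'   \code{"control"}).
#' @param n_perm permutations for the paired test (default 999).
#' @return list with \code{means} (named numeric), \code{differences}
#'   (condition minus control) and \code{p_values} (two-sided).
#' @export
hemiAbundanceChange <- function(amd_tables, control = "control",
                                n_perm = 999L) {
    stopifnot(control %in% names(amd_tables))
    ids <- Reduce(intersect, lapply(amd_tables, function(t) t$id))
    if (!length(ids)) stop("no entities shared across conditions")
    m <- vapply(amd_tables, function(t) t$amd[match(ids, t$id)],
                numeric(length(ids)))
    means <- colMeans(m)
    others <- setdiff(names(amd_tables), control)
    diffs <- means[others] - means[control]
    pvals <- vapply(others, function(k) {
        d <- m[, k] - m[, control]
        obs <- mean(d)
        perm <- vapply(seq_len(n_perm), function(b)
            mean(d * sample(c(-1, 1), length(d), replace = TRUE)),
            numeric(1))
        (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    }, numeric(1))
    list(means = means, differences = diffs, p_values = pvals)
}

#' Select genes by expression change and correlate with demethylation
#'
#' \code{selectByExpressionChange} keeps genes whose |log2 fold change| is
#' strictly above the mean |log2 fold change| of all genes (the
#' expression analogue of \code{\link{selectAboveAverage}}).
#'
#' @param log2fc data.frame with \code{id} and \code{log2fc}.
#' @return character vector of selected gene ids.
#' @export
selectByExpressionChange <- function(log2fc) {
    stopifnot(nrow(log2fc) > 0L)
    a <- abs(log2fc$log2fc)
    log2fc$id[a > mean(a)]
}

#' @rdname selectByExpressionChange
#' @details \code{expressionDeltaCorrelation} correlates per-gene
#'   demethylation with expression change over the shared genes; it is
#'   \code{\link{deltaCorrelation}} applied to a delta table and a log2fc
#'   table and is the per-arm statistic contrasted between active and
#'   passive demethylation.
#' @param deltas data.frame with \code{id}, \code{delta}.
#' @param method correlation method, as in \code{\link{deltaCorrelation}}.
#' @export
expressionDeltaCorrelation <- function(deltas, log2fc,
                                       method = c("pearson", "spearman")) {
    deltaCorrelation(deltas, log2fc, method = match.arg(method))
}

#' Compare two correlations by Fisher's z
#'
#' Used to ask whether the demethylation-expression coupling is stronger
#' in one demethylation arm than another.
#'
#' @param r1,r2 correlation estimates.
#' @param n1,n2 the sample sizes behind them.
#' @return list with \code{z} (positive when r1 > r2) and the one-sided
#'   \code{p_value} for r1 > r2.
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
    stopifnot(n1 > 3, n2 > 3)
    z1 <- atanh(r1); z2 <- atanh(r2)
    z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE))
}
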