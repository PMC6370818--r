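#' @importFrom stats median
NULL

#' Classify genes into promoter CpG-density / methylation zones
#'
#' Zone I collects genes whose TSS window holds a mid-range CpG count
#' (default 42-83 dyads, the density band where hemi-methylation
#' concentrates); Zone II is the subset of Zone I with intermediate
#' methylation (default 40-60\%). All band endpoints are inclusive.
#'
#' @param profiles data.frame from \code{\link{geneProfiles}}.
#' @param cpg_min,cpg_max inclusive CpG-count band for Zone I.
#' @param meth_min,meth_max inclusive methylation band (percent) for
#'   Zone II.
#' @return data.frame with \code{gene_id}, \code{n_cpg},
#'   \code{gene_level} and \code{zone} (factor: none / I / II; unmeasured
#'   genes are \code{none}).
#' @export
classifyZones <- function(profiles, cpg_min = 42L, cpg_max = 83L,
                          meth_min = 40, meth_max = 60) {
    z1 <- profiles$measured & profiles$n_cpg >= cpg_min &
          profiles$n_cpg <= cpg_max
    z2 <- z1 & profiles$gene_level >= meth_min &
          profiles$gene_level <= meth_max
    zone <- ifelse(z2, "II", ifelse(z1, "I", "none"))
    data.frame(gene_id = profiles$gene_id, n_cpg = profiles$n_cpg,
               gene_level = profiles$gene_level,
               zone = factor(zone, levels = c("none", "I", "II")),
               stringsAsFactors = FALSE)
}

#' Hemi-methylation enrichment by inter-CpG distance
#'
#' Each dyad's distance is the gap to its nearest neighbouring dyad on the
#' same chromosome (difference of plus-strand positions). Dyads are
#' cross-tabulated by distance band and pooled-methylation band and each
#' cell's mean AMD reported; hemi-methylation shows up as elevated AMD in
#' particular distance bands (canonically 45-90 bp) and the 20-85\%
#' methylation band.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @param distance_breaks band edges in bp (right-closed); defaults
#'   include the 45 and 90 bp edges.
#' @param meth_breaks methylation band edges (percent); defaults include
#'   the 20-85\% band.
#' @return data.frame with \code{distance_band}, \code{meth_band},
#'   \code{n} and \code{mean_amd}. Chromosomes carrying a single dyad
#'   contribute nothing (distance undefined).
#' @export
interCpGDistanceEnrichment <- function(dyads,
        distance_breaks = c(0, 45, 90, 180, Inf),
        meth_breaks = c(0, 20, 85, 100)) {
    chrom <- as.character(GenomicRanges::seqnames(dyads))
    pos <- GenomicRanges::start(dyads)
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]
    amd <- siteAMD(dyads)[o]
    lev <- dyadLevel(dyads)[o]
    n <- length(pos)
    gap_prev <- c(NA, diff(pos))
    gap_prev[c(TRUE, chrom[-1] != chrom[-n])] <- NA
    gap_next <- c(gap_prev[-1], NA)
    dist <- pmin(gap_prev, gap_next, na.rm = TRUE)
    dist[is.na(gap_prev) & is.na(gap_next)] <- NA
    ok <- !is.na(dist)
    dt <- data.table(
        distance_band = cut(dist[ok], distance_breaks,
                            include.lowest = TRUE),
        meth_band = cut(lev[ok], meth_breaks, include.lowest = TRUE),
        amd = amd[ok])
    agg <- dt[, list(n = .N, mean_amd = mean(amd)),
              by = c("distance_band", "meth_band")]
    as.data.frame(agg[order(agg$distance_band, agg$meth_band)])
}

#' Split genes into high / low hemi-methylation enrichment
#'
#' Genes are first binned by methylation level on the 102-bin scheme so
#' that the split is conditional on methylation; within each bin, genes at
#' or above the bin's median AMD are labelled \code{high}, the rest
#' \code{low}. Odd bins put the median gene in \code{high}; bins with a
#' single constant AMD are all \code{high} (documented tie rule). Bins
#' with fewer than 2 measured genes are left unassigned (NA).
#'
#' @param profiles data.frame from \code{\link{geneProfiles}}.
#' @return data.frame with \code{gene_id}, \code{bin}, \code{enrichment}
#'   (factor low/high, NA when unassigned).
#' @export
splitHighLowEnrichment <- function(profiles) {
    out <- data.frame(gene_id = profiles$gene_id, bin = NA_character_,
                      enrichment = factor(rep(NA_character_,
                                              nrow(profiles)),
                                          levels = c("low", "high")),
                      stringsAsFactors = FALSE)
    meas <- which(profiles$measured)
    if (!length(meas)) return(out)
    bins <- methylationBins(profiles$gene_level[meas])$bin
    out$bin[meas] <- bins
    for (b in unique(bins)) {
        i <- meas[bins == b]
        if (length(i) < 2L) next
        med <- median(profiles$gene_amd[i])
        out$enrichment[i] <- ifelse(profiles$gene_amd[i] >= med,
                                    "high", "low")
    }
    out
}

#' Mean of a per-gene measure along fixed-width methylation bins
#'
#' @param profiles data.frame from \code{\link{geneProfiles}}.
#' @param values data.frame with \code{id} and \code{value} (e.g. a
#'   chromatin accessibility score or expression measure).
#' @param n_bins number of fixed-width bins on gene methylation
#'   (default 20: 0-5\%, ..., 95-100\%).
#' @param min_n bins with fewer genes than this are suppressed
#'   (\code{NA} mean; default 50).
#' @return data.frame with \code{bin} (label), \code{mid} (bin midpoint,
#'   percent), \code{n}, \code{mean_level}, \code{mean_value}.
#' @export
methylationBinCurve <- function(profiles, values, n_bins = 20L,
                                min_n = 50L) {
    p <- profiles[profiles$measured, ]
    v <- values$value[match(p$gene_id, values$id)]
    ok <- !is.na(v)
    p <- p[ok, ]; v <- v[ok]
    edges <- seq(0, 100, length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(p$gene_level, edges,
                                  rightmost.closed = TRUE), 1L), n_bins)
    out <- data.frame(
        bin = sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                      c(rep(")", n_bins - 1L), "]")),
        mid = (edges[-length(edges)] + edges[-1]) / 2,
        n = 0L, mean_level = NA_real_, mean_value = NA_real_)
    for (k in seq_len(n_bins)) {
        i <- idx == k
        out$n[k] <- sum(i)
        if (sum(i) >= min_n) {
            out$mean_level[k] <- mean(p$gene_level[i])
            out$mean_value[k] <- mean(v[i])
        }
    }
    out
}

.default_bands <- list(I = c(0, 10), II = c(30, 40), III = c(30, 40),
                       IV = c(60, 70), V = c(60, 70), VI = c(90, 100))
.low_ratio_groups <- c("I", "II", "IV", "VI")

#' Build active/passive mimic groups from methylation and AMD
#'
#' Six gene groups mimic demethylation end-points: Groups I, II, IV and
#' VI hold genes in the 0-10, 30-40, 60-70 and 90-100\% methylation bands
#' whose AMD/methylation ratio is below \code{ratio_low} (essentially no
#' hemi-methylation: the active-demethylation end-points); Groups III and
#' V hold genes in the 30-40 and 60-70\% bands with ratio above
#' \code{ratio_high} (hemi-rich: the passive end-points). Band endpoints
#' are inclusive; genes with zero methylation are skipped (ratio
#' undefined).
#'
#' @param profiles data.frame from \code{\link{geneProfiles}}.
#' @param bands named list of inclusive \code{c(lo, hi)} methylation
#'   bands for groups I-VI.
#' @param ratio_low,ratio_high AMD/methylation ratio thresholds
#'   (defaults 0.02 and 0.1).
#' @param min_size groups at or below this size are flagged
#'   under-powered (default 100).
#' @return data.frame with one row per group: \code{group},
#'   \code{band_lo}, \code{band_hi}, \code{rule}, \code{n},
#'   \code{mean_level}, \code{mean_amd}, \code{mean_ratio},
#'   \code{underpowered}; attribute \code{members} is a named list of
#'   gene-id vectors.
#' @export
buildMimicGroups <- function(profiles, bands = .default_bands,
                             ratio_low = 0.02, ratio_high = 0.1,
                             min_size = 100L) {
    p <- profiles[profiles$measured & profiles$gene_level > 0, ]
    ratio <- p$gene_amd / p$gene_level
    members <- list()
    rows <- lapply(names(bands), function(g) {
        b <- bands[[g]]
        inband <- p$gene_level >= b[1] & p$gene_level <= b[2]
        low <- g %in% .low_ratio_groups
        sel <- inband & if (low) ratio < ratio_low else ratio > ratio_high
        members[[g]] <<- p$gene_id[sel]
        data.frame(group = g, band_lo = b[1], band_hi = b[2],
                   rule = if (low) sprintf("ratio < %g", ratio_low)
                          else sprintf("ratio > %g", ratio_high),
                   n = sum(sel),
                   mean_level = if (any(sel)) mean(p$gene_level[sel]) else NA_real_,
                   mean_amd = if (any(sel)) mean(p$gene_amd[sel]) else NA_real_,
                   mean_ratio = if (any(sel)) mean(ratio[sel]) else NA_real_,
                   underpowered = sum(sel) <= min_size,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "members") <- members
    out
}

#' Contrast mimic groups on a per-gene measure
#'
#' Orders the demethylation-mimic contrasts: II vs IV and IV vs VI mimic
#' active demethylation of the IV and VI starting points, III vs IV and
#' V vs VI mimic passive demethylation. An "active exceeds passive"
#' summary flags whether the active mimic shows the larger gain at both
#' starting points.
#'
#' @param groups result of \code{\link{buildMimicGroups}}.
#' @param values data.frame with \code{id}, \code{value}.
#' @return list with \code{contrasts} (data.frame: contrast, mean
#'   difference, rank-sum p, flags) and \code{active_gt_passive}
#'   (logical, NA when a needed contrast is missing).
#' @export
mimicComparison <- function(groups, values) {
    members <- attr(groups, "members")
    gmean <- function(g) {
        v <- values$value[match(members[[g]], values$id)]
        v[!is.na(v)]
    }
    pairs <- list(c("II", "IV"), c("III", "IV"), c("IV", "VI"),
                  c("V", "VI"))
    rows <- lapply(pairs, function(pr) {
        a <- gmean(pr[1]); b <- gmean(pr[2])
        if (!length(a) || !length(b))
            return(data.frame(contrast = paste(pr, collapse = " vs "),
                              difference = NA_real_, p_value = NA_real_,
                              skipped = TRUE))
        data.frame(contrast = paste(pr, collapse = " vs "),
                   difference = mean(a) - mean(b),
                   p_value = wilcox.test(a, b)$p.value, skipped = FALSE)
    })
    tab <- do.call(rbind, rows)
    d <- setNames(tab$difference, tab$contrast)
    agp <- if (any(tab$skipped)) NA else
        (d["II vs IV"] > d["III vs IV"]) && (d["IV vs VI"] > d["V vs VI"])
    list(contrasts = tab, active_gt_passive = unname(agp))
}

#' Select genes matched for demethylation across the two arms
#'
#' The three-criterion filter behind the matched (300-gene-style)
#' comparison of active vs passive demethylation products: (1) control
#' methylation within \code{band} (inclusive); (2) demethylation by more
#' than \code{min_drop} percentage points in both perturbations (or
#' either, with \code{both_arms = FALSE}); (3) the two perturbed levels
#' differ by less than \code{max_diff} points and by no more than
#' \code{max_rel} of their mean.
#'
#' @param matrix condition matrix (\code{\link{buildConditionMatrix}}).
#' @param system system label whose control/Tet1/sh-Dnmt1 columns are
#'   used.
#' @param band inclusive control-methylation band, default
#'   \code{c(20, 60)}.
#' @param min_drop minimum demethylation, percentage points (default 20).
#' @param max_diff maximum absolute difference between the two perturbed
#'   levels, points (default 5, strict).
#' @param max_rel maximum difference as a fraction of the mean perturbed
#'   level (default 0.1, inclusive).
#' @param both_arms require the drop in both perturbations (default
#'   TRUE).
#' @param perturbations the two arm labels (default Tet1 / sh-Dnmt1).
#' @return character vector of gene ids passing all criteria;
#'   deterministic and invariant to row order.
#' @export
matchedDemethylationSelection <- function(matrix, system,
        band = c(20, 60), min_drop = 20, max_diff = 5, max_rel = 0.1,
        both_arms = TRUE,
        perturbations = c("Tet1", "sh-Dnmt1")) {
    kc <- .condKey(system, "control")
    k1 <- .condKey(system, perturbations[1])
    k2 <- .condKey(system, perturbations[2])
    for (k in c(kc, k1, k2))
        if (!k %in% colnames(matrix))
            stop("condition not present in matrix: ", k)
    ok <- complete.cases(matrix[, c(kc, k1, k2), drop = FALSE])
    ctl <- matrix[ok, kc]; a <- matrix[ok, k1]; b <- matrix[ok, k2]
    ids <- rownames(matrix)[ok]
    c1 <- ctl >= band[1] & ctl <= band[2]
    drop1 <- (ctl - a) > min_drop
    drop2 <- (ctl - b) > min_drop
    c2 <- if (both_arms) drop1 & drop2 else drop1 | drop2
    dd <- abs(a - b)
    c3 <- dd < max_diff & dd <= max_rel * (a + b) / 2
    sort(ids[c1 & c2 & c3])
}

#' Select genes whose demethylation responds to vitamin C
#'
#' Genes demethylated more by Tet1 during reprogramming with Vc than
#' without, and up-regulated by Tet1 in the Vc system (log2FC > 0): the
#' Vc-response (606-gene-style) selection capturing the preferentially
#' boosted demethylation of fully methylated substrates.
#'
#' @param matrix condition matrix with Tet1 and control columns for both
#'   Vc systems.
#' @param expression data.frame with \code{id} and \code{log2fc} of Tet1
#'   vs control in the Vc-plus system.
#' @param vc_plus,vc_minus system labels (defaults \code{"OKMS-Vc+"},
#'   \code{"OKMS-Vc-"}).
#' @return character vector of selected gene ids.
#' @export
vcResponseSelection <- function(matrix, expression,
                                vc_plus = "OKMS-Vc+",
                                vc_minus = "OKMS-Vc-") {
    dp <- demethylationDelta(matrix, vc_plus, "Tet1")
    dm <- demethylationDelta(matrix, vc_minus, "Tet1")
    ids <- Reduce(intersect, list(dp$id, dm$id, expression$id))
    more <- dp$delta[match(ids, dp$id)] > dm$delta[match(ids, dm$id)]
    up <- expression$log2fc[match(ids, expression$id)] > 0
    sort(ids[more & up])
}
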