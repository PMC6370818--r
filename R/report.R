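#' @importFrom stats runif
NULL

## Gene-level methylation table for one condition: profile gene levels
## keyed by gene id, measured genes only.
.geneLevelTable <- function(dyads, genes) {
    p <- geneProfiles(dyads, genes)
    p <- p[p$measured, ]
    data.frame(id = p$gene_id, level = p$gene_level,
               stringsAsFactors = FALSE)
}

#' Run the full three-system analysis on a simulated (or loaded) study
#'
#' Ties the pipeline stages together: per condition, calls are paired
#' into dyads; per system, mean methylation, the AMD excess over the
#' sampling null, gene-level demethylation deltas and the above-average
#' target selections with their overlap are computed; targets consistent
#' across systems, promoter zone counts, and the matched-demethylation
#' and Vc-response selections complete the summary.
#'
#' @param bundle a \code{hemimeth_study} from \code{\link{simulateStudy}}
#'   (or an equivalently shaped list of loaded data).
#' @param min_depth per-strand depth floor for dyad pairing (default 5).
#' @param n_perm permutations for the AMD-excess test (default 199 here;
#'   single-sample analyses typically use 999).
#' @return a nested list (class \code{hemimeth_report}) with sections
#'   \code{methylation}, \code{amd}, \code{demethylation},
#'   \code{zones}, \code{selections}.
#' @export
studyReport <- function(bundle, min_depth = 5L, n_perm = 199L) {
    genes <- bundle$annotation
    systems <- names(bundle$calls)
    dyads <- lapply(bundle$calls, function(byp)
        lapply(byp, pairDyads, min_depth = min_depth))

    meth <- lapply(dyads, function(byp)
        vapply(byp, function(d) mean(dyadLevel(d)), numeric(1)))

    amd <- lapply(systems, function(sys) {
        d <- dyads[[sys]][["control"]]
        ex <- amdExcess(d, n_perm = n_perm)
        per_cond <- vapply(dyads[[sys]], function(x) mean(siteAMD(x)),
                           numeric(1))
        list(mean_amd = per_cond, excess = ex$excess,
             null_aggregate = ex$null_aggregate, p_value = ex$p_value)
    })
    names(amd) <- systems

    gene_tabs <- list()
    for (sys in systems)
        for (pert in names(dyads[[sys]]))
            gene_tabs[[paste0(sys, ":", pert)]] <-
                .geneLevelTable(dyads[[sys]][[pert]], genes)
    cmat <- buildConditionMatrix(gene_tabs)

    demeth <- list(); sel_sets <- list()
    for (sys in systems) {
        dt1 <- demethylationDelta(cmat, sys, "Tet1")
        dsh <- demethylationDelta(cmat, sys, "sh-Dnmt1")
        s1 <- selectAboveAverage(dt1)
        ssh <- selectAboveAverage(dsh)
        ov <- overlapStats(s1, ssh, union(dt1$id, dsh$id))
        cc <- deltaCorrelation(dt1, dsh)
        demeth[[sys]] <- list(mean_delta_Tet1 = attr(dt1, "mean_delta"),
                              mean_delta_shDnmt1 = attr(dsh, "mean_delta"),
                              n_selected_Tet1 = length(s1),
                              n_selected_shDnmt1 = length(ssh),
                              overlap_Tet1_in_shDnmt1 = ov$frac_a_in_b,
                              overlap_p = ov$p_hyper,
                              delta_correlation = cc$estimate)
        sel_sets[[sys]] <- intersect(s1, ssh)
    }
    consistent <- if (length(sel_sets) >= 2L) consistentTargets(sel_sets)
                  else sel_sets[[1]]

    ref_sys <- systems[[1]]
    prof <- geneProfiles(dyads[[ref_sys]][["control"]], genes)
    zones <- classifyZones(prof)
    zone_counts <- table(zones$zone)

    selections <- list(n_consistent = length(consistent))
    if (all(c("control", "Tet1", "sh-Dnmt1") %in%
            names(dyads[[ref_sys]])))
        selections$n_matched_demethylation <-
            length(matchedDemethylationSelection(cmat, ref_sys))
    if (all(c("OKMS-Vc+", "OKMS-Vc-") %in% systems) &&
        !is.null(bundle$expression[["OKMS-Vc+"]][["Tet1"]]))
        selections$n_vc_response <- length(vcResponseSelection(cmat,
            bundle$expression[["OKMS-Vc+"]][["Tet1"]]))

    structure(list(methylation = meth, amd = amd,
                   demethylation = demeth,
                   zones = as.list(zone_counts),
                   selections = selections),
              class = "hemimeth_report")
}

#' Write a study report as JSON and markdown
#'
#' @param report result of \code{\link{studyReport}}.
#' @param dir output directory; writes \code{report.json} and
#'   \code{report.md}.
#' @return invisibly, \code{dir}.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    md <- c("# Hemi-methylation study summary", "")
    for (sys in names(report$methylation)) {
        md <- c(md, sprintf("## %s", sys),
                sprintf("- mean methylation: %s",
                        paste(sprintf("%s %.2f%%",
                                      names(report$methylation[[sys]]),
                                      report$methylation[[sys]]),
                              collapse = ", ")),
                sprintf("- control AMD excess: %.3f points (p = %.4g)",
                        report$amd[[sys]]$excess,
                        report$amd[[sys]]$p_value),
                sprintf("- Tet1-target overlap with sh-Dnmt1 targets: %.1f%%",
                        100 * report$demethylation[[sys]]$overlap_Tet1_in_shDnmt1),
                "")
    }
    md <- c(md, "## Zones",
            sprintf("- %s: %d", names(report$zones),
                    unlist(report$zones)),
            "", "## Selections",
            sprintf("- %s: %d", names(report$selections),
                    unlist(report$selections)))
    writeLines(md, file.path(dir, "report.md"))
    invisible(dir)
}
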