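test_that("zone classification honours the inclusive CpG and methylation bands", {
    p <- toyProfiles(
        gene_id = paste0("g", 1:10),
        n_cpg = c(42, 83, 83, 41, 84, 50, 50, 30, 42, 60),
        gene_level = c(50, 40, 60, 50, 50, 39.9, 60.1, 45, 39, 80),
        gene_amd = 1)
    z <- classifyZones(p)
    expect_equal(as.character(z$zone),
                 c("II", "II", "II", "none", "none", "I", "I", "none",
                   "I", "I"))
    ## counts nest: zone II <= zone I + II <= all
    expect_lte(sum(z$zone == "II"), sum(z$zone %in% c("I", "II")))
    expect_lte(sum(z$zone %in% c("I", "II")), nrow(p))
    ## unmeasured genes never enter a zone
    p2 <- p; p2$measured[1] <- FALSE
    expect_equal(as.character(classifyZones(p2)$zone[1]), "none")
})

test_that("inter-CpG distances use the nearest same-chromosome neighbour", {
    d <- CpGDyads(c("chr1", "chr1", "chr1", "chr2"),
                  c(100L, 160L, 400L, 50L),
                  plus_level = c(50, 50, 50, 50),
                  minus_level = c(70, 10, 50, 50),
                  plus_depth = 10L, minus_depth = 10L)
    tab <- interCpGDistanceEnrichment(d)
    ## distances 60, 60, 240; the chr2 singleton is excluded
    expect_equal(sum(tab$n), 3L)
    b45_90 <- tab[tab$distance_band == "(45,90]", ]
    expect_equal(sum(b45_90$n), 2L)
    expect_equal(sum(tab$n[tab$distance_band == "(180,Inf]"]), 1L)
    ## cell mean AMD: the two close dyads carry AMDs 20 and 40
    expect_equal(b45_90$mean_amd[b45_90$n == 2], 30)
})

test_that("distance-band hemi enrichment is recoverable from simulated dyads", {
    set.seed(14)
    n <- 4000
    pos <- cumsum(sample(c(30L, 60L, 75L, 120L, 250L), n, TRUE))
    gap_prev <- c(NA, diff(pos)); gap_next <- c(gap_prev[-1], NA)
    mindist <- pmin(gap_prev, gap_next, na.rm = TRUE)
    hemi <- ifelse(!is.na(mindist) & mindist >= 45 & mindist <= 90,
                   0.35, 0.05)
    st <- makeDyadStates(runif(n, 30, 70), hemi,
                         orientation = sample(c(-1L, 1L), n, TRUE))
    d <- pairDyads(simulateReads(st, pos = pos), 5)
    tab <- interCpGDistanceEnrichment(d, meth_breaks = c(0, 100))
    in_band <- tab$distance_band == "(45,90]"
    expect_gt(min(tab$mean_amd[in_band]), max(tab$mean_amd[!in_band]))

    ## uniform hemi: flat table within sampling error
    st0 <- makeDyadStates(runif(n, 30, 70), 0.1,
                          orientation = sample(c(-1L, 1L), n, TRUE))
    d0 <- pairDyads(simulateReads(st0, pos = pos), 5)
    tab0 <- interCpGDistanceEnrichment(d0, meth_breaks = c(0, 100))
    expect_lt(diff(range(tab0$mean_amd)), 3)
})

test_that("high/low enrichment split is a per-bin median split with ties high", {
    p <- toyProfiles(paste0("g", 1:7),
                     n_cpg = 50,
                     gene_level = c(35.5, 35.2, 35.8, 35.4, 70.5, 70.2,
                                    20.5),
                     gene_amd = c(1, 5, 3, 7, 2, 2, 4))
    s <- splitHighLowEnrichment(p)
    ## bin (35,36]: AMDs 1,5,3,7 -> median 4: high = {5, 7}
    expect_equal(as.character(s$enrichment[1:4]),
                 c("low", "high", "low", "high"))
    ## bin (70,71]: identical AMDs -> all high (tie rule)
    expect_equal(as.character(s$enrichment[5:6]), c("high", "high"))
    ## singleton bin stays unassigned
    expect_true(is.na(s$enrichment[7]))
    ## odd bin count puts the median gene in high
    p3 <- toyProfiles(paste0("h", 1:3), 50, c(42.1, 42.5, 42.9),
                      gene_amd = c(1, 2, 3))
    s3 <- splitHighLowEnrichment(p3)
    expect_equal(as.character(s3$enrichment), c("low", "high", "high"))
})

test_that("fixed-width methylation bin curves suppress thin bins", {
    p <- toyProfiles(paste0("g", 1:200), 50,
                     gene_level = rep(c(12.5, 37.5, 62.5, 99), c(80, 60,
                                                                 58, 2)),
                     gene_amd = 1)
    vals <- data.frame(id = p$gene_id, value = p$gene_level)
    cur <- methylationBinCurve(p, vals, n_bins = 20, min_n = 50)
    ## populated bins reproduce the identity; the 2-gene bin is suppressed
    expect_equal(cur$mean_value[cur$n == 80], 12.5)
    expect_equal(cur$mean_value[cur$n == 60], 37.5)
    expect_true(is.na(cur$mean_value[cur$n == 2]))
    expect_equal(sum(cur$n), 200L)

    ## anti-monotone values give a decreasing curve over populated bins
    vals2 <- data.frame(id = p$gene_id, value = 100 - p$gene_level)
    cur2 <- methylationBinCurve(p, vals2, n_bins = 20, min_n = 50)
    got <- cur2$mean_value[!is.na(cur2$mean_value)]
    expect_true(all(diff(got) < 0))
})

test_that("mimic groups follow the printed bands and ratio thresholds", {
    p <- toyProfiles(
        gene_id = paste0("g", 1:10),
        n_cpg = 50,
        gene_level = c(35, 35, 35, 35, 35, 5, 65, 65, 95, 50),
        gene_amd = c(0.5, 5, 2, 0.7, 3.5, 0.05, 1, 7, 1, 1))
    g <- buildMimicGroups(p, min_size = 0L)
    m <- attr(g, "members")
    expect_equal(m$II, "g1")     # ratio 0.0143 < 0.02
    expect_equal(m$III, "g2")    # ratio 0.143 > 0.1
    expect_equal(m$I, "g6")
    expect_equal(m$IV, "g7")
    expect_equal(m$V, "g8")
    expect_equal(m$VI, "g9")
    ## between thresholds, or exactly on them, joins nothing
    all_members <- unlist(m)
    expect_false(any(c("g3", "g4", "g5", "g10") %in% all_members))
    ## groups are pairwise disjoint
    expect_equal(anyDuplicated(all_members), 0L)
    ## a small group is flagged under-powered at the default threshold
    g2 <- buildMimicGroups(p)
    expect_true(all(g2$underpowered))
})

test_that("mimic comparison orders active above passive contrasts", {
    p <- toyProfiles(
        gene_id = paste0("g", 1:80),
        n_cpg = 50,
        gene_level = rep(c(35, 35, 65, 65, 95), each = 16),
        gene_amd = rep(c(0.1, 8, 0.1, 10, 0.5), each = 16))
    g <- buildMimicGroups(p, min_size = 0L)
    ## a value that penalises hemi content (here through the AMD itself)
    vals <- data.frame(id = p$gene_id,
                       value = 0.1 * (100 - p$gene_level) -
                               0.5 * p$gene_amd)
    mc <- suppressWarnings(mimicComparison(g, vals))
    expect_true(mc$active_gt_passive)
    ## flipping the penalty sign inverts the ordering
    vals2 <- vals; vals2$value <- 0.1 * (100 - p$gene_level) +
                                  0.5 * p$gene_amd
    expect_false(suppressWarnings(mimicComparison(g, vals2))$active_gt_passive)
    ## identical distributions: all contrasts vanish
    vals3 <- data.frame(id = p$gene_id, value = 1)
    mc3 <- suppressWarnings(mimicComparison(g, vals3))
    expect_equal(mc3$contrasts$difference, rep(0, 4))
})

test_that("matched-demethylation selection enforces all three criteria", {
    tabs <- list(
        "MEF:control" = data.frame(id = letters[1:8],
            level = c(50, 50, 70, 40, 60, 21, 55, 45)),
        "MEF:Tet1" = data.frame(id = letters[1:8],
            level = c(25, 27, 30, 15, 35, 0.5, 30, 25)),
        "MEF:sh-Dnmt1" = data.frame(id = letters[1:8],
            level = c(28, 29, 32, 18, 36, 0.4, 28, 24.2)))
    cm <- buildConditionMatrix(tabs)
    sel <- matchedDemethylationSelection(cm, "MEF")
    ## a: diff 3 < 5 but 3 > 0.1 * 26.5 -- the relative clause binds
    ## b: diff 2 <= 0.1 * 28 -- passes
    ## c: control 70 outside 20-60
    ## d: diff 3 > 0.1 * 16.5 -- fails
    ## e: passes (diff 1 <= 3.55)
    ## f: diff 0.1 > 0.1 * 0.45 -- relative clause fails
    ## g: diff 2 <= 2.9 -- passes
    ## h: Tet1 drop 20 is not > 20 -- fails with both arms required
    expect_equal(sel, c("b", "e", "g"))
    ## h passes once a single demethylated arm suffices
    sel_any <- matchedDemethylationSelection(cm, "MEF", both_arms = FALSE)
    expect_equal(sel_any, c("b", "e", "g", "h"))
    ## order invariance
    cm_shuf <- cm[rev(seq_len(nrow(cm))), ]
    expect_equal(matchedDemethylationSelection(cm_shuf, "MEF"), sel)
})

test_that("Vc-response selection needs larger Vc+ demethylation and up-regulation", {
    tabs <- list(
        "OKMS-Vc+:control" = data.frame(id = c("a", "b", "c"),
                                        level = c(80, 80, 80)),
        "OKMS-Vc+:Tet1" = data.frame(id = c("a", "b", "c"),
                                     level = c(50, 50, 70)),
        "OKMS-Vc-:control" = data.frame(id = c("a", "b", "c"),
                                        level = c(80, 80, 80)),
        "OKMS-Vc-:Tet1" = data.frame(id = c("a", "b", "c"),
                                     level = c(65, 65, 60)))
    cm <- buildConditionMatrix(tabs)
    expr <- data.frame(id = c("a", "b", "c"), log2fc = c(1, -0.2, 1))
    ## a: delta 30 > 15 and up-regulated; b: down-regulated;
    ## c: delta 10 < 20
    expect_equal(vcResponseSelection(cm, expr), "a")
})
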