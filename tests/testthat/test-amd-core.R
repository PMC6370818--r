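test_that("site AMD is the absolute strand-level difference", {
    d <- CpGDyads("chr1", c(100L, 200L, 300L),
                  plus_level = c(80, 55, 0), minus_level = c(30, 55, 100),
                  plus_depth = 10L, minus_depth = 10L)
    expect_equal(siteAMD(d), c(50, 0, 100))
    expect_equal(dyadLevel(d), c(55, 55, 50))
})

test_that("CpGDyads validity rejects impossible levels and widths", {
    expect_error(CpGDyads("chr1", 1L, 120, 50, 10L, 10L), "0, 100")
    expect_error(CpGDyads("chr1", 1L, 50, 50, -1L, 10L), "non-negative")
})

test_that("gene profiles average strands before the absolute difference", {
    ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
    S4Vectors::mcols(ann)$gene_id <- "g1"

    ## opposite-orientation hemi dyads cancel: site AMDs 100, gene AMD 0
    d <- CpGDyads("chr1", c(100L, 200L), c(100, 0), c(0, 100),
                  10L, 10L)
    p <- geneProfiles(d, ann)
    expect_equal(p$plus_mean, 50)
    expect_equal(p$minus_mean, 50)
    expect_equal(p$gene_amd, 0)
    expect_equal(p$gene_level, 50)
    expect_equal(p$n_cpg, 2L)
    expect_equal(p$total_depth, 40)

    ## single dyad: gene AMD reduces to the site AMD
    d1 <- CpGDyads("chr1", 100L, 60, 20, 10L, 10L)
    expect_equal(geneProfiles(d1, ann)$gene_amd, 40)

    ## three dyads, hand-averaged
    d3 <- CpGDyads("chr1", c(100L, 200L, 300L), c(80, 40, 60),
                   c(20, 40, 60), 10L, 10L)
    p3 <- geneProfiles(d3, ann)
    expect_equal(p3$plus_mean, 60)
    expect_equal(p3$minus_mean, 40)
    expect_equal(p3$gene_amd, 20)

    ## a gene with no covered dyad is flagged unmeasured, not zero
    ann2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1000))
    S4Vectors::mcols(ann2)$gene_id <- "gempty"
    pe <- suppressWarnings(geneProfiles(d3, ann2))
    expect_false(pe$measured)
    expect_true(is.na(pe$gene_amd))
})

test_that("gene AMD never exceeds the window's mean site AMD", {
    ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    S4Vectors::mcols(ann)$gene_id <- "g1"
    set.seed(99)
    for (i in 1:15) {
        n <- sample(2:30, 1)
        d <- CpGDyads("chr1", seq(10L, by = 50L, length.out = n),
                      runif(n, 0, 100), runif(n, 0, 100), 10L, 10L)
        p <- geneProfiles(d, ann)
        expect_lte(p$gene_amd, mean(siteAMD(d)) + 1e-12)
    }
})

test_that("sample AMD averaging keeps only shared entities", {
    g1 <- data.frame(id = c("a", "b"), amd = c(10, 4))
    g2 <- data.frame(id = c("a", "c"), amd = c(20, 8))
    out <- combineSampleAMDs(list(G1 = g1, G2M = g2))
    expect_equal(out$id, "a")
    expect_equal(out$amd, 15)
    ## single sample is the identity
    expect_equal(combineSampleAMDs(list(g1)), g1)
    expect_error(combineSampleAMDs(list(g1, data.frame(id = "z", amd = 1))),
                 "shared")
})

test_that("HPLC methylation fraction follows 5mdC/(dC + 5mdC)", {
    expect_equal(hplcMethylationFraction(80, 20), 20)
    expect_equal(hplcMethylationFraction(80, 0), 0)
    expect_equal(hplcMethylationFraction(0, 20), 100)
    expect_error(hplcMethylationFraction(0, 0), "zero")
})

test_that("exact expectation matches the brute-force enumeration oracle", {
    set.seed(5)
    for (i in 1:40) {
        n1 <- sample(1:40, 1); n2 <- sample(1:40, 1); p <- runif(1)
        expect_equal(exactAbsMeanDiffExpectation(n1, n2, p),
                     bruteExpectation(n1, n2, p), tolerance = 1e-12)
    }
})

test_that("exact expectation obeys its closed forms and symmetries", {
    ## Bernoulli closed form 200 p (1 - p), exact
    for (p in c(0, 0.25, 0.5, 0.8, 1))
        expect_equal(exactAbsMeanDiffExpectation(1, 1, p),
                     200 * p * (1 - p), tolerance = 1e-13)
    ## degenerate p
    for (n in c(1, 7, 30)) {
        expect_identical(exactAbsMeanDiffExpectation(n, n, 0), 0)
        expect_identical(exactAbsMeanDiffExpectation(n, n, 1), 0)
    }
    ## depth swap and p <-> 1 - p symmetry
    for (p in c(0.05, 0.195, 0.5, 0.8))
        for (nn in list(c(3, 11), c(10, 10), c(5, 25))) {
            e <- exactAbsMeanDiffExpectation(nn[1], nn[2], p)
            expect_equal(exactAbsMeanDiffExpectation(nn[2], nn[1], p), e,
                         tolerance = 1e-12)
            expect_equal(exactAbsMeanDiffExpectation(nn[1], nn[2], 1 - p), e,
                         tolerance = 1e-12)
        }
    ## monotone decay toward 0 with depth
    for (p in c(0.195, 0.5)) {
        e <- vapply(c(1, 2, 5, 10, 30, 80, 200),
                    function(n) exactAbsMeanDiffExpectation(n, n, p),
                    numeric(1))
        expect_true(all(diff(e) < 0))
        expect_lt(e[length(e)], 5)
    }
    ## input validation
    expect_error(exactAbsMeanDiffExpectation(2.5, 10, 0.5), "integer")
    expect_error(exactAbsMeanDiffExpectation(0, 10, 0.5), ">= 1")
})

test_that("the 102-bin scheme isolates the 0 and 100 point bins", {
    b <- methylationBins(c(0, 0.4, 1, 19.5, 99.2, 100))
    expect_equal(b$bin, c("0", "(0,1]", "(0,1]", "(19,20]", "(99,100]",
                          "100"))
    expect_equal(b$p, c(0, 0.005, 0.005, 0.195, 0.995, 1))
})

test_that("theoretical site null aggregates exact per-cell expectations", {
    ## fully methylated everywhere: zero expected AMD at any depth
    d <- CpGDyads("chr1", seq(1L, by = 10L, length.out = 5),
                  100, 100, c(5L, 10L, 20L, 10L, 5L), 10L)
    expect_equal(aggregateNull(theoreticalSiteNull(d)), 0)

    ## single (bin, depth) cell reduces to the direct expectation
    d1 <- CpGDyads("chr1", seq(1L, by = 10L, length.out = 4),
                   19.5, 19.5, 10L, 10L)
    expect_equal(aggregateNull(theoreticalSiteNull(d1)),
                 exactAbsMeanDiffExpectation(10, 10, 0.195))

    ## two equally weighted cells average linearly
    d2 <- CpGDyads("chr1", c(1L, 11L), c(19.5, 49.5), c(19.5, 49.5),
                   10L, 10L)
    e1 <- exactAbsMeanDiffExpectation(10, 10, 0.195)
    e2 <- exactAbsMeanDiffExpectation(10, 10, 0.495)
    expect_equal(aggregateNull(theoreticalSiteNull(d2)), (e1 + e2) / 2)

    ## weights sum to one; aggregate invariant to dyad order
    set.seed(3)
    n <- 300
    dr <- CpGDyads("chr1", seq(1L, by = 10L, length.out = n),
                   runif(n, 0, 100), runif(n, 0, 100),
                   sample(5:20, n, TRUE), sample(5:20, n, TRUE))
    null <- theoreticalSiteNull(dr)
    expect_equal(sum(nullTable(null)$weight), 1)
    perm <- sample(n)
    expect_equal(aggregateNull(theoreticalSiteNull(dr[perm])),
                 aggregateNull(null))
    expect_error(theoreticalSiteNull(dr[0]), "no dyads")
})

test_that("gene null pools window depth into one virtual site", {
    ## zero methylation: zero null
    expect_equal(theoreticalGeneNull(toyProfiles("g", 5, 0, 0,
                                                 total_depth = 100)), 0)
    ## one dyad at depth 10 + 10 reduces to the site expectation
    expect_equal(theoreticalGeneNull(toyProfiles("g", 1, 19.5, 0,
                                                 total_depth = 20)),
                 exactAbsMeanDiffExpectation(10, 10, 0.195))
    ## pooling shrinks the null below any constituent site's expectation
    pooled <- theoreticalGeneNull(toyProfiles("g", 10, 50, 0,
                                              total_depth = 200))
    expect_lt(pooled, exactAbsMeanDiffExpectation(10, 10, 0.5))
    expect_gt(pooled, 0)
    expect_error(theoreticalGeneNull(toyProfiles("g", 1, 50, 0,
                                                 total_depth = 1)),
                 "total_depth")
})

test_that("per-dyad null expectations match the aggregate null", {
    set.seed(8)
    n <- 500
    d <- CpGDyads("chr1", seq(1L, by = 10L, length.out = n),
                  runif(n, 0, 100), runif(n, 0, 100),
                  sample(5:30, n, TRUE), sample(5:30, n, TRUE))
    expect_equal(mean(siteNullExpectation(d)),
                 aggregateNull(theoreticalSiteNull(d)))
})

test_that("AMD excess is near zero without hemi-methylation and detects it when present", {
    set.seed(21)
    n <- 3000
    st0 <- makeDyadStates(runif(n, 0, 100), 0)
    d0 <- pairDyads(simulateReads(st0, pos = seq(1L, by = 100L,
                                                 length.out = n)), 5)
    ex0 <- amdExcess(d0, n_perm = 199)
    expect_lt(abs(ex0$excess), 0.6)
    expect_gt(ex0$p_value, 0.01)

    st1 <- makeDyadStates(runif(n, 20, 80), 0.3,
                          orientation = sample(c(-1L, 1L), n, TRUE))
    d1 <- pairDyads(simulateReads(st1, pos = seq(1L, by = 100L,
                                                 length.out = n)), 5)
    ex1 <- amdExcess(d1, n_perm = 199)
    expect_gt(ex1$excess, 10)
    expect_equal(ex1$p_value, 1 / 200)
    expect_true(all(c("bin", "mean_observed", "expected", "excess") %in%
                    names(ex1$bin_excess)))
})
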