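## Shared fixtures and independent oracles.

## Four-call cytosine report: two dyads with per-strand counts
## 8/2, 3/7 (levels 80, 30) and 5/0, 0/5 (levels 100, 0).
fixtureReportLines <- c(
    "chr1\t100\t+\t8\t2\tCpG\tCGG",
    "chr1\t101\t-\t3\t7\tCpG\tCGT",
    "chr1\t300\t+\t5\t0\tCpG\tCGA",
    "chr1\t301\t-\t0\t5\tCpG\tCGT")

writeFixtureReport <- function(lines = fixtureReportLines) {
    f <- tempfile(fileext = ".txt")
    writeLines(lines, f)
    f
}

## Independent brute-force oracle: enumerate every outcome pair of two
## independent binomial measurements, weight by the pmf product. Kept
## deliberately naive (O(n1 n2) outer products), separate from the
## package's cumulative-sum implementation.
bruteExpectation <- function(n1, n2, p) {
    x <- 0:n1
    y <- 0:n2
    100 * sum(outer(dbinom(x, n1, p), dbinom(y, n2, p)) *
              abs(outer(x / n1, y / n2, "-")))
}

## Monte Carlo oracle.
mcExpectation <- function(n1, n2, p, ndraw = 1e6) {
    mean(abs(rbinom(ndraw, n1, p) / n1 - rbinom(ndraw, n2, p) / n2)) * 100
}

## Hand-built gene profile table (the geneProfiles output contract).
toyProfiles <- function(gene_id, n_cpg, gene_level, gene_amd,
                        total_depth = 1000) {
    data.frame(gene_id = gene_id, n_cpg = n_cpg,
               plus_mean = gene_level + gene_amd / 2,
               minus_mean = gene_level - gene_amd / 2,
               gene_level = gene_level, gene_amd = gene_amd,
               total_depth = total_depth, measured = TRUE,
               stringsAsFactors = FALSE)
}

dyadKey <- function(d) paste(as.character(GenomicRanges::seqnames(d)),
                             GenomicRanges::start(d))

## Dyad-level demethylation deltas between two paired-call sets.
dyadDeltas <- function(d_control, d_perturbed) {
    sh <- intersect(dyadKey(d_control), dyadKey(d_perturbed))
    data.frame(id = sh,
               delta = dyadLevel(d_control)[match(sh, dyadKey(d_control))] -
                       dyadLevel(d_perturbed)[match(sh, dyadKey(d_perturbed))],
               stringsAsFactors = FALSE)
}

## Gene-level methylation table from paired calls.
geneLevelTab <- function(dyads, ann) {
    p <- geneProfiles(dyads, ann)
    p <- p[p$measured, ]
    data.frame(id = p$gene_id, level = p$gene_level,
               stringsAsFactors = FALSE)
}
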