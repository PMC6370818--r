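#' @importFrom data.table fread fwrite data.table setkey as.data.table :=
#' @importFrom utils head
NULL

## Bismark CpG cytosine report columns (tab separated, no header):
## chrom, pos (1-based, strand-local), strand, count methylated,
## count unmethylated, context, trinucleotide.
.report_cols <- c("chrom", "pos", "strand", "meth_count", "unmeth_count",
                  "context", "tri")

#' Read a Bismark-style CpG cytosine report
#'
#' Parses the tab-separated per-cytosine report dialect (chrom, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide) into one record per cytosine call, keeping input order.
#'
#' @param path path to the report (plain text, no header).
#' @param context_filter sequence context to keep; default \code{"CpG"}.
#'   Use \code{NULL} to keep all rows.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{strand},
#'   \code{meth_count}, \code{unmeth_count}, \code{context}, plus derived
#'   \code{depth} and \code{level} (percent; \code{NA} when depth is 0).
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t100\t+\t8\t2\tCpG\tCGA",
#'              "chr1\t101\t-\t3\t7\tCpG\tCGT"), f)
#' readCytosineReport(f)
#' @export
readCytosineReport <- function(path, context_filter = "CpG") {
    if (!file.exists(path))
        stop("cytosine report not found: ", path)
    if (file.size(path) == 0L) {
        warning("empty cytosine report: ", path)
        return(data.frame(chrom = character(), pos = integer(),
                          strand = character(), meth_count = integer(),
                          unmeth_count = integer(), context = character(),
                          depth = integer(), level = numeric()))
    }
    dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
                colClasses = list(character = c(1, 3, 6, 7)))
    if (ncol(dt) < 6L)
        stop("malformed cytosine report (expected >= 6 tab-separated columns, got ",
             ncol(dt), "): ", path)
    names(dt)[seq_len(min(ncol(dt), 7L))] <- .report_cols[seq_len(min(ncol(dt), 7L))]
    bad <- which(is.na(dt$pos) | is.na(dt$meth_count) | is.na(dt$unmeth_count) |
                 !(dt$strand %in% c("+", "-")))
    if (length(bad))
        stop("malformed cytosine report line(s) ",
             paste(head(bad, 5), collapse = ", "), " in ", path)
    neg <- which(dt$meth_count < 0 | dt$unmeth_count < 0)
    if (length(neg))
        stop("negative counts on line(s) ",
             paste(head(neg, 5), collapse = ", "), " in ", path)
    if (!is.null(context_filter))
        dt <- dt[dt$context == context_filter, ]
    out <- data.frame(chrom = dt$chrom, pos = as.integer(dt$pos),
                      strand = dt$strand,
                      meth_count = as.integer(dt$meth_count),
                      unmeth_count = as.integer(dt$unmeth_count),
                      context = dt$context, stringsAsFactors = FALSE)
    out$depth <- out$meth_count + out$unmeth_count
    out$level <- ifelse(out$depth > 0, 100 * out$meth_count / out$depth, NA_real_)
    out
}

#' Write calls as a Bismark-style cytosine report
#'
#' @param calls data.frame as returned by \code{\link{readCytosineReport}}
#'   (columns chrom, pos, strand, meth_count, unmeth_count, context).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCytosineReport <- function(calls, path) {
    tri <- if ("tri" %in% names(calls)) calls$tri
           else ifelse(calls$strand == "+", "CGN", "CGN")
    ctx <- if ("context" %in% names(calls)) calls$context else "CpG"
    dt <- data.table(calls$chrom, calls$pos, calls$strand,
                     calls$meth_count, calls$unmeth_count, ctx, tri)
    fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Assemble strand-resolved calls into CpG dyads
#'
#' A dyad is emitted where a plus-strand call at position p and a
#' minus-strand call at p + 1 both exist and both reach \code{min_depth}
#' reads. The depth filter is applied per strand: the AMD compares two
#' independent strand measurements, each of which must be adequately
#' sampled. Calls with zero depth carry no level and are dropped first.
#'
#' @param calls data.frame of per-cytosine calls
#'   (\code{\link{readCytosineReport}}).
#' @param min_depth minimum per-strand read depth (default 5, the usual
#'   WGBS coverage floor).
#' @return A \code{\linkS4class{CpGDyads}} object. Attributes
#'   \code{n_unpaired} (calls without a partner on the other strand) and
#'   \code{n_undercovered} (paired but below \code{min_depth} on either
#'   strand) report what was dropped.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(100L, 101L),
#'                     strand = c("+", "-"),
#'                     meth_count = c(8L, 3L), unmeth_count = c(2L, 7L),
#'                     context = "CpG")
#' pairDyads(calls, min_depth = 5)
#' @export
pairDyads <- function(calls, min_depth = 5L) {
    stopifnot(min_depth >= 1)
    dup <- duplicated(calls[, c("chrom", "pos", "strand")])
    if (any(dup)) {
        d <- calls[which(dup)[1L], ]
        stop("duplicate call at ", d$chrom, ":", d$pos, " strand ", d$strand)
    }
    depth <- calls$meth_count + calls$unmeth_count
    calls <- calls[depth > 0L, , drop = FALSE]
    depth <- depth[depth > 0L]
    level <- 100 * calls$meth_count / depth

    plus <- data.table(chrom = calls$chrom, pos = calls$pos,
                       level = level, depth = depth)[calls$strand == "+"]
    minus <- data.table(chrom = calls$chrom, pos = calls$pos - 1L,
                        level = level, depth = depth)[calls$strand == "-"]
    setkey(plus, chrom, pos); setkey(minus, chrom, pos)
    m <- merge(plus, minus, by = c("chrom", "pos"),
               suffixes = c("_plus", "_minus"))
    n_unpaired <- (nrow(plus) - nrow(m)) + (nrow(minus) - nrow(m))
    ok <- m$depth_plus >= min_depth & m$depth_minus >= min_depth
    n_under <- sum(!ok)
    m <- m[ok]
    out <- CpGDyads(m$chrom, m$pos, m$level_plus, m$level_minus,
                    m$depth_plus, m$depth_minus)
    attr(out, "n_unpaired") <- as.integer(n_unpaired)
    attr(out, "n_undercovered") <- as.integer(n_under)
    out
}

#' Read a gene annotation with TSS windows
#'
#' Accepts either a header-bearing TSV (columns \code{gene_id},
#' \code{chrom}, \code{strand}, \code{tss}; 1-based TSS) or a headerless
#' 6-column BED (chrom, start, end, name, score, strand) where the TSS is
#' the strand-aware 5' end. Each gene gets the promoter window spanning
#' 1500 bases upstream through 2000 bases downstream of the TSS along the
#' gene's orientation.
#'
#' @param path annotation file path.
#' @param upstream,downstream window extent from the TSS along the gene
#'   (defaults 1500 / 2000).
#' @return \code{\link[GenomicRanges]{GRanges}} of windows with metadata
#'   columns \code{gene_id} and \code{tss}; the range strand is the gene
#'   strand.
#' @examples
#' f <- tempfile()
#' writeLines(c("gene_id\tchrom\tstrand\ttss", "g1\tchr1\t+\t10000"), f)
#' readGeneAnnotation(f)
#' @export
readGeneAnnotation <- function(path, upstream = 1500L, downstream = 2000L) {
    first <- readLines(path, n = 1L)
    if (grepl("gene_id", first, fixed = TRUE)) {
        tab <- fread(path, header = TRUE, sep = "\t",
                     colClasses = list(character = c("gene_id", "chrom", "strand")))
        ann <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                          strand = tab$strand, tss = as.integer(tab$tss),
                          stringsAsFactors = FALSE)
    } else {
        tab <- fread(path, header = FALSE, sep = "\t")
        if (ncol(tab) < 6L)
            stop("BED annotation needs 6 columns (chrom start end name score strand): ",
                 path)
        strand <- as.character(tab[[6]])
        ## BED is 0-based half-open; 5' end by strand, converted to 1-based
        tss <- ifelse(strand == "+", as.integer(tab[[2]]) + 1L,
                      as.integer(tab[[3]]))
        ann <- data.frame(gene_id = as.character(tab[[4]]),
                          chrom = as.character(tab[[1]]),
                          strand = strand, tss = tss, stringsAsFactors = FALSE)
    }
    bad <- !(ann$strand %in% c("+", "-"))
    if (any(bad))
        stop("unknown strand symbol '", ann$strand[which(bad)[1L]],
             "' for gene ", ann$gene_id[which(bad)[1L]])
    plus <- ann$strand == "+"
    start <- ifelse(plus, ann$tss - upstream, ann$tss - downstream)
    end <- ifelse(plus, ann$tss + downstream, ann$tss + upstream)
    gr <- GRanges(ann$chrom, IRanges(start, end), strand = ann$strand)
    mcols(gr) <- DataFrame(gene_id = ann$gene_id, tss = ann$tss)
    gr
}

#' Write / read the internal dyad table
#'
#' The dyad TSV carries chrom, plus_pos (1-based), per-strand levels and
#' depths and the per-site AMD; \code{readDyads} restores a
#' \code{\linkS4class{CpGDyads}} object exactly.
#'
#' @param dyads a \code{\linkS4class{CpGDyads}} object.
#' @param path file path.
#' @return \code{writeDyads}: invisibly, \code{path}. \code{readDyads}: a
#'   \code{CpGDyads} object.
#' @export
writeDyads <- function(dyads, path) {
    dt <- data.table(chrom = as.character(GenomicRanges::seqnames(dyads)),
                     plus_pos = GenomicRanges::start(dyads),
                     plus_level = dyads$plus_level,
                     minus_level = dyads$minus_level,
                     plus_depth = dyads$plus_depth,
                     minus_depth = dyads$minus_depth,
                     amd = siteAMD(dyads))
    fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname writeDyads
#' @export
readDyads <- function(path) {
    dt <- fread(path, header = TRUE, sep = "\t",
                colClasses = list(character = "chrom"))
    CpGDyads(dt$chrom, dt$plus_pos, dt$plus_level, dt$minus_level,
             dt$plus_depth, dt$minus_depth)
}
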