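#' @importFrom stats rbinom rpois rnorm rbeta
NULL

## A dyad state vector gives the fractions of the cell population whose
## (plus, minus) strand methylation is (u,u), (m,u), (u,m), (m,m).
.state_cols <- c("uu", "mu", "um", "mm")

#' Construct dyad population-state vectors
#'
#' Builds per-dyad fractions over the four (plus, minus) strand-state
#' configurations from a target pooled methylation level and a hemi
#' fraction. Hemi mass is placed according to \code{orientation} (+1: on
#' the plus strand, i.e. f_mu; -1: on the minus strand) and \code{skew}
#' (1 = fully one-sided, the clonally coherent default; 0 = balanced,
#' which the AMD statistic cannot see). The hemi fraction is clipped to
#' what the level permits (h <= 2 min(l, 1-l)).
#'
#' @param level pooled methylation percent, recycled.
#' @param hemi hemi fraction (f_mu + f_um), recycled.
#' @param orientation +1 / -1 per dyad; default alternating-free random
#'   is NOT drawn here -- pass a vector for stochastic orientation.
#' @param skew in [0, 1]: fraction of hemi mass on the dominant
#'   orientation is (1 + skew) / 2.
#' @return matrix with columns \code{uu}, \code{mu}, \code{um},
#'   \code{mm}; rows sum to 1.
#' @examples
#' makeDyadStates(level = 50, hemi = 0.3, orientation = 1)
#' @export
makeDyadStates <- function(level, hemi, orientation = 1L, skew = 1) {
    n <- max(length(level), length(hemi), length(orientation))
    level <- rep_len(level, n); hemi <- rep_len(hemi, n)
    orientation <- rep_len(orientation, n)
    stopifnot(all(level >= 0 & level <= 100), all(hemi >= 0 & hemi <= 1),
              skew >= 0, skew <= 1, all(orientation %in% c(-1, 1)))
    l <- level / 100
    h <- pmin(hemi, 2 * pmin(l, 1 - l))
    mm <- l - h / 2
    uu <- 1 - l - h / 2
    hi <- h * (1 + skew) / 2
    lo <- h - hi
    mu <- ifelse(orientation > 0, hi, lo)
    um <- h - mu
    st <- cbind(uu = uu, mu = mu, um = um, mm = mm)
    if (any(st < -1e-12)) stop("infeasible state (negative fraction)")
    pmax(st, 0)
}

#' True summaries of dyad state vectors
#'
#' @param states state matrix (\code{\link{makeDyadStates}}).
#' @return data.frame with \code{plus_level}, \code{minus_level},
#'   \code{level} (pooled, percent), \code{hemi} (fraction) and
#'   \code{amd} (percent, = 100 |f_mu - f_um|).
#' @export
stateSummaries <- function(states) {
    data.frame(plus_level = 100 * (states[, "mm"] + states[, "mu"]),
               minus_level = 100 * (states[, "mm"] + states[, "um"]),
               level = 100 * (states[, "mm"] + (states[, "mu"] + states[, "um"]) / 2),
               hemi = states[, "mu"] + states[, "um"],
               amd = 100 * abs(states[, "mu"] - states[, "um"]))
}

#' Apply a demethylation perturbation to dyad states
#'
#' Deterministic population-level transition kernels for the two
#' demethylation routes:
#' \itemize{
#' \item \code{Tet1} (active): each hemi configuration loses its
#'   methylated strand with probability \code{r_hemi}; fully methylated
#'   dyads lose each strand independently with probability \code{r_full}
#'   (so mm -> hemi with 2 r (1-r) and -> uu with r^2). Vitamin C
#'   multiplies \code{r_full} by \code{vc_full_multiplier} and
#'   \code{r_hemi} by \code{vc_hemi_multiplier}, both clipped at 1 --
#'   the preferential boost on fully methylated substrates.
#' \item \code{sh-Dnmt1} (passive): one replication generation in which a
#'   fraction \code{lambda} of fully methylated dyads fail maintenance on
#'   the daughter strand (mm -> hemi); standing hemi sites are not
#'   demethylated. \code{lambda} may be a per-dyad vector.
#'   \code{sh_orientation} places the new hemi mass: \code{"dominant"}
#'   (default) on each dyad's already-dominant orientation (clonally
#'   coherent maintenance failure), \code{"split"} equally on both.
#' \item \code{control}: identity.
#' }
#'
#' @param states state matrix.
#' @param perturbation one of \code{"control"}, \code{"Tet1"},
#'   \code{"sh-Dnmt1"}.
#' @param vc logical: vitamin C present (affects Tet1 only).
#' @param r_hemi,r_full Tet1 per-strand demethylation rates for hemi /
#'   full substrates (defaults 0.40 and 0.16, the relative drops measured
#'   for the two substrate types in vitro). May be per-dyad vectors, e.g.
#'   when an upstream model scales enzymatic access per locus.
#' @param vc_full_multiplier,vc_hemi_multiplier Vc rate multipliers
#'   (defaults 2.0 and 1.3).
#' @param lambda maintenance-failure fraction for sh-Dnmt1 (scalar or
#'   per-dyad), in [0, 1].
#' @param sh_orientation \code{"dominant"} or \code{"split"}.
#' @return transformed state matrix (rows still sum to 1).
#' @examples
#' st <- makeDyadStates(50, hemi = 1)       # pure hemi
#' applyPerturbation(st, "Tet1")            # f_uu = 0.4, f_mu = 0.6
#' @export
applyPerturbation <- function(states,
        perturbation = c("control", "Tet1", "sh-Dnmt1"),
        vc = FALSE, r_hemi = 0.40, r_full = 0.16,
        vc_full_multiplier = 2.0, vc_hemi_multiplier = 1.3,
        lambda = 0.5, sh_orientation = c("dominant", "split")) {
    perturbation <- match.arg(perturbation)
    sh_orientation <- match.arg(sh_orientation)
    if (any(c(r_hemi, r_full, lambda) < 0) || any(c(r_hemi, r_full, lambda) > 1))
        stop("rates must lie in [0, 1]")
    if (perturbation == "control") return(states)
    uu <- states[, "uu"]; mu <- states[, "mu"]
    um <- states[, "um"]; mm <- states[, "mm"]
    if (perturbation == "Tet1") {
        rh <- pmin(1, r_hemi * if (vc) vc_hemi_multiplier else 1)
        rf <- pmin(1, r_full * if (vc) vc_full_multiplier else 1)
        out <- cbind(uu = uu + rh * (mu + um) + rf^2 * mm,
                     mu = mu * (1 - rh) + rf * (1 - rf) * mm,
                     um = um * (1 - rh) + rf * (1 - rf) * mm,
                     mm = (1 - rf)^2 * mm)
    } else {                                   # sh-Dnmt1
        moved <- lambda * mm
        if (sh_orientation == "split") {
            mu2 <- mu + moved / 2
            um2 <- um + moved / 2
        } else {
            plus_dom <- mu >= um
            mu2 <- mu + ifelse(plus_dom, moved, 0)
            um2 <- um + ifelse(plus_dom, 0, moved)
        }
        out <- cbind(uu = uu, mu = mu2, um = um2, mm = mm - moved)
    }
    dimnames(out) <- list(NULL, .state_cols)
    out
}

#' Sample strand-resolved bisulfite calls from dyad states
#'
#' Per strand, the read depth is drawn from the depth model and the
#' methylated count from Binomial(depth, strand true level); the sampler
#' is unbiased for the strand levels. Output is in the cytosine-report
#' call layout of \code{\link{readCytosineReport}} (plus-strand C at
#' \code{pos}, minus-strand C at \code{pos + 1}).
#'
#' @param states state matrix, one row per dyad.
#' @param chrom,pos dyad coordinates (plus-strand C), recycled.
#' @param depth_mean mean per-strand depth (default 30).
#' @param depth_model \code{"poisson"} (default) or \code{"fixed"}.
#' @param seed optional integer; when given, sampling is done under a
#'   local RNG state so identical seeds give identical calls.
#' @return data.frame of calls (both strands interleaved).
#' @export
simulateReads <- function(states, chrom = "chr1",
                          pos = seq(1L, by = 100L,
                                    length.out = nrow(states)),
                          depth_mean = 30, depth_model = c("poisson", "fixed"),
                          seed = NULL) {
    depth_model <- match.arg(depth_model)
    if (!is.null(seed)) {
        old <- globalenv()$.Random.seed
        on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                          envir = globalenv()))
        set.seed(seed)
    }
    n <- nrow(states)
    if (n == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          strand = character(), meth_count = integer(),
                          unmeth_count = integer(), context = character(),
                          stringsAsFactors = FALSE))
    chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
    p_plus <- states[, "mm"] + states[, "mu"]
    p_minus <- states[, "mm"] + states[, "um"]
    d1 <- if (depth_model == "poisson") rpois(n, depth_mean)
          else rep.int(as.integer(depth_mean), n)
    d2 <- if (depth_model == "poisson") rpois(n, depth_mean)
          else rep.int(as.integer(depth_mean), n)
    m1 <- rbinom(n, d1, p_plus)
    m2 <- rbinom(n, d2, p_minus)
    idx <- rep(seq_len(n), each = 2L)
    is_plus <- rep(c(TRUE, FALSE), n)
    data.frame(chrom = chrom[idx],
               pos = pos[idx] + ifelse(is_plus, 0L, 1L),
               strand = ifelse(is_plus, "+", "-"),
               meth_count = ifelse(is_plus, m1[idx], m2[idx]),
               unmeth_count = ifelse(is_plus, d1[idx] - m1[idx],
                                     d2[idx] - m2[idx]),
               context = "CpG", stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic study. Defaults encode the study
#' conditions: Tet1 removes the methylated strand of hemi dyads at rate
#' 0.40 and each strand of full dyads at 0.16; vitamin C multiplies the
#' full-substrate rate by 2.0 and the hemi rate by 1.3; pluripotency-like
#' genes carry 42-83 promoter CpGs at intermediate methylation with
#' elevated, clonally coherent hemi-methylation; EMT-like genes are
#' highly methylated with almost no hemi; expression changes couple more
#' strongly to active than passive demethylation.
#'
#' @param n_genes number of genes (default 500).
#' @param class_mix named fractions for classes background /
#'   pluripotent / emt; must sum to 1.
#' @param depth_mean,depth_model read-depth model per strand (Poisson
#'   mean 30 by default -- deep enough that sampling AMD is well below
#'   biological AMD).
#' @param r_hemi,r_full,vc_full_multiplier,vc_hemi_multiplier Tet1 /
#'   vitamin-C rates, see \code{\link{applyPerturbation}}.
#' @param lambda maintenance-failure multiplier for sh-Dnmt1: the
#'   per-dyad failed fraction is \code{min(0.9, lambda * phi)} where phi
#'   is the dyad's standing hemi share of its methylated mass, so
#'   failure concentrates where hemi already accumulates.
#' @param hemi_mean named per-class mean hemi fractions.
#' @param hemi_skew orientation skew of hemi mass (1 = clonally
#'   coherent, the default; 0 = balanced and invisible to the AMD).
#' @param orientation_coherence probability that a dyad adopts its
#'   gene's dominant hemi orientation rather than a random one; standing
#'   hemi-methylation is replication-derived and hence locally clonal,
#'   which is what gives genes (not just sites) a real AMD.
#' @param level_mix background-gene methylation mixture (fractions of
#'   low [2-20\%], mid [20-80\%], high [80-97\%] promoters): promoter
#'   methylation is bimodal, most promoters hypomethylated.
#' @param access_coupling chromatin-access coupling in [0, 1]: the
#'   effective in-vivo Tet1 rates at a dyad are scaled by
#'   eta = 1 - access_coupling * level / 100, so densely methylated
#'   (closed) loci are demethylated less than the in vitro rates alone
#'   would predict. At the default 1, enzymatic access is proportional
#'   to the unmethylated (open) fraction.
#' @param kappa_active,kappa_passive,expr_noise_sd expression coupling
#'   log2FC = kappa * (true demethylation / 100) + N(0, sd), with
#'   kappa_active on Tet1 arms and kappa_passive on sh-Dnmt1 arms.
#' @param acc_level_slope,acc_hemi_penalty,acc_noise_sd accessibility
#'   score = slope * (100 - level) - penalty * hemi + noise.
#' @param systems,perturbations condition labels to simulate.
#' @return a list of class \code{hemimeth_sim_config}.
#' @export
simulationConfig <- function(n_genes = 800L,
        class_mix = c(background = 0.60, pluripotent = 0.25, emt = 0.15),
        depth_mean = 30, depth_model = "poisson",
        r_hemi = 0.40, r_full = 0.16,
        vc_full_multiplier = 2.0, vc_hemi_multiplier = 1.3,
        lambda = 0.5,
        hemi_mean = c(background = 0.06, pluripotent = 0.30, emt = 0.02),
        hemi_skew = 1, orientation_coherence = 0.8,
        level_mix = c(low = 0.5, mid = 0.3, high = 0.2),
        access_coupling = 1,
        kappa_active = 8, kappa_passive = 1.5, expr_noise_sd = 0.25,
        acc_level_slope = 0.05, acc_hemi_penalty = 4, acc_noise_sd = 0.5,
        systems = c("MEF", "OKMS-Vc-", "OKMS-Vc+"),
        perturbations = c("control", "Tet1", "sh-Dnmt1")) {
    if (abs(sum(class_mix) - 1) > 1e-8)
        stop("class_mix must sum to 1")
    stopifnot(all(c("background", "pluripotent", "emt") %in% names(class_mix)),
              all(names(hemi_mean) == names(class_mix)))
    structure(as.list(environment()), class = "hemimeth_sim_config")
}

## Draw the static genome: gene classes, coordinates, CpG positions and
## baseline states. Internal; called under simulateStudy's seeded RNG.
.simGenome <- function(cfg) {
    n <- cfg$n_genes
    if (n == 0L)
        return(list(genes = data.frame(gene_id = character(),
                                       chrom = character(),
                                       strand = character(),
                                       tss = integer(), class = character(),
                                       level = numeric(), hemi = numeric(),
                                       orientation = integer()),
                    dyads = data.frame()))
    cls <- sample(names(cfg$class_mix), n, replace = TRUE,
                  prob = cfg$class_mix)
    per_chrom <- 100L
    chrom <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
    tss <- 5000L + ((seq_len(n) - 1L) %% per_chrom) * 10000L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_cpg <- integer(n)
    n_cpg[cls == "background"] <- sample(10:120, sum(cls == "background"),
                                         replace = TRUE)
    n_cpg[cls == "pluripotent"] <- sample(42:83, sum(cls == "pluripotent"),
                                          replace = TRUE)
    n_cpg[cls == "emt"] <- sample(20:80, sum(cls == "emt"), replace = TRUE)
    level <- numeric(n)
    nb <- sum(cls == "background")
    mode <- sample(names(cfg$level_mix), nb, replace = TRUE,
                   prob = cfg$level_mix)
    bg <- numeric(nb)
    bg[mode == "low"] <- runif(sum(mode == "low"), 2, 20)
    bg[mode == "mid"] <- runif(sum(mode == "mid"), 20, 80)
    bg[mode == "high"] <- runif(sum(mode == "high"), 80, 97)
    level[cls == "background"] <- bg
    level[cls == "pluripotent"] <- runif(sum(cls == "pluripotent"), 40, 60)
    level[cls == "emt"] <- runif(sum(cls == "emt"), 85, 98)
    ## low concentration for background fattens the near-zero hemi tail
    ## (most promoters carry essentially no standing hemi-methylation)
    hm <- cfg$hemi_mean[cls]
    conc <- c(background = 7, pluripotent = 25, emt = 25)[cls]
    hemi <- rbeta(n, hm * conc, (1 - hm) * conc)
    gene_or <- sample(c(-1L, 1L), n, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                        chrom = chrom, strand = strand, tss = tss,
                        class = cls, level = level, hemi = hemi,
                        orientation = gene_or, stringsAsFactors = FALSE)
    ## dyads: plus-strand C positions inside the -1500/+2000 TSS window
    dy <- lapply(seq_len(n), function(i) {
        w0 <- if (strand[i] == "+") tss[i] - 1500L else tss[i] - 2000L
        cand <- seq(w0, w0 + 3498L, by = 2L)     # even spacing floor of 2 bp
        pos <- sort(sample(cand, n_cpg[i]))
        lev <- pmin(100, pmax(0, level[i] + rnorm(n_cpg[i], 0, 5)))
        coh <- runif(n_cpg[i]) < cfg$orientation_coherence
        orient <- ifelse(coh, gene_or[i],
                         sample(c(-1L, 1L), n_cpg[i], replace = TRUE))
        data.frame(gene_id = genes$gene_id[i], chrom = chrom[i],
                   plus_pos = pos, level = lev, hemi = hemi[i],
                   orientation = orient, stringsAsFactors = FALSE)
    })
    list(genes = genes, dyads = do.call(rbind, dy))
}

#' Simulate a full strand-resolved methylation study
#'
#' Generates a synthetic genome (gene classes, TSS windows, CpG dyads
#' with clonally coherent hemi-methylation), applies every
#' (system, perturbation) condition, samples strand-resolved reads, and
#' couples expression and accessibility tables to the true demethylation.
#' Everything is driven by one seed: identical seeds give identical
#' bundles.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed (default 1).
#' @param dir optional directory; when given, the bundle is also written
#'   to disk via \code{\link{writeStudy}}.
#' @return a list of class \code{hemimeth_study}: \code{calls} (nested
#'   list by system then perturbation, cytosine-report-layout
#'   data.frames), \code{annotation} (TSS-window GRanges),
#'   \code{truth} (gene table and per-dyad baseline table plus the true
#'   per-gene level matrix across conditions), \code{expression} (nested
#'   list of per-gene log2FC tables), \code{accessibility} (per-gene
#'   score), \code{config} and \code{seed}.
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1L,
                          dir = NULL) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    cfg <- config
    gen <- .simGenome(cfg)
    dy <- gen$dyads
    nd <- nrow(dy)
    base <- if (nd) makeDyadStates(dy$level, dy$hemi, dy$orientation,
                                   cfg$hemi_skew)
            else matrix(numeric(), ncol = 4,
                        dimnames = list(NULL, .state_cols))
    ## per-dyad maintenance-failure fraction under sh-Dnmt1
    meth_mass <- base[, "mm"] + base[, "mu"] + base[, "um"]
    phi <- ifelse(meth_mass > 0,
                  (base[, "mu"] + base[, "um"]) / meth_mass, 0)
    lam <- pmin(0.9, cfg$lambda * phi)
    ## chromatin-access scaling of the in-vivo Tet1 rates
    eta <- 1 - cfg$access_coupling *
        (if (nd) stateSummaries(base)$level else numeric()) / 100

    calls <- list(); truth_levels <- list(); expression <- list()
    for (sys in cfg$systems) {
        vc <- identical(sys, "OKMS-Vc+")
        calls[[sys]] <- list(); expression[[sys]] <- list()
        for (pert in cfg$perturbations) {
            st <- applyPerturbation(base, pert, vc = vc,
                    r_hemi = cfg$r_hemi * eta, r_full = cfg$r_full * eta,
                    vc_full_multiplier = cfg$vc_full_multiplier,
                    vc_hemi_multiplier = cfg$vc_hemi_multiplier,
                    lambda = lam, sh_orientation = "dominant")
            calls[[sys]][[pert]] <- simulateReads(st, dy$chrom,
                    dy$plus_pos, depth_mean = cfg$depth_mean,
                    depth_model = cfg$depth_model)
            tl <- if (nd) tapply(stateSummaries(st)$level, dy$gene_id,
                                 mean)
                  else numeric()
            truth_levels[[paste0(sys, ":", pert)]] <- tl
        }
        ctl <- truth_levels[[paste0(sys, ":control")]]
        for (pert in setdiff(cfg$perturbations, "control")) {
            delta <- ctl - truth_levels[[paste0(sys, ":", pert)]]
            kap <- if (pert == "Tet1") cfg$kappa_active
                   else cfg$kappa_passive
            expression[[sys]][[pert]] <- data.frame(
                id = names(delta),
                log2fc = kap * as.numeric(delta) / 100 +
                         rnorm(length(delta), 0, cfg$expr_noise_sd),
                stringsAsFactors = FALSE)
        }
    }
    lvl_mat <- if (length(truth_levels) && length(truth_levels[[1]]))
        do.call(cbind, truth_levels) else
        matrix(numeric(), nrow = 0, ncol = length(truth_levels),
               dimnames = list(NULL, names(truth_levels)))

    acc <- if (nrow(gen$genes))
        data.frame(id = gen$genes$gene_id,
                   value = cfg$acc_level_slope * (100 - gen$genes$level) -
                           cfg$acc_hemi_penalty * gen$genes$hemi +
                           rnorm(nrow(gen$genes), 0, cfg$acc_noise_sd),
                   stringsAsFactors = FALSE)
    else data.frame(id = character(), value = numeric())

    ann <- if (nrow(gen$genes)) {
        g <- gen$genes
        plus <- g$strand == "+"
        gr <- GRanges(g$chrom,
                      IRanges(ifelse(plus, g$tss - 1500L, g$tss - 2000L),
                              ifelse(plus, g$tss + 2000L, g$tss + 1500L)),
                      strand = g$strand)
        mcols(gr) <- DataFrame(gene_id = g$gene_id, tss = g$tss,
                               class = g$class)
        gr
    } else GRanges()

    bundle <- structure(list(calls = calls, annotation = ann,
        truth = list(genes = gen$genes, dyads = dy,
                     base_states = base, gene_levels = lvl_mat),
        expression = expression, accessibility = acc,
        config = cfg, seed = as.integer(seed)),
        class = "hemimeth_study")
    if (!is.null(dir)) writeStudy(bundle, dir)
    bundle
}

#' Write a simulated study bundle to disk
#'
#' Emits one Bismark-style cytosine report per (system, perturbation),
#' the gene annotation TSV, ground-truth tables, expression and
#' accessibility TSVs and a manifest JSON recording the configuration
#' and seed.
#'
#' @param bundle result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeStudy <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    safe <- function(x) gsub("[^A-Za-z0-9_+-]", "_", x)
    for (sys in names(bundle$calls))
        for (pert in names(bundle$calls[[sys]]))
            writeCytosineReport(bundle$calls[[sys]][[pert]],
                file.path(dir, sprintf("%s_%s.CpG_report.txt",
                                       safe(sys), safe(pert))))
    g <- bundle$truth$genes
    fwrite(data.table(gene_id = g$gene_id, chrom = g$chrom,
                      strand = g$strand, tss = g$tss),
           file.path(dir, "annotation.tsv"), sep = "\t")
    fwrite(as.data.table(g), file.path(dir, "truth_genes.tsv"), sep = "\t")
    fwrite(as.data.table(bundle$truth$dyads),
           file.path(dir, "truth_dyads.tsv"), sep = "\t")
    for (sys in names(bundle$expression))
        for (pert in names(bundle$expression[[sys]]))
            fwrite(as.data.table(bundle$expression[[sys]][[pert]]),
                   file.path(dir, sprintf("expression_%s_%s.tsv",
                                          safe(sys), safe(pert))),
                   sep = "\t")
    fwrite(as.data.table(bundle$accessibility),
           file.path(dir, "accessibility.tsv"), sep = "\t")
    cfg <- bundle$config
    cfg$class_mix <- as.list(cfg$class_mix)
    cfg$hemi_mean <- as.list(cfg$hemi_mean)
    jsonlite::write_json(list(seed = bundle$seed,
                              config = cfg[order(names(cfg))]),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
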