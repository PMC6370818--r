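---
title: "Detecting hemi-methylated CpG dyads with the AMD statistic"
author: "hemimeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hemi-methylated CpG dyads with the AMD statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemimeth)
```

## The measurement problem

A CpG dyad has a cytosine on each strand, and maintenance methylation
normally copies the parental strand's state onto the daughter strand
after replication. When maintenance fails (DNMT1 suppression) the
dyad is left *hemi-methylated*; TET1-driven active demethylation in
turn prefers hemi-methylated substrates. Bulk bisulfite sequencing
cannot observe a dyad's joint state — reads from the two strands come
from different molecules — but it does measure the two strands
separately. `hemimeth` quantifies hemi-methylation from that strand
contrast.

The per-site statistic is the absolute methylation difference,
AMD = |m~+~ − m~−~| with m the percent methylation of each strand's
cytosine. At gene level, each strand's levels are averaged
(unweighted) over all CpG dyads in the TSS window (1500 bases
upstream to 2000 downstream along the gene) *before* the absolute
difference is taken, so opposite-orientation site asymmetries cancel
and only coherent strand asymmetry survives. This is deliberate: the
gene AMD is bounded above by the window's mean site AMD (triangle
inequality; a unit test enforces it).

### What the AMD can and cannot see

The population fractions of the four joint states
(uu, mu, um, mm) determine the strand levels:
m~+~ = mm + mu, m~−~ = mm + um (×100). The true AMD is therefore
100·|f~mu~ − f~um~|. A hemi-methylated population whose orientations
are perfectly balanced (f~mu~ = f~um~) has identical strand levels
and is *invisible* to the AMD — and to any bulk strand-contrast
statistic. Observable hemi-methylation is orientation-skewed
hemi-methylation, which is what replication produces locally: the
cells descending from one recent replication share the same
hemi orientation (clonal coherence). This assumption is stated here
once because it shapes both the statistic's interpretation and the
simulator's design below.

## The sampling null

A nonzero AMD arises from finite depth alone. Under no
hemi-methylation, the two strands are independent
Binomial(n~1~, p) and Binomial(n~2~, p) measurements of one level p,
and the sampling-only AMD is E|X/n~1~ − Y/n~2~| × 100. The package
evaluates this expectation *exactly* — no normal approximation
anywhere, since approximation error is precisely the kind of bias the
excess statistic would absorb. The implementation reorganises the sum
over all (n~1~+1)(n~2~+1) outcome pairs with cumulative sums (cost
O(n~1~+n~2~)); the test suite keeps an independent brute-force
enumeration oracle and checks agreement to 10^−12^, plus the closed
form E = 200·p(1−p) at n~1~ = n~2~ = 1, the p ↔ 1−p and depth-swap
symmetries, and a 10^6^-draw Monte Carlo cross-check.

For a sample, dyads are binned by pooled level (mean of the two
strand levels) into 102 bins — {0}, (0,1], …, (99,100), {100} — and
each (bin, depth pair) cell contributes its exact expectation at the
bin representative, weighted by its dyad fraction. Numerical
choices:

* the bin representative is the interval midpoint; the two point
  bins use p = 0 and p = 1 exactly (their expectation is 0, which is
  self-consistent: a dyad whose pooled observed level is 0 has AMD 0);
* expectations are memoised over distinct (n~1~, n~2~, p) triples;
* the gene-level null treats the whole TSS window as one pooled site:
  level = window average, depth = summed depth, split evenly between
  two virtual strands (rounded, floor 1). The even split is a
  modelling choice — the true per-strand split is not recoverable
  from pooled summaries — and pooling makes the gene null much
  smaller than any single-site null, which is why gene AMDs of a few
  percent are already informative.

One reference cell deserves a note. For the 19–20% bin at depth 10
the exact expectation at the midpoint (p = 0.195, n~1~ = n~2~ = 10)
is 13.74%; under the alternative reading of "depth 10" as pooled
(5 + 5 per strand) it is 18.80%. A reported reference value of
14.82% for this cell is not reproduced by exact enumeration anywhere
in the scanned range (p = 0.190…0.200, both conventions); the
package pins the midpoint/per-strand value and the acceptance
machinery documents the +1.08-point residual rather than absorbing
it into the implementation.

## Testing for excess AMD

The aggregate excess is mean observed AMD minus the aggregate null.
Its significance comes from a within-dyad read-reshuffle permutation
test: conditional on a dyad's total methylated reads and its two
depths, the plus-strand methylated count under the null is exactly
hypergeometric, so resampling it (and recomputing the mean AMD)
generates an exact conditional null distribution. Real strand
asymmetry is destroyed by the reshuffle, so the observed mean sits in
the upper tail. The p-value uses the add-one convention
(1 + #{perm ≥ obs})/(B + 1); B defaults to 999 for single analyses
(replicated calibration studies inside the test suite use B = 199 —
the test is exact at any B). Randomness comes from the session RNG;
set a seed for reproducibility.

Type-I calibration is checked on 100 seeded replicates of a zero-hemi
synthetic sample (10,000 dyads, depth 30): the rejection count at the
5% level is required to stay inside the exact binomial 99% envelope
(≤ 10 of 100). That envelope is the a-priori correct reading of a
calibration check on finitely many Bernoulli replicates; demanding
literally ≤ 5 rejections would fail a perfectly calibrated test a
third of the time.

## Comparative analyses

* **Deltas and selections.** Demethylation delta =
  level(control) − level(perturbed), positive = demethylation,
  computed over entities measured in both conditions (missingness is
  dropped pairwise, never imputed). "Demethylated by X" means delta
  strictly above the mean delta of all measured entities; an absolute
  threshold mode exists but is not the default. The same
  strictly-above-average rule selects genes by |log2FC|.
* **Overlap.** Overlap fractions are universe-independent; the
  one-sided hypergeometric enrichment p is not (both are reported).
  Consistent targets are the strict intersection across systems.
* **Curves.** AMD-response curves sort by AMD (stable sort, ties
  broken by id) into equal-count groups — 14 for sites, 20 for genes
  by convention; the remainder spreads over the first groups so group
  sizes differ by at most one. Equal-count (not equal-width) grouping
  was an open choice and is flagged as such.
* **Zones and mimic groups.** Zone I: 42–83 CpGs in the TSS window;
  Zone II: additionally 40–60% methylation. All printed band
  endpoints are inclusive and frozen in tests; the ratio thresholds
  (AMD/level < 0.02, > 0.1) are strict on both sides, so values
  exactly on a threshold join nothing. Groups at or below 100
  members are flagged under-powered rather than dropped.
* **Matched-demethylation filter.** Control level within 20–60%
  (inclusive); demethylation by more than 20 percentage points —
  read as points, the units used throughout, not 20% relative — in
  *both* arms by default (the printed rule says "Tet1 or sh-Dnmt1"
  but the matching clause presupposes both arms moved;
  `both_arms = FALSE` restores the literal reading); and the two
  perturbed levels within 5 points (strict) *and* within 10% of
  their mean (inclusive). Both clauses genuinely bind: fixtures in
  the test suite include a gene that passes the 5-point clause and
  fails the relative one.
* **Vc-response filter.** Larger Tet1 delta with vitamin C than
  without, and log2FC > 0 (sign only; no extra fold-change threshold
  is applied, another open choice made here).

## The simulator

`simulateStudy()` exists so every stage is testable without external
data. It draws a gene-centric genome and per-dyad joint-state vectors,
pushes them through condition-specific kernels, and samples reads.

**Baseline.** Three gene classes: background (60%),
pluripotency-like (25%), EMT-like (15%). Background promoter
methylation is bimodal — 50% low (2–20%), 30% mid (20–80%), 20% high
(80–97%) — the standard picture of promoter methylation;
pluripotency-like genes get 42–83 promoter CpGs at 40–60% with
elevated hemi fraction (mean 0.30); EMT-like genes are 85–98%
methylated with almost no hemi (mean 0.02). Background hemi is
Beta-distributed with a fat near-zero tail (mean 0.06, concentration
7): most promoters carry essentially no standing hemi-methylation.
Hemi orientation is clonally coherent: each dyad puts its hemi mass
on one strand (`hemi_skew = 1`), and a dyad follows its gene's
dominant orientation with probability 0.8. Balanced hemi
(`hemi_skew = 0`) is available and is exactly the case the AMD cannot
detect — the simulator makes that blindness testable instead of
hiding it.

**Kernels.** Tet1 removes the methylated strand of a hemi dyad with
probability r~hemi~ = 0.40 and each strand of a full dyad
independently with r~full~ = 0.16 (the relative drops measured for
the two substrate types in vitro); vitamin C multiplies r~full~ by
2.0 and r~hemi~ by 1.3 (clipped at 1) — the preferential boost on
full substrates that redirects demethylation toward highly
methylated (EMT-like) genes. Because in vivo TET1 must reach its
substrate through chromatin, the *effective* per-dyad rates in the
study simulation are scaled by an access factor
η = 1 − level/100: enzymatic access proportional to the open
(unmethylated) fraction. This matches the observation that densely
methylated genes are demethylated less in vivo than enzyme kinetics
alone would predict, and it is what makes demethylation rise
monotonically with AMD rather than with raw methylation. sh-Dnmt1 is
one replication generation of maintenance failure: a per-dyad
fraction λ~d~ = min(0.9, 0.5·φ~d~) of full dyads becomes
hemi-methylated on the daughter strand, where φ~d~ is the dyad's
standing hemi share of its methylated mass — failure concentrates
where hemi-methylation already accumulates, which is what makes the
two demethylation routes share targets. New hemi mass lands on the
dyad's dominant orientation (clonal coherence again). Multi-
generation replication dynamics are deliberately not modelled by
default.

**Measurement.** Per strand, depth ~ Poisson(30) (deep enough that
sampling AMD is well below biological AMD at the chosen hemi
fractions) and methylated count ~ Binomial(depth, strand level).
The sampler is unbiased (checked at 10^5^ draws within 0.1 point)
and byte-reproducible under a seed.

**Couplings.** Expression: log2FC = κ·(true gene delta)/100 +
N(0, 0.25), with κ~active~ = 8 on Tet1 arms and κ~passive~ = 1.5 on
sh-Dnmt1 arms — active demethylation affects expression more. These
are free parameters chosen once for realistic magnitudes (a strongly
demethylated pluripotency gene gains ~0.5 log2 units) and a clear
arm contrast; setting them equal is the negative control.
Accessibility: 0.05·(100 − level) − 4·hemi + N(0, 0.5), encoding
the finding that hemi-rich genes are less accessible at matched
methylation.

**What the simulator does not emulate.** Read-level errors and
bisulfite conversion failure; 5hmC/5fC/5caC chemistry (bisulfite
data cannot resolve them, so neither does the model); fragment-level
linkage between the two strands' reads; chromosome-scale spatial
structure beyond promoter windows; cell-cycle mixtures. Passing
tests therefore demonstrate the pipeline's statistical behaviour
under the stated generative assumptions, not the magnitudes any
particular real dataset would give.

## Problem sizes and determinism

The shipped studies use 800 genes (~50,000 dyads per condition,
nine conditions), null-calibration and recovery runs use 10,000
dyads at depth 30 with 100 replicates, ordering checks use 50
replicates of the study's MEF arm, and curve checks average five
seeded replicates (the monotonicity claim is about the expected
curve). These sizes were chosen to make group means stable at desk
scale. Every stochastic step is seed-driven; re-running any stage on
identical inputs and seed reproduces identical primary outputs,
including file bytes.

## Known limitations

* Balanced hemi-methylation is undetectable in principle; all
  quantitative statements concern orientation-coherent hemi mass.
* The theoretical gene null's even depth split is an approximation;
  strongly asymmetric strand coverage would make it slightly
  optimistic. Asymmetric coverage is dropped (per-strand depth
  filter), never imputed.
* Binning by *observed* pooled level makes the site null very mildly
  biased near bin edges; at depth 30 and 10,000 dyads the aggregate
  bias stays within ±0.3 points (tested).
* The AMD-sorted group curves inherit level-dependent sampling noise
  in the AMD ranking; interpretation of single-replicate curves at
  small n should be cautious — hence the replicate averaging.
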