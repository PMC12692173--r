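---
title: "Clonal inference from single-cell transcriptome variants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal inference from single-cell transcriptome variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescope)
```

## The problem

Tumors are mosaics of clones — cell populations that share somatic
mutations accumulated along a lineage. Single-cell RNA-seq reads carry
those mutations, so in principle a transcriptome experiment can genotype
every cell and reconstruct the clonal structure without DNA sequencing.
In practice four obstacles intervene: expression drop-out (a site simply
not covered in a cell), allelic imbalance (heterozygous sites expressed
away from a 50/50 allele ratio), RNA editing (enzymatic A-to-I and C-to-U
changes that masquerade as somatic T>C / C>T mutations), and plain
sequencing error at low depth. clonescope is a pipeline built around those
four obstacles: pileup calling, database-trained SVM filtering,
beta-binomial genotyping, neighbor-based imputation, robust-PCA denoising,
and random-forest-refined hierarchical clustering.

## Variant detection

Reads are demultiplexed by barcode tag (`CB`) or one file per cell, and
tallied per position with base- and mapping-quality cutoffs (defaults:
depth ≥ 2, alt reads ≥ 2, base quality ≥ 20, mapping quality ≥ 20;
duplicate, secondary and supplementary alignments are ignored).
Coordinates are 1-based (VCF convention). Each call is annotated with a
single region class using the precedence
splicing > UTR5 > UTR3 > exonic > ncRNA > intronic > intergenic, and with
its pyrimidine-strand substitution class and trinucleotide context.
Runs of adjacent substitutions within one cell are merged into multi-base
(MBS) records — these are retained because they are informative training
material for the filter (below). Insertions and deletions are called from
the alignment CIGARs but excluded from genotype matrices and signatures.

## Separating mutations from editing and error

The filter is a binary SVM whose labels come from databases rather than
manual truth: calls matching a dbSNP-like resource at population frequency
≥ 0.01 are positives (certainly real sequence), while calls at catalogued
RNA-editing sites without amino-acid-changing annotation, plus all MBS
calls, are negatives. Features are per-call quantities a VCF would carry —
depth, alternate count, VAF and its Wilson lower confidence bound, base
and site quality, strand-bias ratio, substitution/region one-hots — plus
the number of catalogued editing sites within ±30 bp of the call. The
neighborhood feature reflects a structural fact about A-to-I editing: it
concentrates in inverted Alu repeats, so editing artifacts cluster around
other known editing sites while genuine somatic mutations rarely do; this
is the same evidence that Alu-region masks exploit in conventional RNA-seq
variant calling.

Two deliberate choices depart from the obvious defaults:

* **Cross-cell support is computed but not used by the decision
  function.** Both training classes are intrinsically multi-cell (germline
  variants are in every cell; catalogued editing sites recur), while the
  genuine somatic mutations the filter must pass are mostly private to
  single cells — the cumulative unique-site curve of raw calls is nearly
  linear in cell count. A support-driven boundary would be systematically
  biased against exactly the calls the pipeline exists to find.
* **The operating point is calibrated, not the raw sign.** With balanced
  class weights the zero crossing of the decision function can sit inside
  the positive class even when ranking is nearly perfect (held-out AUROC
  ≈ 0.99+). The default threshold therefore maximizes Youden's J on
  out-of-fold decision values; `decision_threshold` overrides it.

Calls matching the dbSNP-like resource are retained regardless of their
SVM score by default: low-depth known variants are still useful for
genotyping drop-outs downstream (`strict_svm = TRUE` disables this).

## Genotype inference

At a site with alternate count $k$ out of depth $n$, the likelihood of
genotype $g \in \{0, 1, 2\}$ is beta-binomial,
$k \sim \mathrm{BetaBin}(n, \mu_g, s)$ with
$\alpha = \mu s,\ \beta = (1-\mu)s$, and means $\mu_0 = \varepsilon$,
$\mu_1 = \rho$, $\mu_2 = 1 - \varepsilon$. Defaults:
$\varepsilon = 0.001$ (error rate), $s = 100$ (concentration; the
beta-binomial absorbs the extra-binomial spread that amplification and
allele-specific expression induce), uniform prior, and a hard call only
when the maximum posterior reaches 0.8 (otherwise the entry is missing).
$\rho$ is the expected heterozygous alternate fraction: 0.5 by default,
or a per-gene value from an allelic-imbalance table, clipped to
[0.05, 0.95]. When a per-gene expression rate is available, the prior odds
of genotype 0 are multiplied by it (floored at 0.1): at a drop-out-prone
gene, "no alternate reads" is weaker evidence of wild type. The exact
functional form that combines allelic imbalance with expression rate is
this package's choice — the prior-reweighting above — and it can be
disabled (`use_expression_rate = FALSE`) for ablation.

Counts are re-tallied at the filtered site list for *every* cell
(`site_counts()`), so a covered cell with no alternate reads is an
observed genotype 0, not a missing entry. Cells with fewer than
`min_sites` (default 10) observed genotypes are dropped.

## Drop-out imputation

Distances between cells are missing-aware scaled Manhattan distances:
$d(i,j) = \sum_{\text{shared}} |g_i - g_j| \cdot S / S_{ij}$ where $S$ is
the total site count and $S_{ij}$ the shared observed count; pairs sharing
fewer than `min_overlap` (5) sites are incomparable. Neighbors are the
cells within the `dist_quantile` (0.15) quantile of a cell's comparable
distances, optionally restricted to the same annotation and to cells with
similar 96-context spectra (off by default — per-cell spectra are noisy at
shallow coverage). A missing entry is filled with the weighted-majority
genotype (weights $1/(1+d)$) when at least `min_votes` (3) neighbors are
observed there and the majority is unique; ties leave the entry missing,
and observed entries are never modified. Reported robustness to these
thresholds motivates round defaults rather than tuning.

## Denoising

The genotype matrix of a clonal population is approximately low-rank
(cells of a clone repeat one genotype pattern) plus sparse (cell-private
artifacts). Principal component pursuit,
$\min \|L\|_* + \lambda \|S\|_1\ \mathrm{s.t.}\ L + S = M$, is solved by
inexact augmented-Lagrange iterations with
$\lambda = 1/\sqrt{\max(\mathrm{dim})}$, tolerance $10^{-7}$, and at most
500 iterations. Missing entries are handled by masking: they are imputed
with the current $L + S$ at every iteration, so only observed entries
constrain the fit. Observed entries whose sparse component exceeds 0.5 in
magnitude are reset to the re-quantized low-rank value (nearest of
{0, 1, 2}); everything else is untouched, and missing stays missing. Two
guards matter in practice: all-missing columns are dropped, and if the
nuclear penalty collapses every cell onto a single pattern — which can
happen when there are too few cells to form blocks — denoising is a no-op
with a warning rather than an erasure of real structure. Sites mutated in
fewer than `min_cells` (3) cells are removed afterwards as presumptive
noise.

## Clonal clustering and refinement

Cells are clustered by average-linkage (UPGMA) agglomeration on the
Manhattan distances — Ward linkage assumes Euclidean geometry the
genotype distances do not have. The tree is cut at each candidate k
(default 2–10) and the chosen k maximizes mean silhouette, penalized by
`complexity_penalty` per extra clone (ties go to the smaller k: the
lower-complexity clonal structure). A random forest (500 trees) is then
trained to predict the clone labels from genotypes; each mutation gets a
normalized Gini importance and a permutation ("accuracy") importance, and
stratified 5-fold cross-validation reports how reliably each clone is
recognized. Refinement keeps mutations above the `gini_quantile` (0.75)
importance cutoff whose prevalence pattern is clone-consistent (every
clone cleanly mutated ≥ 50% or cleanly wild-type ≤ 20%), re-clusters on
the retained sites, and iterates to a fixed point (labels unchanged; at
most 5 rounds). The retained set never grows, and an empty retained set
falls back to the unrefined assignment with a warning.

Internal and external quality indices (silhouette, Calinski–Harabasz,
Davies–Bouldin, adjusted Rand, Fowlkes–Mallows, normalized mutual
information) are implemented from their textbook definitions and verified
in the test suite against exhaustive pair-count oracles.

## Mutational signatures

Single-base substitutions are counted into the 96 trinucleotide context
classes (6 pyrimidine-centric substitutions × 16 flank pairs, conventional
COSMIC ordering), reverse-complementing purine-reference calls. A
recurrent site counts once per cell carrying it by default (`per =
"site"` collapses recurrences). Cosine similarity between spectra is the
plain inner-product cosine and is scale-invariant, so counts and
fractions give identical values.

## Spatial data

Spots are pseudo-cells with coordinates: the genotype pipeline is
identical. Because each ROI spot pools several cells, the evidence
threshold is stricter (`min_mutations = 20`), and the retained fraction is
reported as spot utilization. Clone labels are intersected with
expression clusters: every non-empty (cluster × clone) combination is a
subclone, combinations smaller than `min_group` (10 spots) merge into the
cluster's dominant clone, and split clusters are named `<type>_<k>`.

## The synthetic benchmark

Everything above is exercised on generated data; no downloads are needed.
Two generators exist.

`simulate_clonal_population()` draws count matrices directly: 3 clones on
a chain tree (each clone adds its own mutations to its ancestor's), 60
cells, 80 clonal sites, depth ~ NegBinomial(mean 15, size 2), drop-out
0.3, $\rho = 0.5$, $\varepsilon = 0.001$, plus cell-independent editing
events sized to ~20% of raw alt-bearing calls with low editing fractions
(Beta(2, 8)).

`write_synthetic_bam()` emits an indexed, barcoded BAM plus reference,
annotation, a dbSNP-like VCF and an editing-site TSV. Its design choices
mirror what the filter must face in real data: germline common variants in
every cell with transition-biased alleles (Ts:Tv = 2:1); clonal somatic
mutations on the chain tree; RNA editing as a site-level property — every
expressing cell edits a low Beta(1.5, 10) fraction of transcripts — at
sites that are 90% A-to-I (A/T bases), 85% clustered within ~120 bp
(the inverted-Alu geometry), and 80% intronic/3'UTR; adjacent double
substitutions as MBS artifacts; uniform sequencing error 0.001; and read
coverage split into a pre-mRNA layer across the gene body and a mature
layer confined to exonic segments, so intronic coverage is a minority of
exonic coverage. Base qualities are drawn around Phred 35 and reads are
80 bp on a 100 kb contig with 20 genes — sizes chosen so the whole
benchmark runs in minutes on one CPU.

The spike-in benchmark (`run_spikein_benchmark()`) introduces 1000
designed mutations per replicate into randomly selected cells at sites
with coverage ≥ 10, by editing `round(VAF × coverage)` reads in place;
designed VAFs are genotype-consistent (0.5 heterozygous / 1.0 homozygous,
15% homozygous) because a diploid single cell cannot carry an
intermediate allele fraction. Recovery is the fraction of designed
mutations re-detected and retained by calling + filtering with default
parameters, summarized per substitution category over six seeded
replicates.

### What the fixtures do not show

The generators emulate the statistical structure of the problem, not its
full biology: no transcript-level splicing isoforms, no UMI structure, no
copy-number variation (genotype means assume a diploid locus), no
cell-cycle or batch covariates, uniform base composition, and an editing
model in which every catalogued site behaves consistently across cells.
Passing the benchmark therefore demonstrates the machinery is correct and
calibrated under these conditions; it does not certify performance on any
particular real dataset. Mutations whose observed features are genuinely
inside the editing population — heterozygous-looking T>C calls in the
middle of an editing cluster — are removed by design, which is the price
of removing the far larger editing background.

## Numerical choices

* Beta-binomial likelihoods are computed in log space via `lbeta`/
  `lchoose`; posteriors are normalized after subtracting the maximum.
* RPCA uses the standard inexact-ALM schedule: $\mu = 1.25/\sigma_1$,
  growth 1.5, dual initialized from the scaled data matrix;
  singular-value thresholding uses base `svd`.
* Hierarchical clustering ties (equal penalized silhouette) resolve to the
  smaller k; weighted-majority ties in imputation resolve to "stay
  missing"; incomparable distance pairs are set to the maximum observed
  distance for tree building only.
* All stochastic steps (simulation, SVM fold assignment, random forest)
  take explicit seeds; rerunning any stage with the same seed and inputs
  reproduces its artifacts byte for byte.

## Known limitations

Genotypes are diploid-naive (copy number shifts heterozygous means);
imputation can propagate errors inside tight neighborhoods; RPCA assumes
clone blocks are large relative to the matrix (the collapse guard exists
for exactly this reason); the SVM is only as good as the database
resources that label its training set; and spot-level inference inherits
every caveat of pooled genotypes. The refinement objective (penalized
silhouette) is one reasonable operationalization of "low-complexity clonal
structure"; alternatives (e.g. gap statistics) would be drop-in
replacements.
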