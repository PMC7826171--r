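---
title: "Methods: scanning pool-seq data for ancient balanced polymorphisms"
author: "tspscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning pool-seq data for ancient balanced polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `tspscan`, the
reasoning behind its tunable parameters and defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The problem

In high-dispersal species living in strongly heterogeneous habitats —
the motivating system is an intertidal, broadcast-dispersing barnacle
with populations in two ocean basins and a sister species as outgroup —
local adaptation is opposed by gene flow, and theory predicts that
spatially balancing selection (e.g. marginal overdominance across
microhabitats) can maintain functional polymorphism for very long
times. Its molecular footprints are: alleles older than species splits
(trans-species polymorphisms, TSPs), elevated diversity (π), a deficit
of rare alleles (Tajima's *D* > 0), excess variants at intermediate
frequencies in the folded SFS, low differentiation (F~ST~) around the
balanced site, linked nonsynonymous variation (sheltered load), and
allele trees in which haplotypes cluster by allelic class rather than
by geography. `tspscan` measures all of these from pool-seq allele
counts plus one phased genome per population and one outgroup genome.

## Inputs and coordinate conventions

Four interchange formats are read: FASTA (reference), GFF3 (gene
models), popoolation-style sync (per-pool `A:T:C:G:N:del` read counts
per site) and VCF 4.x with phased `GT` fields; trees are emitted as
newick. All of these formats are 1-based inclusive, and the package
keeps that convention internally as well: positions parsed from any
input are directly comparable to positions in any other, and interval
membership is plain `start <= pos & pos <= end`. (A 0-based half-open
internal representation was considered and rejected: every neighbouring
R/Bioconductor container is 1-based, and a conversion layer at the I/O
boundary is precisely where off-by-one errors breed in an R package.)
Boundary behaviour — first/last base of an exon, thinning at exactly
the minimum distance, H~E~ at exactly the threshold — is unit-tested.

Deletion counts in sync files are parsed but never enter any statistic
(the scan analyses SNPs). Unphased heterozygous genotypes inside a tree
window are masked rather than randomly phased, keeping allele trees
deterministic; unphased homozygotes carry no ambiguity and are kept.
When a gene has several transcripts, the one with the longest CDS is
used for synonymous/nonsynonymous annotation; a CDS whose
phase-adjusted length is not a multiple of 3 is flagged and excluded
from NS/S calls rather than silently translated.

## Estimators

Per-site diversity from reads is the unbiased average pairwise
difference among reads, `π̂ = C/(C−1)·(1 − Σ(c_a/C)²)`; it equals
brute-force enumeration of all read pairs, which the test suite checks
exhaustively for all count vectors up to coverage 30. Watterson's
`θ̂_W = S/(a_n L)` and Tajima's `D` use `n` = pool chromosome count
(2 × pooled diploids) with the classic variance constants, not a
coverage-adjusted pool-seq estimator. This is a deliberate
simplification: the scan's inferences rest on *contrasts* (TSP-bearing
vs other exons), which are invariant to a shared correction, and the
simple estimator is exactly testable against the neutral coalescent
(mean π within 3 SE of `4·Ne·µ`, mean *D* ≈ 0 over 200 replicate 10-kb
loci — both run in the acceptance suite). The cost is a small absolute
bias at finite coverage: read-level π estimates miss the finite-pool
factor `n/(n−1)`, so the pool and exact-haplotype paths agree to ~2% on
π and θ at deep coverage but *D*, which normalises a difference, is
compared on an absolute scale (±0.05) in the consistency test.

Site-wise differentiation uses the frequency form
`F_ST = (π_T − π_S)/π_T` with π~S~ the mean within-pool heterozygosity
and π~T~ from the unweighted mean of the two pools' allele frequencies,
clamped at 0 from below and undefined when π~T~ = 0.

SNP-calling filters default to: minor allele read count ≥ 2 **and**
frequency ≥ 5% within a pool (suppresses sequencing error, and matches
a common-variant panel design); usable coverage between 10× and 2× the
mean observed coverage (the upper bound guards collapsed repeats).
Sites with more than two supported alleles are excluded from TSP logic
but still contribute to π. A minor-allele tie at exactly 0.5 reports
the non-reference allele as minor (deterministic tie-break).

## TSP calling and enrichment

A site is *cosmopolitan* when it is biallelic and its minor allele
frequency is ≥ the MAF threshold in **every** focal population (any
population with failed coverage makes the site non-cosmopolitan, not an
error). A cosmopolitan site is a *TSP* when both alleles are observed
in the outgroup sample; with a single outgroup diploid, that means a
heterozygous outgroup genotype carrying the same two alleles. This is
the only criterion available under a one-outgroup-genome design; an
outgroup *pool*, if supplied, would instead require both alleles at the
min-count/MAF thresholds.

Genomic classes partition all sites with the priority
coding > 5'-UTR > 3'-UTR > intron > promoter > intergenic, the promoter
being the 1 kb immediately upstream of the TSS on the coding strand
(1 kb is the conventional default; configurable). Enrichment per class
is a two-sided Fisher exact test on the 2×2 table (TSP vs non-TSP ×
in-class vs out-of-class), odds ratio `ad/bc`, Bonferroni-corrected
across the tested classes; the test suite checks the p-value against an
independent hypergeometric-sum oracle at 10⁻¹⁰.

LD thinning (`thin_by_distance`) is greedy left-to-right per contig
with an inclusive boundary (a site exactly `min_dist` away is kept).

## Exon contrasts and the folded SFS

Per-exon statistics restrict the window estimators to the exon
interval; exon F~ST~ is the mean over all population pairs of the mean
site-wise F~ST~ (the averaging set is a free choice; all-pairs is the
symmetric one). Sheltered load is summarised as the ratio of summed
H~E~ over nonsynonymous sites to summed H~E~ over synonymous sites —
sums, not means, so an exon with no synonymous SNP yields a missing
ratio instead of a division by a noisy small denominator. Exons are
compared between groups (TSP-bearing vs other) within 250-bp length
bins up to 3 kb (last bin open-ended), with percentile bootstrap CIs
over exons; binning was chosen over smoothing because it is exactly
reproducible and trivially testable, and both groups run through one
code path (verified by a label-swap symmetry test). The folded SFS
folds to `min(p, 1−p)`, bins over (0, 0.5], and bootstraps gene
labels — the unit of resampling is the gene, not the SNP, because SNP
frequencies within a gene are strongly correlated through linkage.

## Allele trees and CPD~w–b~

For each candidate gene (≥ 1 nonsynonymous TSP), the tree window is the
TSP-bearing exon when the TSP is exonic and ±500 bp otherwise — LD in
the study system decays below 1 kb, so wider windows would dilute the
signal with recombined flanks. Haplotypes with more than half the
window masked are dropped; loci with fewer than 4 usable haplotypes or
no segregating site are skipped with a recorded reason. Distances are
p-distances with pairwise deletion; trees are neighbour-joining with
negative branch lengths clamped to 0 (keeping the cophenetic distance a
metric), rooted on the outgroup. NJ on p-distances, rather than a
likelihood tree, is deterministic, exactly consistent on additive
matrices (tested), and adequate for sub-kb windows.

The statistic is `CPD_w−b` = mean cophenetic distance of
within-population tip pairs − mean of between-population pairs,
outgroup excluded. Under phylogeography, within < between and the
statistic is negative; under ancient balancing selection, heterozygous
individuals carry both allelic classes, within-population (indeed
within-individual) pairs span the deep class split, and the statistic
is positive.

**Significance.** Two tests are computed. (1) A one-sided label
permutation test, `p = (1 + #{permuted ≥ observed})/(n_perm + 1)`,
permuting population labels over non-outgroup tips; its p-values are
verified uniform under an exchangeable star-tree null. (2) A one-sided
Welch *t* test comparing the within-pair and between-pair distance
sets. Classification uses the Welch test, Bonferroni-corrected across
tested loci, for a structural reason: with one diploid per population,
every label permutation induces a perfect matching of tips into pairs,
and any permutation that re-creates a perfect cross-class matching
(~7% of permutations at six populations) reproduces the observed
statistic almost exactly — the permutation p therefore has a hard floor
near 0.07 on exactly the trees the scan is designed to detect, and can
never reach Bonferroni significance. Worse, on a star tree with two
tips per population the within-pair *sum* is invariant across all
matchings (each tip is used exactly once), so the permutation statistic
is fully degenerate in that design. The pair-level Welch test has the
resolution the problem needs, at the cost of treating tip pairs as
exchangeable observations; it is anticonservative in absolute terms,
which is consonant with the extremely small significance thresholds
such pair-level CPD analyses report. The permutation p is kept in the
output (`p_perm`) as the honest nonparametric companion.

A locus is classified **ancient** when CPD~w–b~ > 0, the
Bonferroni-adjusted p is below α (default 0.05), and the rooted tree
violates the phylogeographic expectation (at least one ocean basin's
tips non-monophyletic); otherwise **recent**. On an unrooted tree the
monophyly check is skipped and the call flagged. The α is a scan
parameter, not a fixed constant: thresholds quoted on real datasets are
functions of their locus counts.

## The synthetic-data generator

`sim_config()` defines the study conditions; they are fixed defaults,
not tuning dials:

* six focal populations — one Pacific, five Atlantic — pooled at
  20–38 diploids each (24, 38, 30, 28, 20, 36), one sequenced diploid
  per population, one outgroup diploid;
* three-level structured coalescent: panmixia within basins, basins
  merge `t_split_oceans = 2×10⁶` generations ago, the outgroup species
  merges at `t_split_species = 9×10⁶` (one generation per year, i.e. a
  ~2 My trans-Arctic basin split and an ~8–10 My species split);
* `µ = 5×10⁻⁹`/site/generation and `Ne = 5×10⁵`, giving neutral
  diversity `θ = 4Neµ = 1%` per site — the diversity scale of large
  marine invertebrate populations;
* pool-seq observation model: per site, coverage ~ Poisson(60), each
  read copies a uniformly drawn pool chromosome, and with probability
  0.001 the base is replaced by a uniform different base;
* loci are 500-bp single-exon genes (30-bp 5'-UTR, in-frame CDS, 3'-UTR
  remainder, alternating strands) separated by 1 kb of intergenic
  sequence; no within-locus recombination (windows are sub-kb, below
  the LD decay scale).

A **balanced locus** is implanted as two allelic classes X and Y that
split `t_balanced = 9×10⁶` generations ago: class-defining sites number
Poisson(2·µ·t_balanced·L) and are carried by every Y haplotype, and
each class carries its own structured-coalescent genealogy underneath
(effective size Ne/2 per class) — a star-shaped within-class model was
rejected because it is genealogically wrong and violates infinite sites
at realistic pool sizes. Class frequencies are drawn independently per
population from [0.2, 0.8] (the signal of interest is "segregates
everywhere", not a spatial cline); both classes are always present in
every focal pool and in the outgroup diploid. Mutations follow infinite
sites: unique positions, derived base drawn uniformly from the three
alternatives.

The sequenced adult of each population is a class heterozygote with
probability `het_excess`, default 1. This parameter deserves its
rationale spelled out. Under Hardy–Weinberg pairing the expected
within-individual cross-class probability is `E[2p(1−p)] < 0.5`, while
between-population pairs cross classes with probability ≈ 0.5 — so with
random pairing the *expected* CPD~w–b~ at a balanced locus is slightly
negative, and no statistic can recover ancestral balance from the
sequenced individuals at high rates. The statistic's diagnostic
condition is the class-heterozygous adult, and the biology supplies it:
balancing selection by (marginal) overdominance acts on viability, and
with settlement-to-maturity survival of order 0.2%, surviving adults
are strongly enriched for heterozygotes. The default therefore makes
the sequenced adults heterozygous; lowering `het_excess` reproduces the
homozygote-oversampling failure mode in which genuinely balanced loci
show CPD~w–b~ < 0 — the expected behaviour for a fraction of real
candidate loci, and the reason a real scan reports both signs.

**What the generator does not emulate:** within-locus recombination
(a toggle-free simplification; real long exons would show eroded
signals, which is why the exon-length contrast exists), migration
asymmetries and clines within basins, bottlenecks and growth (so the
genome-wide *D* background is ≈ 0 here, whereas real Atlantic
populations can be negatively skewed), reference/mapping bias,
coverage heterogeneity along the genome, indels, multi-exon genes, and
multiallelic sites (infinite sites forbids them). Passing tests
therefore demonstrate correctness of the estimators and the scan logic
under the assumed statistical structure, not robustness to every real
data pathology.

## Determinism and problem sizes

One master seed fans out to every stochastic stage through
label-hashed derived seeds (`derive_seed`), so adding a stage never
perturbs earlier stages, and two runs with the same configuration are
byte-identical (tested by hashing all outputs). The test and acceptance
workloads use: the exhaustive π oracle to coverage 30; 200 replicate
10-kb neutral loci at 20 chromosomes for calibration; 20 neutral and 50
balanced loci under the full six-population design for
specificity/power; 50 + 50 loci for the age-classification recovery;
and 200 star-tree replicates at 499 permutations for the null-
uniformity check — sizes chosen so the whole suite runs comfortably on
one CPU while keeping Monte-Carlo error well inside the asserted
margins.

## Interface notes

The scan is exposed as an R API — `sim_config()`/`emit_dataset()` for
data generation, `scan_config()`/`run_scan()` returning a classed
result with `print`/`summary`/`plot` methods, plus the exported
stage functions for piecemeal use — rather than a shell CLI;
this matches how comparable R population-genetics toolkits are used,
and `scripts/acceptance.R` demonstrates full end-to-end runs from the
command line. Optional `out_dir` output writes TSV tables (TSPs,
enrichment, exon statistics, SFS, CPD results, ranked candidates),
per-candidate newick trees and a JSON run summary, each stamped with
the package version, thresholds and seed.

## Known limitations

Pool-seq frequency thresholds use point estimates (no binomial CI on
read frequencies), keeping calls deterministic at the cost of noisier
behaviour near thresholds at low coverage. θ/D use the classic
constants rather than pool-aware corrections (see above). The Welch
pair test is anticonservative in absolute terms; interpret adjusted
p-values as a ranking device backed by the CPD sign and the topology
check, and consult `p_perm` for a conservative companion. The NS/S
annotator uses the longest transcript only and the standard genetic
code. The enrichment stage inherits whatever ascertainment the SNP
discovery filters impose.
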