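---
title: "Genome-resolved metaproteomic profiling: models and methods"
author: "gutMetaproteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved metaproteomic profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutMetaproteome)
```

## The problem

Shotgun metaproteomics of developing gut communities measures tens of
thousands of MS/MS spectra per fecal sample and matches them against a
protein database predicted from genome bins assembled out of matched
metagenomes, plus a human protein background. Turning those
peptide-spectrum matches (PSMs) into interpretable biology requires a chain
of inferences: controlling the false discovery rate with a decoy database,
collapsing indistinguishable proteins into groups, distributing spectra of
shared peptides, normalizing across runs, attributing groups to
species/strain genome bins, aggregating to orthologous groups for
cross-sample comparison, and finally scoring gut metabolic modules (GMMs)
to describe each community's investment in nutrient utilization and
short-chain fatty acid (SCFA) metabolism. This package implements that
chain end to end, together with a seed-controlled simulator so that every
stage can be validated against known ground truth.

## The simulator: what it emulates, and what it does not

`generateCommunity()` builds genome bins of random protein sequences
(uniform over the twenty amino acids, 80–600 residues, N-terminal M), a
human protein background in which roughly a third of proteins are ~95%
identical isoforms of another (so the 90%-identity human grouping rule has
work to do), and a controlled number of proteins duplicated byte-identically
into a second bin, emulating indistinguishable proteins of closely related
strains. Every microbial protein carries exactly one ortholog id; a fixed
share of per-bin protein slots carries a community-wide "core" id so that
conserved-function analyses have a non-trivial core.

`simulateAbundanceTrajectories()` drives per-bin relative abundances with a
log-normal random walk (default step SD 0.35 per sampling interval, drift
0), renormalized per sample, and interpolates the human spectral fraction
linearly over day of life (default 0.8 at the first sample down to 0.2 at
the last, matching the observed decline of host-derived spectra as
microbial colonization proceeds).

`simulatePsmTables()` draws a configurable number of spectra per run (two
technical replicates per sample by default). Each spectrum is a correct
target match with probability `1 - 2 * decoyRate`, an incorrect target
match with probability `decoyRate`, or a decoy match with probability
`decoyRate`. Correct matches sample peptides proportionally to owner
abundance times a per-peptide detectability weight, drawn once per peptide
from a log-normal with log-SD 0.5 — unequal peptide response without
modeling spectra. Decoy and incorrect matches draw scores from a standard
normal; correct matches from the same distribution shifted by +2 SD, so a
2% FDR threshold is neither trivial nor unattainable. The incorrect-target
rate equals the decoy rate by design: that is the equal-split assumption
under which the concatenated target-decoy estimator `#decoys/#targets` is
unbiased, and it is what makes the realized false-discovery proportion
measurable against the exported per-spectrum truth labels.

The simulator deliberately omits: spectrum-level detail (m/z, retention
time), chimeric spectra, post-translational modifications, mass-range
filtering of peptides, and any organism-specific codon or length structure.
Passing tests therefore demonstrate that the *inference chain* is correct
under a realistic sampling model — not that any particular biological
dataset would be recovered with the same fidelity.

Tryptic digestion follows the standard rule — cleave after K or R except
before P — with up to two missed cleavages and peptide length 6–50 by
default. Validation accepts the extended amino-acid alphabet (including
ambiguity codes B, Z, X and the rare U, O, J); anything else is rejected
with the offending accession named.

## FDR filtering

`filterPsmsByFdr()` sorts by descending score and keeps the largest prefix
in which `#decoys / #targets <= threshold` (the threshold is inclusive; the
default 0.02 is the conventional PSM-level operating point of this kind of
study). Decoys sort before targets within tied scores, which makes the
boundary conservative. Filtering is per run by default — each run's score
distribution is its own — with a `global = TRUE` switch to pool. Decoy rows
are removed from the output; the per-run totals of *collected* spectra are
retained because they, not the retained counts, are the normalization
denominators downstream.

## Protein grouping and quantification

Microbial proteins group at 100% identity: classes of byte-identical
sequences, which merges identical proteins shared across related strains.
Human proteins group at 90% identity by greedy centroid clustering:
sequences are visited in order of decreasing length (ties broken by
accession, so the procedure is deterministic), and each joins the first
centroid whose global-alignment identity — matches over alignment length,
gaps included, scored +1 match / −1 mismatch with default affine gap
penalties — reaches the threshold, else it founds a new centroid. Exact
all-pairs clustering was rejected for cost; greedy centroid clustering with
a fixed visiting order is the standard cheap approximation and is
idempotent on the resulting representatives.

Groups need at least two distinct peptide sequences to survive
(`buildPeptideGraph()`); charge and modification variants are collapsed to
the bare sequence before counting. Spectral counts of peptides unique to
one group accrue fully to it; a peptide shared by *k* groups splits its
spectra proportionally to the groups' unique counts in that run, or equally
(1/k) when none has unique evidence (`balanceSharedSpectralCounts()`). This
conserves the per-run total exactly, which the tests assert to 1e-9.
Normalization divides by the run's total collected spectra; per-sample
values are the arithmetic mean over the sample's technical replicates. Both
the per-run and the replicate-averaged matrices are kept, because
run-level profiles are what correlation clustering operates on.

## Taxonomic and functional profiles

Groups map to bins through their members; multi-bin groups get a merged
`binA+binB` label and are reported under it, not split — mirroring how
indistinguishable strains are treated in genome-resolved studies. Microbial
taxon fractions normalize within the microbial compartment; the human
fraction is human over total. The Shannon index uses the natural log (the
conventional choice when no base is stated) and is computed with vegan.
Proteome coverage counts a bin's *predicted proteins* seen in surviving
groups — so each member of a two-member identical-sequence group counts for
its own bin — divided by the bin's predicted proteome size.

Ortholog aggregation annotates each group by majority vote over member
annotations (ties: lexicographically smallest id); groups with no annotated
member fall into a reserved `UNANNOTATED` row that set analyses exclude.
Presence for conserved-function sets is strictly positive abundance in a
sample (either replicate). Clustering uses Spearman correlation (average
ranks) with complete linkage on `1 - rho`, cut to exactly *k* clusters
(default 7, configurable); being rank-based it is invariant to monotone
transforms of abundance, which the tests check.

## Differential abundance between clusters

Counts are scaled to a common effective library size (library size × TMM
factor; TMM delegates to edgeR, with the hand-coded published recipe kept
as an independent oracle in the test suite), shifted by a 0.5 pseudo-count
and log2-transformed. For each cluster pair the per-row statistic is a
studentized difference of group means: the denominator is the pooled
standard error plus a stabilizer (the median pooled SE across rows), which
protects near-constant rows. Group labels are permuted — exhaustively when
the label space fits the permutation budget, sampled otherwise — and
two-sided p-values are read off a null *pooled across rows*.

Pooling is a deliberate design choice. With six runs per cluster the label
space holds only 924 assignments, so per-row p-values cannot go below
2/924 ≈ 0.002; after Benjamini-Hochberg adjustment across a thousand rows
no row could ever reach q < 0.05 and the test would have zero power at any
realistic effect size. Because the statistic is studentized it is
approximately pivotal across rows, so pooling preserves calibration (the
type-I rate at p < 0.05 sits within [0.03, 0.07] in the null simulations)
while restoring resolution of about 1/(rows × permutations). The reported
effect is the difference of mean log2 normalized counts, i.e. a log2 fold
change; per-pair top tables list the 25 most significant rows at p < 0.01.

## Module scoring

A gut metabolic module is an ordered series of steps, each satisfiable by
alternative orthologs. Alternatives within a step combine by sum; coverage
is the fraction of steps with positive abundance; module abundance is the
median over detected step abundances (configurable to mean or sum — the
median is the robust convention for reference-module frameworks, which do
not publish a single canonical aggregation). A module is retained when
coverage reaches the cutoff, default 0.556 — the operating point reported
for gut communities of this kind; the cutoff is an explicit parameter
because the optimal-cutoff inference of the original web service is not
reproduced here. Category profiles divide the summed abundance of retained
modules by the number of modules *mapped* to the category (unretained
modules count in the divisor — the literal definition), separately for the
nutrient triple (carbohydrate, amino acid, lipid) and the SCFA triple
(acetate, propionate, butyrate); tri-plot coordinates are the barycentric
normalization of each triple, undefined (flagged, NA) when all three are
zero.

Per-taxon module attribution restricts the group matrix to one taxon at a
time before aggregation and scoring, so per-taxon step abundances sum to
the community step abundance exactly.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds; stage seeds derive from
  a root seed and stay below 2^31. Identical seeds give byte-identical
  fixture bundles.
* Conservation of balanced counts, truth abundance normalization, TMM
  geometric-mean-1, and barycentric sums are asserted at 1e-9.
* FDR is inestimable without decoys (or without targets): an error, not a
  guess. Zero-variance vectors make Pearson correlation an error. A sample
  with no microbial signal yields an empty profile with a warning flag
  rather than NaN fractions.
* Clusters with fewer than two runs are skipped (with a warning) in
  differential testing; a constant run is an error in Spearman clustering,
  naming the run.

## Problem sizes used in the checks

The validation suite simulates at desk scale, chosen so that the stochastic
criteria are comfortably identifiable: FDR calibration uses 20 replicates
of 50,000 PSMs; abundance recovery a 10-bin community at 100,000 spectra
per run; clustering recovery 3 planted archetypes × 6 runs over 20 seeds;
differential calibration 20 null simulations of 1000 rows at 6 vs 6 runs.
The end-to-end example bundle uses two infants, three samples each, two
replicates, 3000 spectra per run.

## Known limitations

* The realized human spectral fraction tracks, but does not equal, the
  configured fraction: spectra sample peptides proportionally to owner
  abundance × detectability, so the realized fraction also reflects the
  relative sizes of the human and microbial peptide universes. Trajectory
  *shape* (the decline) is faithfully recovered; the tests assert the sign
  of the slope, not the intercept.
* Greedy centroid clustering depends on the visiting order; the order is
  fixed (length, then accession) for reproducibility, not optimality.
* The edgeR quasi-likelihood F-test that motivated the TMM normalization is
  replaced by the permutation test described above; coefficient-level
  replication of the GLM is out of scope.
* No protein-level FDR control beyond the two-peptide rule; no
  match-between-runs; no modification-aware peptide handling.
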