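---
title: "Profiling bai operon abundance in gut metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling bai operon abundance in gut metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baiprofiler)
```

## The biological problem

Secondary bile acids (SBAs) such as deoxycholate (DCA) are produced from
host-derived primary bile acids (PBAs, e.g. cholate, CA) by a small number of
gut bacteria carrying the bile acid-inducible (*bai*) operon, an eight-gene
cluster encoding the 7α-dehydroxylation pathway. A stool sample whose DCA:CA
ion-abundance ratio falls below 1 is *SBA-deficient* — a state enriched in
inflammatory bowel disease. Because untargeted metabolomics gives only
relative ion abundances, the DCA:CA ratio (rather than absolute
concentrations) is the phenotype of interest, binarized at ratio 1 with ties
assigned to the low-SBA class (the high class is defined by *strictly* more
DCA than CA; exact ties have measure zero in real intensity data).

This package estimates the relative abundance of the *bai* operon in shotgun
metagenomes, clusters the bai-carrying reference genomes into operon-level
sequence clusters, and provides the statistics linking operon abundance to
the bile acid phenotype, to diagnosis, and to engraftment dynamics in fecal
microbiota transplantation (FMT).

## The abundance estimator

Reads are quality-trimmed, then translated in all six frames and searched
against an amino-acid reference of bai genes. A read is assigned to its
single best reference hit (highest alignment score) provided the alignment
reaches **90% identity over at least 25 amino acids**. Per gene family
$g$, the relative abundance in a sample is

$$\hat a_g = \frac{n_g}{N},$$

where $n_g$ is the number of best-hit reads on family $g$ (pooled across
reference genomes) and $N$ the number of QC-passed reads. The operon-level
abundance is the geometric mean across the eight families,

$$\hat A = \Big(\prod_{g=1}^{8} \max(\hat a_g, 10^{-9})\Big)^{1/8},$$

with zero fractions floored at the pseudocount $10^{-9}$ **at the fraction
level**, so $\hat A$ is always positive and log-transforms are finite. The
geometric mean deliberately punishes uneven profiles: reads on a single
family (e.g. a shared homolog) cannot produce a high operon abundance, while
a genuine operon yields reads on all eight families. The same rule, applied
to the per-cluster best-hit counts, gives per-cluster abundances; a cluster
counts as *detected* in a sample when at least four of its eight families
received at least one read.

## Reference database and operon clustering

The reference is built from a curated seed set of bai amino-acid sequences
(headers `seqid|genome|family`) extended with ORF sets from candidate
genomes. An ORF joins family $g$ when it aligns to a family-$g$ seed at
**≥ 70% identity** over **≥ 70% of the family's 90th-quantile alignment
length**, and a genome joins the reference when it contributes matches to
**at least four of the eight families**. Choices fixed for reproducibility:

* quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7);
* the q90 length is computed over all recorded seed-vs-ORF hits of that
  family (the population over which the quantile is taken is otherwise
  underdetermined);
* an ORF matching several families keeps its best-identity family, ties
  broken by lexicographic family name; a genome contributing two ORFs for
  one family keeps the higher-identity one.

Genome pairs are compared by the **operon-averaged identity**: per shared
family, the local alignment's matching residues and alignment length are
pooled, and identity = total matches / total aligned length. Pairs in which
less than **80%** of the total bai sequence length aligns are excluded; the
denominator of that coverage is the *mean* of the two genomes' summed bai
lengths — a symmetric choice among several defensible ones. Genomes are then
clustered at **90% averaged identity** by single linkage (connected
components of the thresholded pair graph). Single linkage was chosen because
the clustering rule is stated only as a threshold: connected components need
no further parameters, are order-independent, and are easy to verify against
exhaustive reachability. Cluster ids are canonicalized by each cluster's
smallest member genome id, so output is invariant to input order.

## The alignment backend

All protein alignments go through one pluggable contract
(`align_protein()`): best local alignment with identity, length, match count
and score. The built-in backend is an affine-gap Smith-Waterman
(BLOSUM62, gap open 11, extend 1 — the default scoring of the translated
search tools this workflow replaces), implemented in compiled code with an
exact amino-acid k-mer prescreen (k = 6) in front of the dynamic program for
read mapping. Identity is matching residues divided by alignment length
*including gap columns*. Stop codons are scored prohibitively, so a local
alignment never crosses a stop — each inter-stop segment of a reading frame
is effectively aligned independently. Equal-score best hits resolve to the
lexicographically smallest reference sequence id, making mapping output
independent of hash or input order.

Two caveats are worth knowing. Co-optimal local alignments are genuinely
ambiguous: different tracebacks of the same optimal score can differ
slightly in match count (for instance around zero-scoring terminal mismatch
columns), so identity comparisons across implementations are only meaningful
where the optimum is unique. And the k-mer prescreen requires one exact
6-mer match; for reads at the 90% identity threshold this is comfortably
sensitive (mismatches would need to occur every ≤ 6 residues along the whole
alignment to defeat it), and simulated reads are error-free, but it is a
heuristic, as in any seeded search tool.

## Quality control

Reads are trimmed 3′-trailing at Q20, then clipped at the start of the first
4-base window whose mean quality drops below 20, and finally dropped when
shorter than 75 bases — in that order, matching the order of the parameter
string of the trimmer this replaces. The window rule here clips at the
window start and does not re-scan within the failing window; that
sub-window refinement of some trimmers changes nothing scientifically and
the simpler rule is unambiguous and exactly testable. Phred+33 is assumed;
scores that can only arise from Phred+64 input raise an error. Host-read
removal is an interface: a predicate flags reads to drop, and the default
predicate flags nothing (synthetic data contains no host reads).

## The statistics layer

* **Phenotype association.** Mann-Whitney U between operon abundances of the
  high- and low-SBA classes, two-sided, normal approximation with tie
  correction. The ROC AUC is U divided by the product of the group sizes,
  with U counting pairs in which the high-class value exceeds the low-class
  value (ties 1/2).
* **Diagnosis association.** Pearson chi-square on the diagnosis × phenotype
  table, expected counts from the margins; continuity correction only for
  2×2 tables (the diagnosis design is 3×2, dof = 2).
* **Cluster correlations.** Spearman rank correlation of log10 per-cluster
  abundances (pseudocount-floored, so logs are finite), p-values from the t
  approximation; Theil-Sen fits (median of pairwise slopes, median residual
  intercept) for robust trend lines.
* **FMT.** Per subject, fold change = geometric mean of post-FMT operon
  abundances / geometric mean of pre-FMT abundances; association with the
  supplied clinical-response flag again by Mann-Whitney AUC. Response is an
  input, never computed from clinical scores.
* No multiple-testing correction is applied anywhere; p-values are reported
  raw.

## What the synthetic data emulates

`sim_config()` defines the simulated study conditions; the generator
produces every input the pipeline consumes with full ground truth (every
read traceable to its source gene, every sample to its true abundances and
phenotype state).

**Reference sets** are simulated on a star phylogeny: per family, a root
sequence, cluster ancestors mutated at the between-cluster rate (default
0.30), genomes mutated from their ancestor at the within-cluster rate
(default 0.05), giving expected within-cluster identity ≈ 1 − 2·0.05 = 0.90
— deliberately at the clustering threshold by default; cluster-recovery
analyses use 0.02, which separates cleanly. Nucleotide templates come from
seeded reverse translation with uniform codon choice (no codon bias: reads
only need to be translatable, not mimetic of real genomes).

**Reads** are in-frame fragments of those templates at random offset and
strand, plus background reads of i.i.d. uniform nucleotides — under which a
spurious hit at ≥ 90% identity over ≥ 25 aa has vanishing probability, as
confirmed by the zero background mapping rate in the tests. Sequencing
error is off by default so threshold behaviour can be tested with explicitly
constructed substitutions. Qualities are flat per read: passing reads at
Q30-40, a configurable fraction at Q5-15 that fails the window trim. The
trimming rules are exercised on structured quality profiles in the unit
tests; the simulated cohorts only need pass/fail control.

**Cohorts.** Each of 100 samples receives a diagnosis (CD/UC/nonIBD in equal
expected proportions) and carries the operon with probability 0.70 / 0.84 /
0.96 respectively — mirroring the observation that SBA-deficiency
(≈ carriage loss) is common in CD, intermediate in UC, rare in controls.
Carriers fall into one of two mutually exclusive community states: a
healthy-like state in which clusters 1 and 2 co-occur (probability 0.90 in
nonIBD, 0.50 in UC, 0.25 in CD) and an IBD-like state carrying cluster 3
alone. This reproduces the qualitative structure reported for real cohorts —
two positively correlated clusters prevalent in controls, one anti-coupled
cluster prevalent in patients — and the tests verify exactly that sign
pattern is recovered from reads.

**Scaling.** Real gut metagenomes have > 10⁷ reads per sample and carrier
abundances spanning roughly 10⁻⁸–10⁻⁵ per gene; at package-test scale the
cohorts use 5,000 reads per sample with carrier per-gene abundances
log-uniform on 10⁻³–5·10⁻³, preserving the expected per-gene read counts
(≈ 5–25) of a deeply sequenced carrier. Non-carriers have zero bai
abundance and estimate at the pseudocount floor. The phenotype threshold
keeps its natural-scale default of 10⁻⁷ true operon abundance: carriers sit
far above it, non-carriers below, reproducing the bimodal, threshold-like
relationship between operon abundance and the DCA:CA ratio. What this
scaling does *not* exercise is the regime of barely-detectable carriers near
the sequencing detection limit, where estimator noise rather than phenotype
noise dominates — conclusions about that regime require depth the test
conditions deliberately do not simulate.

**Phenotype noise.** log10(DCA:CA) is drawn as N(±1, `phenotype_noise_sd`),
positive mean above the abundance threshold. The default sd is 0 (noiseless
coupling). For noisy-cohort analyses the package uses sd = 0.55, calibrated
once so that a few percent of samples fall on the wrong side of ratio 1:
enough mislabeling that discrimination is visibly imperfect, not so much
that the phenotype stops being abundance-driven. With ~83% of samples
carrying the operon, mislabeled carriers dominate the AUC loss (each costs
≈ 0.02 AUC), so the 10-cohort mean AUC concentrates around 0.90-0.95.

**FMT cohorts** are simulated at the abundance level: engrafters go from the
pseudocount floor (10⁻⁹, i.e. zero pre-FMT counts) to 10⁻⁶ post-FMT (fold
change 10³), non-engrafters stay flat at 10⁻⁷, donors sit at 10⁻⁵ — above
the patients' pre-FMT mean, as in real FMT data. Clinical response agrees
with engraftment with configurable probability (default 1). The read-level
machinery is already exercised by the cohort pipeline; FMT adds only the
fold-change and association logic, which operates on abundances.

## Problem sizes and determinism

The shipped analyses use: 6-genome reference sets (3 clusters × 2 genomes)
for clustering recovery; 20 replicate communities of 10⁵ reads at per-gene
abundance 10⁻³ for estimator recovery (per-family estimates within 3 Poisson
SD of truth in ≥ 95% of replicate×family observations); 100-sample cohorts of
5,000 reads for phenotype discrimination; 10 subjects × 2 samples per phase
for FMT; 1,000 label permutations for the FMT null. These sizes were chosen
so every analysis is exactly reproducible on a single CPU while keeping
expected counts in the regime the estimator targets.

All randomness is seeded: identical `sim_config()` (including `seed`) gives
byte-identical FASTA/FASTQ/TSV outputs, and `run_pipeline()` writes its
tables with fixed formatting so reruns can be compared by checksum.

## Known limitations

* The simulator models neither insert-size distributions, per-base error
  profiles, codon usage bias nor realistic community composition; it is a
  ground-truth harness for the pipeline's logic, not a sequencing emulator.
* Single best-hit assignment cannot resolve reads equally close to two
  reference clusters; at the simulated divergences this is immaterial, but
  for real references with near-identical clusters, per-cluster counts
  near the 90% clustering boundary are soft.
* The clustering rule (single linkage at 90%) can chain clusters through
  intermediates; with real, densely sampled references a different linkage
  could split differently. The pair table is exported so alternatives can
  be applied downstream.
* Paired-end structure is ignored: every QC-passed read counts once in the
  denominator, mates are not merged.
* Host-read removal is a stub by design; plug in a real host filter for
  human stool data.
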