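# baiprofiler

Gut bacteria carrying the eight-gene bile acid-inducible (*bai*) operon
convert primary bile acids (cholate, CA) into secondary bile acids
(deoxycholate, DCA) by 7α-dehydroxylation. Only a handful of taxa encode
this pathway, so when they are lost — as happens in a sizeable minority of
IBD patients — the stool DCA:CA ratio collapses below 1 ("SBA-deficient").
`baiprofiler` is an R package for researchers who want to measure that
functional capacity directly from shotgun metagenomes: it estimates *bai*
operon abundance from reads, resolves which operon sequence cluster carries
it, and links the abundance to the bile acid phenotype, to diagnosis, and to
engraftment in fecal microbiota transplantation (FMT).

## The estimator

Quality-trimmed reads (MINLEN 75, trailing Q20, sliding window 4:Q20) are
translated in six frames and searched against an amino-acid reference of
*bai* genes with a built-in affine-gap Smith-Waterman backend (BLOSUM62,
gap open 11 / extend 1, exact 6-mer prescreen). Each read keeps its single
best hit at ≥ 90% identity over ≥ 25 aa. With `n_g` best-hit reads on family
`g` and `N` QC-passed reads, the operon abundance is the geometric mean of
the per-family fractions with a pseudocount floor:

    A = ( prod_g max(n_g / N, 1e-9) )^(1/8)

Reference genomes are clustered at 90% operon-averaged amino-acid identity
(sum of matching residues / sum of alignment lengths across shared families,
pairs with < 80% of the total bai length aligned excluded; single linkage),
and the same estimator applied per cluster gives per-cluster abundances,
with a cluster *detected* when ≥ 4 of its families receive reads. The
statistics layer provides the DCA:CA phenotype binarization (high-SBA iff
DCA/CA > 1), Mann-Whitney U with AUC = U/(n1·n2), chi-square association,
Spearman correlations, Theil-Sen fits, and per-subject FMT fold changes
(geometric-mean post / geometric-mean pre).

A synthetic-data module generates references, reads, metabolomes and FMT
cohorts with known ground truth, so the entire pipeline is testable without
any downloads.

## Worked example

Simulate a reference of 3 operon clusters (2 genomes each), cluster it,
generate a 20,000-read sample in which clusters 1 and 2 carry the operon at
per-gene abundances 5e-4 and 2e-4, and profile it:

```r
library(baiprofiler)

cfg <- sim_config(seed = 42, n_clusters = 3, genomes_per_cluster = 2,
                  within_cluster_divergence = 0.02, n_reads = 20000L,
                  cluster_abundances = c("1" = 5e-4, "2" = 2e-4))
ref        <- generate_reference_operons(cfg)
pairs      <- pairwise_operon_identity(ref$db)
assignment <- cluster_genomes(pairs, genomes = unique(ref$db$genome_id))
db         <- assign_db_clusters(ref$db, assignment)

sim  <- generate_community_reads(cfg, ref$truth, sample_id = "demo")
tmp  <- tempfile(fileext = ".fastq"); write_sim_fastq(sim$reads, tmp)
qc   <- qc_pipeline(read_fastq(tmp))
hits <- map_reads(qc$reads, db)
prof <- sample_profile("demo", hits, qc$report$passed_reads,
                       clusters = sort(unique(assignment)))
prof
#> bai sample profile: demo
#>   QC-passed reads: 20000
#>   mapped reads: 130
#>   operon abundance: 0.0008002
#>   detected clusters: 1, 2
prof$clusters
#>   cluster_id n_families_detected detected operon_abundance
#> 1          1                   8     TRUE     0.0005458654
#> 2          2                   8     TRUE     0.0002412756
#> 3          3                   0    FALSE     0.0000000010
```

The estimates recover the configured truth: cluster 1 at ≈ 5e-4, cluster 2
at ≈ 2e-4, the total ≈ 7-8e-4, and the absent cluster 3 at the 1e-9
pseudocount floor with its detected flag off. Discrimination of a phenotype
from such abundances uses the AUC helper:

```r
mwu_auc(c(1e-9, 1e-9, 2e-9), c(3e-4, 5e-4, 7e-4))
#> $statistic 9   $auc 1   (low- vs high-SBA samples fully separated)
```

`run_pipeline(sim_config(seed = 1))` runs the whole chain — reference,
clustering, 100 simulated samples, QC, mapping, profiles, metabolome,
statistics — and optionally writes every table as TSV.

A command-line wrapper for profiling a single FASTQ against a reference DB
ships in `inst/scripts/profile_sample.R`.

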