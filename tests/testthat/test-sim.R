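test_that("minimal reference: one cluster, one genome, eight sequences", {
  cfg <- sim_config(seed = 50, n_clusters = 1, genomes_per_cluster = 1)
  ref <- generate_reference_operons(cfg)
  expect_equal(nrow(ref$db), 8L)
  expect_setequal(ref$db$family, bai_families())
  expect_equal(nchar(ref$db$sequence), rep(300L, 8))
  # nucleotide templates translate back to the amino-acid sequences
  refs <- ref$truth$refs
  for (i in 1:2) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(refs$nt_sequence[i])))
    expect_equal(aa, refs$sequence[i])
  }
})

test_that("zero within-cluster divergence gives identical in-cluster genes", {
  cfg <- sim_config(seed = 51, n_clusters = 2, genomes_per_cluster = 3,
                    within_cluster_divergence = 0)
  ref <- generate_reference_operons(cfg)
  refs <- ref$truth$refs
  for (k in 1:2) for (f in c("baiA", "baiH")) {
    s <- refs$sequence[refs$cluster_id == k & refs$family == f]
    expect_equal(length(unique(s)), 1L)
  }
})

test_that("divergence beyond the clustering threshold warns", {
  cfg <- sim_config(seed = 52, within_cluster_divergence = 0.10)
  expect_warning(generate_reference_operons(cfg), "90%")
})

test_that("reference generation is deterministic in the seed", {
  cfg <- sim_config(seed = 53)
  a <- generate_reference_operons(cfg)
  b <- generate_reference_operons(cfg)
  expect_identical(a$db, b$db)
  expect_identical(a$truth$refs, b$truth$refs)
})

test_that("pure background communities produce no bai hits", {
  cfg <- sim_config(seed = 54, n_clusters = 1, genomes_per_cluster = 1,
                    n_reads = 500L, background_fraction = 1.0)
  ref <- generate_reference_operons(cfg)
  sim <- generate_community_reads(cfg, ref$truth, "S1")
  expect_true(all(sim$sources$origin == "background"))
  hits <- map_reads(list(read_id = sim$reads$read_id,
                         sequence = sim$reads$sequence), ref$db)
  expect_equal(nrow(hits), 0L)
})

test_that("read sets differ across seeds but share expected composition", {
  cfg <- sim_config(seed = 55, n_clusters = 1, genomes_per_cluster = 1,
                    n_reads = 2000L, cluster_abundances = c("1" = 0.01))
  ref <- generate_reference_operons(cfg)
  a <- generate_community_reads(cfg, ref$truth, "S1", seed = 1)
  b <- generate_community_reads(cfg, ref$truth, "S1", seed = 2)
  a2 <- generate_community_reads(cfg, ref$truth, "S1", seed = 1)
  expect_identical(a, a2)
  expect_false(identical(a$reads$sequence, b$reads$sequence))
  # both draws hover around the expected 8 * 0.01 * 2000 = 160 bai reads
  for (s in list(a, b)) {
    nb <- sum(s$sources$origin == "bai")
    expect_gt(nb, 100)
    expect_lt(nb, 230)
  }
})

test_that("every non-background read is traceable to a real source gene", {
  cfg <- sim_config(seed = 56, n_clusters = 2, genomes_per_cluster = 1,
                    n_reads = 300L,
                    cluster_abundances = c("1" = 0.02, "2" = 0.02))
  ref <- generate_reference_operons(cfg)
  sim <- generate_community_reads(cfg, ref$truth, "S1")
  src <- sim$sources[sim$sources$origin == "bai", ]
  expect_true(all(src$genome_id %in% ref$truth$refs$genome_id))
  expect_true(all(src$family %in% bai_families()))
  # sequences of bai reads occur in (either strand of) their source gene
  idx <- match(paste(src$genome_id, src$family, sep = "_"),
               ref$truth$refs$sequence_id)
  for (i in seq_len(min(20, nrow(src)))) {
    r <- sim$reads$sequence[sim$reads$read_id == src$read_id[i]]
    template <- ref$truth$refs$nt_sequence[idx[i]]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    expect_true(grepl(r, template, fixed = TRUE) ||
                  grepl(rc, template, fixed = TRUE))
  }
})

test_that("low-quality read fraction fails trimming as configured", {
  cfg <- sim_config(seed = 57, n_clusters = 1, genomes_per_cluster = 1,
                    n_reads = 2000L, background_fraction = 1.0,
                    low_quality_fraction = 0.2)
  ref <- generate_reference_operons(cfg)
  sim <- generate_community_reads(cfg, ref$truth, "S1")
  qc <- qc_pipeline(reads_as_list(sim$reads))
  expect_equal(qc$report$dropped_short, sum(sim$sources$low_quality))
  expect_equal(qc$report$passed_reads, sum(!sim$sources$low_quality))
})

test_that("abundances that cannot sum with background are rejected", {
  expect_error(sim_config(cluster_abundances = c("1" = 0.2)), "sum")
  expect_error(sim_config(within_cluster_divergence = 1.5), "0, 1")
})

test_that("noiseless metabolome follows the threshold rule exactly", {
  cfg <- sim_config(seed = 58, phenotype_noise_sd = 0)
  truth <- data.frame(sample_id = sprintf("S%d", 1:6),
                      true_operon_abundance = c(0, 1e-8, 5e-8, 2e-7, 1e-6,
                                                1e-4))
  met <- generate_metabolome(truth, cfg)
  lab <- ba_phenotype(met$dca, met$ca)
  expect_equal(lab, ifelse(truth$true_operon_abundance > 1e-7,
                           "high_SBA", "low_SBA"))
  # all below threshold: everything low
  met2 <- generate_metabolome(
    data.frame(sample_id = "a", true_operon_abundance = 1e-9), cfg)
  expect_equal(ba_phenotype(met2$dca, met2$ca), "low_SBA")
})

test_that("metabolome separation yields AUC 1 against the label", {
  cfg <- sim_config(seed = 59, phenotype_noise_sd = 0.05)
  truth <- data.frame(sample_id = sprintf("S%d", 1:100),
                      true_operon_abundance = c(rep(1e-8, 50), rep(1e-5, 50)))
  met <- generate_metabolome(truth, cfg)
  lab <- ba_phenotype(met$dca, met$ca)
  r <- mwu_auc(truth$true_operon_abundance[lab == "low_SBA"],
               truth$true_operon_abundance[lab == "high_SBA"])
  expect_equal(r$auc, bf_auc(truth$true_operon_abundance[lab == "low_SBA"],
                             truth$true_operon_abundance[lab == "high_SBA"]))
  expect_equal(r$auc, 1.0)
})

test_that("fmt cohort couples engraftment to response and fold change", {
  cfg <- sim_config(seed = 60, fmt_n_subjects = 10, fmt_engraft_fraction = 0.5,
                    fmt_response_coupling = 1)
  cohort <- generate_fmt_cohort(cfg)
  expect_length(cohort, 10L)
  folds <- vapply(cohort, fmt_fold_change, 0)
  resp <- vapply(cohort, `[[`, NA, "response")
  eng <- vapply(cohort, `[[`, NA, "engrafted")
  expect_equal(resp, eng)
  expect_equal(sum(eng), 5L)
  # engrafters: pseudocount floor 1e-9 to 1e-6 = fold 1e3; others flat
  expect_equal(unname(folds[eng]), rep(1e3, 5))
  expect_equal(unname(folds[!eng]), rep(1.0, 5))
  # donors sit above the patients' pre-FMT abundances
  donor <- attr(cohort, "donor_abundances")
  expect_gt(mean(donor), mean(unlist(lapply(cohort, `[[`, "pre"))))
})
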