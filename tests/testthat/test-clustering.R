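test_that("operon identity pools matches and lengths across families", {
  set.seed(40)
  f1a <- random_aa(100)
  f1b <- substitute_at(f1a, round(seq(5, 95, length.out = 10))) # 90/100
  f2a <- random_aa(100)
  f2b <- substitute_at(f2a, round(seq(7, 93, length.out = 5)))  # 95/100
  db <- new_bai_refdb(data.frame(
    sequence_id = c("A_f1", "A_f2", "B_f1", "B_f2"),
    genome_id = c("A", "A", "B", "B"),
    family = c("baiA", "baiB", "baiA", "baiB"),
    origin = "seed_set",
    sequence = c(f1a, f2a, f1b, f2b), stringsAsFactors = FALSE))
  pr <- pairwise_operon_identity(db)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$total_matching, 185L)
  expect_equal(pr$total_aligned, 200L)
  expect_equal(pr$averaged_identity, 0.925)
  expect_false(pr$excluded)
  # a genome against itself scores identity 1 at full coverage
  pr2 <- pairwise_operon_identity(new_bai_refdb(data.frame(
    sequence_id = c("A_f1", "A2_f1"), genome_id = c("A", "A2"),
    family = "baiA", origin = "seed_set", sequence = f1a,
    stringsAsFactors = FALSE)))
  expect_equal(pr2$averaged_identity, 1.0)
  expect_equal(pr2$coverage, 1.0)
})

test_that("pairs with insufficient aligned coverage are excluded", {
  set.seed(41)
  fams <- bai_families()
  seqs <- vapply(1:8, function(i) random_aa(300), "")
  a <- data.frame(sequence_id = paste0("A_", fams), genome_id = "A",
                  family = fams, origin = "seed_set", sequence = seqs,
                  stringsAsFactors = FALSE)
  b <- data.frame(sequence_id = paste0("B_", fams[1:3]), genome_id = "B",
                  family = fams[1:3], origin = "seed_set",
                  sequence = seqs[1:3], stringsAsFactors = FALSE)
  pr <- pairwise_operon_identity(new_bai_refdb(rbind(a, b)))
  # 3 shared families x 300 aa aligned over mean(2400, 900) total length
  expect_equal(pr$total_aligned, 900L)
  expect_equal(pr$coverage, 900 / 1650)
  expect_true(pr$excluded)
})

test_that("single linkage chains clusters through intermediate genomes", {
  pairs <- data.frame(
    genome_a = c("A", "B", "A"), genome_b = c("B", "C", "C"),
    averaged_identity = c(0.92, 0.92, 0.85),
    coverage = 1, excluded = FALSE, stringsAsFactors = FALSE)
  asg <- cluster_genomes(pairs)
  expect_equal(length(unique(asg)), 1L)
  # without the bridge, A-C alone do not merge
  asg2 <- cluster_genomes(pairs[pairs$genome_b != "B" &
                                  pairs$genome_a != "B", ],
                          genomes = c("A", "C"))
  expect_equal(length(unique(asg2)), 2L)
})

test_that("synthetic three-cluster reference is recovered exactly", {
  ref <- three_cluster_ref(seed = 42)
  pr <- pairwise_operon_identity(ref$db)
  asg <- cluster_genomes(pr, genomes = unique(ref$db$genome_id))
  truth <- ref$truth$refs
  true_cl <- truth$cluster_id[match(names(asg), truth$genome_id)]
  expect_equal(length(unique(asg)), 3L)
  expect_true(all(outer(asg, asg, "==") == outer(true_cl, true_cl, "==")))
})

test_that("cluster ids are invariant to input order and match brute force", {
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    genomes <- sprintf("G%02d", seq_len(n))
    ij <- t(combn(n, 2))
    pairs <- data.frame(
      genome_a = genomes[ij[, 1]], genome_b = genomes[ij[, 2]],
      averaged_identity = sample(c(0.95, 0.5), nrow(ij), replace = TRUE),
      coverage = 1,
      excluded = runif(nrow(ij)) < 0.2, stringsAsFactors = FALSE)
    asg <- cluster_genomes(pairs, genomes = genomes)
    # brute-force components over the same edge set
    adj <- matrix(FALSE, n, n)
    keep <- !pairs$excluded & pairs$averaged_identity >= 0.9
    for (e in which(keep)) {
      adj[ij[e, 1], ij[e, 2]] <- TRUE
      adj[ij[e, 2], ij[e, 1]] <- TRUE
    }
    comp <- bf_components(adj)
    expect_true(all(outer(asg, asg, "==") == outer(comp, comp, "==")))
    # permutation invariance
    perm <- sample(nrow(pairs))
    asg2 <- cluster_genomes(pairs[perm, ], genomes = sample(genomes))
    expect_identical(asg2, asg)
  }
})

test_that("raising the clustering threshold never merges clusters", {
  set.seed(44)
  for (rep in 1:10) {
    n <- 8
    genomes <- sprintf("G%d", 1:n)
    ij <- t(combn(n, 2))
    pairs <- data.frame(
      genome_a = genomes[ij[, 1]], genome_b = genomes[ij[, 2]],
      averaged_identity = runif(nrow(ij), 0.7, 1.0),
      coverage = 1, excluded = FALSE, stringsAsFactors = FALSE)
    lo <- cluster_genomes(pairs, bai_thresholds(cluster_identity = 0.85),
                          genomes = genomes)
    hi <- cluster_genomes(pairs, bai_thresholds(cluster_identity = 0.95),
                          genomes = genomes)
    # the high-threshold partition refines the low-threshold one
    same_hi <- outer(hi, hi, "==")
    same_lo <- outer(lo, lo, "==")
    expect_true(all(same_lo[same_hi]))
  }
})

test_that("read hits inherit the cluster of their reference genome", {
  hits <- data.frame(read_id = c("r1", "r2"), genome_id = c("A", "B"),
                     stringsAsFactors = FALSE)
  asg <- c(A = 1L, B = 2L)
  out <- label_reads_with_clusters(hits, asg)
  expect_equal(out$cluster_id, c(1L, 2L))
  expect_identical(label_reads_with_clusters(out, asg), out)
  expect_error(label_reads_with_clusters(
    data.frame(read_id = "r", genome_id = "Z"), asg), "unassigned")
  empty <- label_reads_with_clusters(hits[0, , drop = FALSE], asg)
  expect_equal(nrow(empty), 0L)
})

test_that("pairwise identity is symmetric in its inputs", {
  set.seed(45)
  s1 <- random_aa(120)
  s2 <- substitute_at(s1, round(seq(10, 110, length.out = 12)))
  h12 <- align_protein(s1, s2)
  h21 <- align_protein(s2, s1)
  expect_equal(h12$matching_residues, h21$matching_residues)
  expect_equal(h12$alignment_length, h21$alignment_length)
  expect_equal(h12$score, h21$score)
})
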