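test_that("family q90 length follows linear interpolation", {
  expect_equal(family_q90_length(c(100, 100, 100)), 100)
  expect_equal(family_q90_length(1:10), 9.1)
  expect_equal(family_q90_length(250), 250)
  expect_error(family_q90_length(numeric(0)), "no alignment")
})

test_that("ORF matching honours the identity threshold", {
  set.seed(10)
  ref <- three_cluster_ref()
  seeds <- ref$db[ref$db$genome_id == "C01G01", ]

  # an ORF identical to a seed matches its family
  orfs <- data.frame(sequence_id = "orf1", genome_id = "GX",
                     sequence = seeds$sequence[seeds$family == "baiE"],
                     stringsAsFactors = FALSE)
  m <- match_orfs(orfs, seeds)
  expect_equal(m$family, "baiE")
  expect_equal(m$percent_identity, 1.0)

  # an ORF at exactly 69% identity to its best seed is below the 70% cutoff
  s <- seeds$sequence[seeds$family == "baiA"]
  pos <- unique(round(seq(5, 295, length.out = 93)))
  expect_equal(length(pos), 93L)
  orf69 <- data.frame(sequence_id = "orf69", genome_id = "GX",
                      sequence = substitute_at(s, pos),
                      stringsAsFactors = FALSE)
  # seeds of the same family in other genomes are ~96% identical to this
  # one, so 69% vs the closest seed stays below threshold for all seeds
  m <- match_orfs(orf69, seeds[seeds$family == "baiA", , drop = FALSE])
  expect_equal(nrow(m), 0L)
})

test_that("ORF matching enforces the q90 alignment-length rule", {
  set.seed(11)
  ref <- three_cluster_ref()
  seeds <- ref$db[ref$db$genome_id == "C01G01", ]
  s <- seeds$sequence[seeds$family == "baiB"]
  full <- data.frame(
    sequence_id = sprintf("full%d", 1:3), genome_id = sprintf("G%d", 1:3),
    sequence = vapply(1:3, function(i)
      substitute_at(s, round(seq(10, 290, length.out = 15))), ""),
    stringsAsFactors = FALSE)
  trunc <- data.frame(sequence_id = "trunc", genome_id = "G4",
                      sequence = substr(s, 1, 180),
                      stringsAsFactors = FALSE)
  m <- match_orfs(rbind(full, trunc),
                  seeds[seeds$family == "baiB", , drop = FALSE])
  # q90 of lengths {300, 300, 300, 180} is 300; 180 < 0.7 * 300 = 210
  expect_true(all(full$sequence_id %in% m$sequence_id))
  expect_false("trunc" %in% m$sequence_id)
})

test_that("genomes qualify with at least four matched families", {
  fam <- bai_families()
  matches <- data.frame(
    sequence_id = sprintf("o%d", 1:12),
    genome_id = c(rep("A", 5), rep("B", 3), rep("C", 4)),
    family = c(fam[1:5], fam[1:3], fam[1:4]),
    percent_identity = 0.9, alignment_length = 300L,
    seed_id = "s", stringsAsFactors = FALSE)
  expect_equal(call_bai_genomes(matches), c("A", "C"))
})

test_that("reference DB construction adds qualifying genomes and dedups", {
  set.seed(12)
  ref <- three_cluster_ref()
  seeds <- ref$db[, c("sequence_id", "genome_id", "family", "sequence")]

  # no ORFs: DB equals the seed set
  db0 <- build_reference_db(seeds)
  expect_equal(sort(db0$sequence_id), sort(seeds$sequence_id))
  expect_true(all(db0$origin == "seed_set"))

  # a new in-cluster genome at ~96% identity contributes all 8 ORFs
  base <- ref$db[ref$db$genome_id == "C01G01", ]
  orfs <- data.frame(
    sequence_id = paste0("NEW_", base$family), genome_id = "NEW",
    sequence = vapply(base$sequence, function(s)
      substitute_at(s, round(seq(10, 290, length.out = 12))), "",
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  db1 <- build_reference_db(seeds, list(orfs))
  added <- db1[db1$origin == "orf_match", ]
  expect_equal(nrow(added), 8L)
  expect_setequal(added$family, bai_families())
  expect_true(all(added$genome_id == "NEW"))

  # a random genome contributes nothing
  set.seed(13)
  junk <- data.frame(sequence_id = sprintf("J%d", 1:5), genome_id = "JUNK",
                     sequence = vapply(1:5, function(i) random_aa(300), ""),
                     stringsAsFactors = FALSE)
  db2 <- build_reference_db(seeds, list(junk))
  expect_equal(sort(db2$sequence_id), sort(seeds$sequence_id))

  # two ORFs for one (genome, family): the higher-identity one is kept
  worse <- data.frame(sequence_id = "NEW_baiA_worse", genome_id = "NEW",
                      sequence = substitute_at(
                        base$sequence[base$family == "baiA"],
                        round(seq(10, 290, length.out = 40))),
                      stringsAsFactors = FALSE)
  db3 <- build_reference_db(seeds, list(rbind(orfs, worse)))
  kept <- db3[db3$genome_id == "NEW" & db3$family == "baiA", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$sequence_id, "NEW_baiA")
})

test_that("raising the identity cutoff never adds genomes", {
  set.seed(14)
  ref <- three_cluster_ref()
  seeds <- ref$db[ref$db$genome_id %in% c("C01G01", "C01G02"),
                  c("sequence_id", "genome_id", "family", "sequence")]
  base <- ref$db[ref$db$genome_id == "C02G01", ]
  orfs <- data.frame(
    sequence_id = paste0("X_", base$family), genome_id = "X",
    sequence = vapply(base$sequence, function(s)
      substitute_at(s, round(seq(10, 290, length.out = 60))), "",
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  included <- function(min_id) {
    m <- match_orfs(orfs, seeds, bai_thresholds(orf_min_identity = min_id))
    call_bai_genomes(m, bai_thresholds(orf_min_identity = min_id))
  }
  sets <- lapply(c(0.30, 0.45, 0.60, 0.75, 0.90), included)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("the DB builds identically twice and round-trips through disk", {
  set.seed(15)
  ref <- three_cluster_ref()
  seeds <- ref$db[, c("sequence_id", "genome_id", "family", "sequence")]
  a <- build_reference_db(seeds)
  b <- build_reference_db(seeds)
  expect_identical(a, b)
  pre <- file.path(tempdir(), "refdb_test")
  write_reference_db(a, pre)
  back <- read_reference_db(pre)
  expect_equal(back$sequence_id, a$sequence_id)
  expect_equal(back$sequence, a$sequence)
  expect_equal(back$family, a$family)
})

test_that("duplicate sequence ids are refused", {
  df <- data.frame(sequence_id = c("a", "a"), genome_id = "g",
                   family = c("baiA", "baiB"), origin = "seed_set",
                   sequence = "MKV", stringsAsFactors = FALSE)
  expect_error(new_bai_refdb(df), "duplicate")
})
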