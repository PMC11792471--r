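# Independent oracles and fixture builders shared across test files.

# Brute-force AUC: fraction of (g1, g2) pairs with g2 > g1, ties counting 1/2.
bf_auc <- function(g1, g2) {
  s <- 0
  for (a in g1) for (b in g2) s <- s + (b > a) + 0.5 * (b == a)
  s / (length(g1) * length(g2))
}

# Textbook chi-square from expected counts.
bf_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - e)^2 / e),
       dof = (nrow(m) - 1) * (ncol(m) - 1))
}

# Connected components by transitive closure of the adjacency matrix
# (exhaustive reachability, independent of the union-find implementation).
bf_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[reach[i, ] > 0] <- k
    }
  }
  comp
}

# Spearman rho via the classic no-ties rank formula.
bf_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# Substitute the residues at `positions` with a different residue
# (deterministically: next letter in the alphabet), keeping everything else.
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    i <- match(ch[p], aa20)
    ch[p] <- aa20[(i %% length(aa20)) + 1L]
  }
  paste(ch, collapse = "")
}

# Small three-cluster reference used by several files (divergences chosen so
# clusters are cleanly separated at the 90% threshold).
three_cluster_ref <- function(seed = 101) {
  cfg <- sim_config(seed = seed, n_clusters = 3, genomes_per_cluster = 2,
                    within_cluster_divergence = 0.02,
                    between_cluster_divergence = 0.30)
  generate_reference_operons(cfg)
}

reads_as_list <- function(df) {
  list(read_id = df$read_id, sequence = df$sequence,
       qualities = lapply(df$quality, function(q) utf8ToInt(q) - 33L))
}
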