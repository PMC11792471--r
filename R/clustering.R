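# Operon-level clustering: averaged amino-acid identity across the eight
# families (sum of matching residues over sum of alignment lengths), the 80%
# aligned-length exclusion, and single-linkage clustering at 90% identity.

#' Pairwise operon-averaged identity between reference genomes
#'
#' For every genome pair, same-family sequences are aligned and matches and
#' alignment lengths pooled across families: `averaged_identity =
#' sum(matching) / sum(aligned)`. Families absent from either genome
#' contribute nothing to the aligned total. Coverage is the aligned total
#' divided by the mean of the two genomes' summed bai sequence lengths (a
#' symmetric definition of "total bai gene sequence length"); pairs with
#' coverage below `pair_min_operon_coverage` are flagged excluded.
#'
#' @param db A `bai_refdb`.
#' @param t [bai_thresholds()].
#' @param aligner Protein aligner honouring the [align_protein()] contract.
#' @return data.frame: `genome_a`, `genome_b`, `total_matching`,
#'   `total_aligned`, `averaged_identity`, `coverage`, `excluded`.
#' @export
pairwise_operon_identity <- function(db, t = bai_thresholds(),
                                     aligner = align_protein) {
  stopifnot(inherits(db, "bai_refdb"), nrow(db) > 0)
  genomes <- sort(unique(db$genome_id))
  bylen <- tapply(nchar(db$sequence), db$genome_id, sum)
  rows <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_len(i - 1L)) {
      ga <- genomes[j]; gb <- genomes[i]
      a <- db[db$genome_id == ga, ]
      b <- db[db$genome_id == gb, ]
      shared <- intersect(a$family, b$family)
      tm <- 0L; ta <- 0L
      for (f in shared) {
        h <- aligner(a$sequence[a$family == f][1],
                     b$sequence[b$family == f][1],
                     query_id = ga, subject_id = gb)
        if (is.null(h)) next
        tm <- tm + h$matching_residues
        ta <- ta + h$alignment_length
      }
      tot <- mean(c(bylen[[ga]], bylen[[gb]]))
      cov <- ta / tot
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = ga, genome_b = gb, total_matching = tm,
        total_aligned = ta,
        averaged_identity = if (ta > 0) tm / ta else 0,
        coverage = cov, excluded = cov < t$pair_min_operon_coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      total_matching = integer(0), total_aligned = integer(0),
                      averaged_identity = numeric(0), coverage = numeric(0),
                      excluded = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cluster genomes at the operon identity threshold
#'
#' Single-linkage clustering: connected components of the graph whose edges
#' are the non-excluded pairs with `averaged_identity >= cluster_identity`.
#' Cluster ids are canonicalized by the smallest member genome id, so
#' membership is invariant to input ordering.
#'
#' @param pairs Output of [pairwise_operon_identity()].
#' @param t [bai_thresholds()].
#' @param genomes Optional full genome universe (so genomes with no
#'   qualifying edges become singleton clusters).
#' @return A named integer vector mapping genome_id to cluster_id.
#' @export
cluster_genomes <- function(pairs, t = bai_thresholds(), genomes = NULL) {
  if (is.null(genomes))
    genomes <- sort(unique(c(pairs$genome_a, pairs$genome_b)))
  else genomes <- sort(unique(genomes))
  edges <- pairs[!pairs$excluded &
                   pairs$averaged_identity >= t$cluster_identity - 1e-12, ,
                 drop = FALSE]
  parent <- seq_along(genomes)
  find2 <- function(p, i) {
    while (p[i] != i) i <- p[i]
    i
  }
  for (e in seq_len(nrow(edges))) {
    ia <- match(edges$genome_a[e], genomes)
    ib <- match(edges$genome_b[e], genomes)
    ra <- find2(parent, ia); rb <- find2(parent, ib)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(genomes), function(i) find2(parent, i), 0L)
  # canonical ids: order components by their smallest member (genomes are
  # sorted, so the root index order is already that order)
  ids <- match(root, sort(unique(root)))
  setNames(as.integer(ids), genomes)
}

#' Attach cluster assignments to a reference DB
#'
#' @param db A `bai_refdb`.
#' @param assignment Named vector from [cluster_genomes()].
#' @return The DB with `cluster_id` filled in.
#' @export
assign_db_clusters <- function(db, assignment) {
  stopifnot(inherits(db, "bai_refdb"))
  miss <- setdiff(unique(db$genome_id), names(assignment))
  if (length(miss))
    stop("no cluster assignment for genome(s): ",
         paste(miss, collapse = ", "))
  db$cluster_id <- as.integer(assignment[db$genome_id])
  db
}

#' Label read hits with the cluster of their best-hit reference
#'
#' @param hits Hit data.frame from [map_reads()].
#' @param assignment Named vector from [cluster_genomes()].
#' @return The hits with `cluster_id` filled in.
#' @export
label_reads_with_clusters <- function(hits, assignment) {
  if (nrow(hits) == 0L) {
    hits$cluster_id <- integer(0)
    return(hits)
  }
  miss <- setdiff(unique(hits$genome_id), names(assignment))
  if (length(miss))
    stop("unassigned genome(s) in hits: ", paste(miss, collapse = ", "))
  hits$cluster_id <- as.integer(assignment[hits$genome_id])
  hits
}
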