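# Translated read profiling: six-frame search of QC-passed reads against the
# bai reference, best single hit per read at >= 90% identity over >= 25 aa,
# then per-family counts, relative abundances and the geometric-mean operon
# abundance with a 1e-9 pseudocount.

#' Map reads against the bai reference database
#'
#' Each read is translated in all six frames; stop codons effectively split
#' a frame into segments because local alignments never cross them. Each
#' frame is searched against the reference under the protein-aligner
#' contract and the single best hit by alignment score that meets both the
#' identity and length thresholds is assigned; equal-score ties go to the
#' lexicographically smallest `sequence_id`.
#'
#' With the default (`aligner = NULL`) the compiled Smith-Waterman backend
#' with an exact k-mer prescreen is used. Supplying an `aligner` function
#' routes every frame-vs-reference comparison through it instead (slower;
#' intended for swapping in an external aligner).
#'
#' @param reads Read list (fields `read_id`, `sequence`) or character vector
#'   of sequences.
#' @param db A `bai_refdb`.
#' @param t [bai_thresholds()].
#' @param aligner `NULL` for the built-in backend, or a function with the
#'   [align_protein()] signature.
#' @return data.frame of read hits: `read_id`, `sequence_id`, `genome_id`,
#'   `family`, `cluster_id`, `identity`, `alignment_length`,
#'   `matching_residues`, `score`.
#' @export
map_reads <- function(reads, db, t = bai_thresholds(), aligner = NULL) {
  stopifnot(inherits(db, "bai_refdb"))
  if (is.character(reads))
    reads <- list(read_id = sprintf("r%06d", seq_along(reads)),
                  sequence = reads)
  ord <- order(db$sequence_id)
  db <- db[ord, ]
  if (is.null(aligner)) {
    sc <- blosum62_scoring()
    gc <- Biostrings::GENETIC_CODE
    hits <- map_reads_cpp(reads$read_id, reads$sequence,
                          db$sequence_id, db$sequence,
                          names(gc), unname(gc),
                          sc$matrix, sc$alphabet,
                          as.integer(t$gap_open), as.integer(t$gap_extend),
                          t$read_min_identity,
                          as.integer(t$read_min_alignment_aa),
                          as.integer(t$seed_kmer))
  } else {
    hits <- .map_reads_r(reads, db, t, aligner)
  }
  idx <- match(hits$sequence_id, db$sequence_id)
  hits$genome_id <- db$genome_id[idx]
  hits$family <- db$family[idx]
  hits$cluster_id <- db$cluster_id[idx]
  hits[, c("read_id", "sequence_id", "genome_id", "family", "cluster_id",
           "identity", "alignment_length", "matching_residues", "score")]
}

# Reference path through an arbitrary aligner honouring the
# align_protein() contract. Used when a non-default backend is supplied.
.map_reads_r <- function(reads, db, t, aligner) {
  out <- list()
  for (i in seq_along(reads$read_id)) {
    peps <- six_frame_translate(reads$sequence[i])
    best <- NULL
    for (pep in peps) {
      if (nchar(pep) < t$read_min_alignment_aa) next
      for (j in seq_len(nrow(db))) {
        h <- aligner(pep, db$sequence[j], query_id = reads$read_id[i],
                     subject_id = db$sequence_id[j])
        if (is.null(h)) next
        if (h$alignment_length < t$read_min_alignment_aa) next
        if (h$percent_identity < t$read_min_identity - 1e-12) next
        if (is.null(best) || h$score > best$score ||
            (h$score == best$score && h$subject_id < best$subject_id))
          best <- h
      }
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        read_id = best$query_id, sequence_id = best$subject_id,
        score = best$score, matching_residues = best$matching_residues,
        alignment_length = best$alignment_length,
        identity = best$percent_identity, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_id = character(0), sequence_id = character(0),
                      score = integer(0), matching_residues = integer(0),
                      alignment_length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Translate a nucleotide sequence in all six frames
#'
#' @param nt Nucleotide string (A/C/G/T/N).
#' @return Character vector of six peptides (stops as `*`, ambiguous codons
#'   as `X`).
#' @export
six_frame_translate <- function(nt) {
  x <- Biostrings::DNAString(nt)
  rc <- Biostrings::reverseComplement(x)
  frames <- character(6)
  for (off in 0:2) {
    for (s in 1:2) {
      src <- if (s == 1) x else rc
      n <- length(src) - off
      n <- n - n %% 3
      frames[(s - 1) * 3 + off + 1] <- if (n >= 3)
        as.character(Biostrings::translate(
          Biostrings::subseq(src, off + 1, off + n),
          if.fuzzy.codon = "X")) else ""
    }
  }
  frames
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read A single nucleotide string.
#' @return A one-row hit data.frame, or `NULL` when the read has no
#'   qualifying hit.
#' @export
map_read <- function(read, db, t = bai_thresholds(), aligner = NULL) {
  h <- map_reads(c(read), db, t, aligner)
  if (nrow(h) == 0L) NULL else h
}

#' Per-family relative abundances
#'
#' @param hits Hit data.frame from [map_reads()].
#' @param denominator QC-passed read count of the sample; must be positive.
#' @param families Family names (default [bai_families()]).
#' @return Named numeric vector: per-family read count divided by the
#'   denominator; families without hits get 0.
#' @export
gene_relative_abundances <- function(hits, denominator,
                                     families = bai_families()) {
  if (denominator <= 0) stop("denominator must be positive")
  counts <- table(factor(hits$family, levels = families))
  setNames(as.numeric(counts) / denominator, families)
}

#' Geometric-mean operon abundance with pseudocount
#'
#' Zero fractions are replaced by the pseudocount (default 1e-9) before
#' taking the geometric mean over the eight family fractions, so the result
#' is always positive.
#'
#' @param fractions Numeric vector of exactly 8 per-family fractions.
#' @param pseudocount Floor for zero fractions.
#' @return The operon abundance.
#' @export
#' @examples
#' operon_abundance(c(rep(1e-5, 4), rep(0, 4))) # 1e-7
operon_abundance <- function(fractions, pseudocount = 1e-9) {
  if (length(fractions) != 8L) stop("exactly 8 family fractions required")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  f <- ifelse(fractions == 0, pseudocount, fractions)
  10^mean(log10(f))
}

#' Per-cluster profiles of a sample
#'
#' Restricts hits to each cluster (every mapped read has one best-hit
#' cluster), computes per-family counts and fractions, the cluster's
#' geometric-mean operon abundance, and the detected flag (at least
#' `min_cluster_genes_detected` families with >= 1 read).
#'
#' @param hits Hit data.frame with a non-NA `cluster_id` column.
#' @param denominator QC-passed read count.
#' @param t [bai_thresholds()].
#' @param clusters Clusters to report (default: all present in `hits`).
#' @return data.frame: `cluster_id`, `n_families_detected`, `detected`,
#'   `operon_abundance`, with the per-cluster count matrix as attribute
#'   `counts`.
#' @export
cluster_profiles <- function(hits, denominator, t = bai_thresholds(),
                             clusters = NULL) {
  if (nrow(hits) && anyNA(hits$cluster_id))
    stop("hits contain reference sequences without cluster assignment")
  fams <- bai_families()
  if (is.null(clusters)) clusters <- sort(unique(hits$cluster_id))
  cmat <- matrix(0L, nrow = length(clusters), ncol = 8L,
                 dimnames = list(as.character(clusters), fams))
  if (nrow(hits)) {
    tab <- table(factor(hits$cluster_id, levels = clusters),
                 factor(hits$family, levels = fams))
    cmat[] <- as.integer(tab)
  }
  nfam <- rowSums(cmat > 0)
  ab <- apply(cmat, 1L, function(cnt)
    operon_abundance(cnt / denominator, t$pseudocount))
  out <- data.frame(cluster_id = clusters,
                    n_families_detected = as.integer(nfam),
                    detected = nfam >= t$min_cluster_genes_detected,
                    operon_abundance = as.numeric(ab),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- cmat
  out
}

#' Assemble the full profile of one sample
#'
#' @param sample_id Sample name.
#' @param hits Hit data.frame from [map_reads()].
#' @param denominator QC-passed read count.
#' @param t [bai_thresholds()].
#' @param clusters Optional cluster universe for the per-cluster table.
#' @return A `sample_profile` object: list with `sample_id`, `denominator`,
#'   `counts`, `fractions`, `operon_abundance` and `clusters` (per-cluster
#'   table when cluster ids are available).
#' @export
sample_profile <- function(sample_id, hits, denominator,
                           t = bai_thresholds(), clusters = NULL) {
  fr <- gene_relative_abundances(hits, denominator)
  counts <- as.integer(round(fr * denominator))
  names(counts) <- names(fr)
  cl <- NULL
  if ((nrow(hits) && !anyNA(hits$cluster_id)) || !is.null(clusters))
    cl <- cluster_profiles(hits, denominator, t, clusters)
  structure(list(sample_id = sample_id, denominator = denominator,
                 counts = counts, fractions = fr,
                 operon_abundance = operon_abundance(fr, t$pseudocount),
                 clusters = cl),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("bai sample profile:", x$sample_id, "\n")
  cat("  QC-passed reads:", x$denominator, "\n")
  cat("  mapped reads:", sum(x$counts), "\n")
  cat("  operon abundance:", format(x$operon_abundance, digits = 4), "\n")
  if (!is.null(x$clusters)) {
    det <- x$clusters$cluster_id[x$clusters$detected]
    cat("  detected clusters:",
        if (length(det)) paste(det, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
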