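#' The eight bai gene families
#'
#' The bai operon comprises eight enzyme-coding gene families. The default
#' names follow the common bai gene nomenclature but are freely overridable:
#' no computation in the package depends on the specific names, only on there
#' being exactly eight unique families.
#'
#' @param names Character vector of length 8 with unique family names.
#' @return Character vector of the eight family names.
#' @export
#' @examples
#' bai_families()
bai_families <- function(names = c("baiA", "baiB", "baiCD", "baiE",
                                   "baiF", "baiG", "baiH", "baiI")) {
  if (length(names) != 8L || anyDuplicated(names) > 0L)
    stop("exactly 8 unique bai family names are required")
  as.character(names)
}

#' Pipeline thresholds
#'
#' All numeric cutoffs used across the pipeline, with the defaults used
#' throughout: ORF inclusion (70% identity over 70% of the family's 90th
#' quantile alignment length; at least 4 of 8 families per genome), read
#' mapping (90% identity over at least 25 aa), operon clustering (90%
#' averaged identity, 80% minimum aligned-length coverage), the geometric
#' mean pseudocount (1e-9), cluster detection (>= 4 families with reads),
#' quality trimming (MINLEN 75, trailing Q20, sliding window 4/Q20), and the
#' DCA:CA phenotype cutoff (ratio 1).
#'
#' @param ... Named overrides of any default threshold.
#' @return A list of class `bai_thresholds`.
#' @export
#' @examples
#' t <- bai_thresholds(read_min_identity = 0.95)
#' t$read_min_identity
bai_thresholds <- function(...) {
  t <- list(
    orf_min_identity = 0.70,
    orf_min_length_fraction = 0.70,
    min_families_for_genome = 4L,
    read_min_identity = 0.90,
    read_min_alignment_aa = 25L,
    pair_min_operon_coverage = 0.80,
    cluster_identity = 0.90,
    pseudocount = 1e-9,
    min_cluster_genes_detected = 4L,
    trim_minlen = 75L,
    trim_trailing_q = 20L,
    trim_window = 4L,
    trim_window_q = 20L,
    phenotype_ratio_cutoff = 1.0,
    gap_open = 11L,
    gap_extend = 1L,
    seed_kmer = 6L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(t))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    t[names(dots)] <- dots
  }
  frac <- c("orf_min_identity", "orf_min_length_fraction", "read_min_identity",
            "pair_min_operon_coverage", "cluster_identity")
  for (f in frac) {
    v <- t[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(f, " must be a fraction in (0, 1]")
  }
  cnt <- c("min_families_for_genome", "read_min_alignment_aa",
           "min_cluster_genes_detected", "trim_minlen", "trim_window")
  for (f in cnt) {
    if (t[[f]] < 1) stop(f, " must be a positive integer")
    t[[f]] <- as.integer(t[[f]])
  }
  if (t$pseudocount <= 0) stop("pseudocount must be positive")
  structure(t, class = "bai_thresholds")
}
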