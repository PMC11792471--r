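# Reference database construction: seed bai sequences plus genome ORF sets,
# under the inclusion rules 70% identity / 70% of the family's 90th-quantile
# alignment length / at least 4 of 8 families per genome.

#' Construct a `bai_refdb` from a reference table
#'
#' @param df data.frame with columns `sequence_id`, `genome_id`, `family`,
#'   `origin` (`seed_set` or `orf_match`) and `sequence`; a `cluster_id`
#'   column is added (NA) if absent.
#' @return The validated data.frame with class `bai_refdb`, sorted by
#'   `sequence_id`.
#' @export
new_bai_refdb <- function(df) {
  need <- c("sequence_id", "genome_id", "family", "origin", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sequence_id))
    stop("duplicate sequence_id in reference DB")
  if (!all(nzchar(df$sequence)) || !all(grepl(.aa_regex, df$sequence)))
    stop("reference sequences must be non-empty amino-acid strings")
  if (!"cluster_id" %in% names(df)) df$cluster_id <- NA_integer_
  df <- df[order(df$sequence_id),
           c("sequence_id", "genome_id", "family", "origin", "cluster_id",
             "sequence")]
  rownames(df) <- NULL
  class(df) <- c("bai_refdb", "data.frame")
  df
}

#' 90th-quantile alignment length for one gene family
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), so lengths 1..10 give 9.1.
#'
#' @param lengths Alignment lengths (residues) of the recorded hits for one
#'   family; must be nonempty.
#' @return The 90th percentile of the lengths.
#' @export
#' @examples
#' family_q90_length(1:10)
family_q90_length <- function(lengths) {
  if (length(lengths) == 0L) stop("no alignment hits for family")
  unname(quantile(lengths, 0.9, type = 7))
}

#' Match genome ORFs against seed bai sequences
#'
#' Every ORF is aligned against every seed sequence; alignments reaching
#' `orf_min_identity` are recorded as hits. The per-family 90th-quantile
#' alignment length is computed over those hits, and an ORF matches family g
#' iff some hit to a family-g seed has alignment length of at least
#' `orf_min_length_fraction` times that family's q90 length. Each ORF keeps
#' at most one family: best identity wins, ties broken by lexicographic
#' family name.
#'
#' @param orfs data.frame with `sequence_id`, `genome_id`, `sequence`.
#' @param seed_refs A `bai_refdb` (or data.frame) of seed sequences with
#'   `family` labels, trusted as given.
#' @param t [bai_thresholds()].
#' @param aligner Protein aligner honouring the [align_protein()] contract.
#' @return data.frame of qualifying matches: `sequence_id`, `genome_id`,
#'   `family`, `percent_identity`, `alignment_length`, `seed_id`.
#' @export
match_orfs <- function(orfs, seed_refs, t = bai_thresholds(),
                       aligner = align_protein) {
  stopifnot(all(c("sequence_id", "genome_id", "sequence") %in% names(orfs)))
  hits <- list()
  for (i in seq_len(nrow(orfs))) {
    for (j in seq_len(nrow(seed_refs))) {
      h <- aligner(orfs$sequence[i], seed_refs$sequence[j],
                   query_id = orfs$sequence_id[i],
                   subject_id = seed_refs$sequence_id[j])
      if (is.null(h)) next
      if (h$percent_identity >= t$orf_min_identity) {
        h$family <- seed_refs$family[j]
        h$genome_id <- orfs$genome_id[i]
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (!length(hits))
    return(data.frame(sequence_id = character(0), genome_id = character(0),
                      family = character(0), percent_identity = numeric(0),
                      alignment_length = integer(0), seed_id = character(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, hits)
  q90 <- tapply(hits$alignment_length, hits$family, family_q90_length)
  keep <- hits$alignment_length >=
    t$orf_min_length_fraction * q90[hits$family]
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(sequence_id = character(0), genome_id = character(0),
                      family = character(0), percent_identity = numeric(0),
                      alignment_length = integer(0), seed_id = character(0),
                      stringsAsFactors = FALSE))
  # one family per ORF: best identity, ties to lexicographically first family
  hits <- hits[order(hits$query_id, -hits$percent_identity, hits$family), ]
  best <- hits[!duplicated(hits$query_id), ]
  data.frame(sequence_id = best$query_id, genome_id = best$genome_id,
             family = best$family, percent_identity = best$percent_identity,
             alignment_length = best$alignment_length,
             seed_id = best$subject_id, stringsAsFactors = FALSE)
}

#' Genomes qualifying as bai carriers
#'
#' A genome is called bai-positive when its ORFs match at least
#' `min_families_for_genome` (default 4) of the eight families.
#'
#' @param matches Output of [match_orfs()].
#' @param t [bai_thresholds()].
#' @return Character vector of qualifying genome ids.
#' @export
call_bai_genomes <- function(matches, t = bai_thresholds()) {
  if (!nrow(matches)) return(character(0))
  nfam <- tapply(matches$family, matches$genome_id,
                 function(f) length(unique(f)))
  sort(names(nfam)[nfam >= t$min_families_for_genome])
}

#' Build the dereplicated bai reference database
#'
#' Union of the seed sequences and the qualifying ORF matches from genomes
#' called bai-positive. When a genome yields several ORFs for one family,
#' the highest-identity one is kept so each (genome, family) has a single
#' representative.
#'
#' @param seed_refs data.frame of seed sequences (`sequence_id`, `genome_id`,
#'   `family`, `sequence`).
#' @param orf_sets A list of ORF data.frames (`sequence_id`, `genome_id`,
#'   `sequence`), e.g. one per genome; may be empty.
#' @param t [bai_thresholds()].
#' @param aligner Protein aligner.
#' @return A `bai_refdb`.
#' @export
build_reference_db <- function(seed_refs, orf_sets = list(),
                               t = bai_thresholds(),
                               aligner = align_protein) {
  seed <- seed_refs
  seed$origin <- "seed_set"
  out <- seed[, c("sequence_id", "genome_id", "family", "origin", "sequence")]
  if (length(orf_sets)) {
    orfs <- do.call(rbind, orf_sets)
    m <- match_orfs(orfs, seed_refs, t, aligner)
    good <- call_bai_genomes(m, t)
    m <- m[m$genome_id %in% good, , drop = FALSE]
    if (nrow(m)) {
      # one representative per (genome, family): highest identity
      m <- m[order(m$genome_id, m$family, -m$percent_identity,
                   m$sequence_id), ]
      m <- m[!duplicated(m[, c("genome_id", "family")]), ]
      seqs <- setNames(orfs$sequence, orfs$sequence_id)
      add <- data.frame(sequence_id = m$sequence_id, genome_id = m$genome_id,
                        family = m$family, origin = "orf_match",
                        sequence = unname(seqs[m$sequence_id]),
                        stringsAsFactors = FALSE)
      out <- rbind(out, add)
    }
  }
  new_bai_refdb(out)
}
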