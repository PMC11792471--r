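# Protein alignment backend: a built-in affine-gap Smith-Waterman (compiled)
# scoring with BLOSUM62, gap open 11 / extend 1, i.e. the default scoring of
# the translated search tools commonly used for this kind of profiling.

.aligner_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix and its alphabet
#'
#' Fetches BLOSUM62 from Biostrings once and caches it. Stop codons (`*`)
#' are re-scored to a large negative value so that local alignments of
#' translated reads never cross a stop; each inter-stop segment of a reading
#' frame is thereby aligned independently.
#'
#' @return A list with `matrix` (integer matrix) and `alphabet` (single
#'   string, row order of the matrix).
#' @keywords internal
blosum62_scoring <- function() {
  if (is.null(.aligner_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    stopifnot(identical(rownames(m), colnames(m)))
    star <- which(rownames(m) == "*")
    if (length(star)) {
      m[star, ] <- -10000L
      m[, star] <- -10000L
    }
    storage.mode(m) <- "integer"
    .aligner_env$blosum62 <- list(matrix = m,
                                  alphabet = paste(rownames(m), collapse = ""))
  }
  .aligner_env$blosum62
}

.aa_regex <- "^[ARNDCQEGHILKMFPSTWYVBJZX*]+$"

#' Locally align two amino-acid sequences
#'
#' Best local (Smith-Waterman) alignment under BLOSUM62 with affine gap
#' penalties (gap of length L costs `gap_open + L * gap_extend`). Identity is
#' defined as matching residues divided by alignment length including gap
#' columns, the reporting convention of translated-search tools.
#'
#' This is the built-in backend of the pluggable protein-aligner contract:
#' every operation that needs alignments (`match_orfs()`,
#' `pairwise_operon_identity()`, `map_reads()`) accepts an `aligner` function
#' with this signature, so an external aligner can be swapped in.
#'
#' @param query,subject Amino-acid strings (standard alphabet plus B, J, Z,
#'   X and `*`).
#' @param query_id,subject_id Optional sequence identifiers carried into the
#'   result.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row data.frame (an `AlignmentHit`) with columns `query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`,
#'   `matching_residues` and `score`, or `NULL` when no positive-scoring
#'   local alignment exists.
#' @export
#' @examples
#' align_protein("MKVLAG", "MKVLAG")$percent_identity
align_protein <- function(query, subject, query_id = "query",
                          subject_id = "subject", gap_open = 11L,
                          gap_extend = 1L) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(subject), length(subject) == 1L, nzchar(subject))
  if (!grepl(.aa_regex, query)) stop("query contains invalid residues")
  if (!grepl(.aa_regex, subject)) stop("subject contains invalid residues")
  sc <- blosum62_scoring()
  r <- sw_align_cpp(query, subject, sc$matrix, sc$alphabet,
                    as.integer(gap_open), as.integer(gap_extend))
  if (r$score <= 0L || r$alignment_length == 0L) return(NULL)
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = r$identity,
             alignment_length = r$alignment_length,
             matching_residues = r$matching_residues,
             score = r$score, stringsAsFactors = FALSE)
}
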