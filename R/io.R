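# File I/O: FASTA/FASTQ through Biostrings, TSV through base R with fixed
# formatting so repeated runs are byte-identical.

#' Read a FASTQ file into reads with integer Phred scores
#'
#' Phred+33 is assumed; scores above 45 indicate Phred+64 input and raise an
#' error rather than silently mis-scaling.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A list with `read_id`, `sequence` (character vectors) and
#'   `qualities` (list of integer vectors).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      # Biostrings warns when dropping FASTQ metadata columns; harmless here
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  q <- as(Biostrings::quality(x), "IntegerList")
  q <- as.list(q)
  ids <- sub("\\s.*$", "", names(x))
  if (any(unlist(lapply(q, max), use.names = FALSE) > 45, na.rm = TRUE))
    stop("quality scores above 45: input looks Phred+64 encoded, expected ",
         "Phred+33")
  list(read_id = ids, sequence = unname(as.character(x)), qualities = q)
}

#' Write reads (sequences plus integer Phred scores) as Phred+33 FASTQ
#'
#' @param reads A list as returned by [read_fastq()] or a data.frame with
#'   `read_id`, `sequence` and `quality` (Phred+33 strings) columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    qual <- Biostrings::PhredQuality(reads$quality)
    dna <- Biostrings::DNAStringSet(reads$sequence)
    names(dna) <- reads$read_id
  } else {
    qual <- Biostrings::PhredQuality(vapply(reads$qualities,
                                            function(q) intToUtf8(q + 33L), ""))
    dna <- Biostrings::DNAStringSet(reads$sequence)
    names(dna) <- reads$read_id
  }
  x <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read amino-acid FASTA with `seqid|genome|family` headers
#'
#' @param path FASTA path.
#' @return data.frame: `sequence_id`, `genome_id`, `family`, `sequence`.
#' @export
read_seed_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(x)), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("FASTA header(s) not in 'seqid|genome|family' form: ",
         paste(utils::head(names(x)[bad], 3), collapse = ", "))
  data.frame(sequence_id = vapply(parts, `[`, "", 1L),
             genome_id = vapply(parts, `[`, "", 2L),
             family = vapply(parts, `[`, "", 3L),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Write a reference DB as FASTA plus a TSV index
#'
#' @param db A `bai_refdb`.
#' @param prefix Output prefix; writes `<prefix>.faa` and `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_reference_db <- function(db, prefix) {
  stopifnot(inherits(db, "bai_refdb"))
  faa <- paste0(prefix, ".faa")
  tsv <- paste0(prefix, ".tsv")
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- paste(db$sequence_id, db$genome_id, db$family, sep = "|")
  Biostrings::writeXStringSet(x, faa)
  write_tsv(db[, c("sequence_id", "genome_id", "family", "origin",
                   "cluster_id")], tsv)
  invisible(c(fasta = faa, index = tsv))
}

#' Read a reference DB written by [write_reference_db()]
#'
#' @param prefix Prefix used when writing.
#' @return A `bai_refdb`.
#' @export
read_reference_db <- function(prefix) {
  seqs <- read_seed_fasta(paste0(prefix, ".faa"))
  idx <- read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE)
  db <- merge(idx, seqs[, c("sequence_id", "sequence")], by = "sequence_id",
              sort = TRUE)
  db <- db[order(db$sequence_id), ]
  rownames(db) <- NULL
  class(db) <- c("bai_refdb", "data.frame")
  db
}

# Deterministic TSV writer (fixed quoting, no row names, "." decimal).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
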