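# Read quality control: trailing-quality trim, sliding-window trim, minimum
# length filter (defaults MINLEN 75 / TRAILING Q20 / SLIDINGWINDOW 4:Q20),
# applied in that order. Trimming only ever truncates from the 3' end.

#' Trailing-quality trim
#'
#' Removes bases from the 3' end while their quality is below `q`, stopping
#' at the first base at or above `q`.
#'
#' @param qualities Integer Phred scores, 5' to 3'.
#' @param q Quality threshold.
#' @return Number of bases kept (the new read length).
#' @export
#' @examples
#' trim_trailing(c(30, 30, 30, 10, 15), 20) # 3
trim_trailing <- function(qualities, q) {
  keep <- which(qualities >= q)
  if (!length(keep)) 0L else max(keep)
}

#' Sliding-window quality trim
#'
#' Scans 5' to 3' over windows of `window` bases and clips the read at the
#' start of the first window whose mean quality falls below `q`. Reads
#' shorter than `window` are evaluated as a single window of their full
#' length. (The re-scan-within-window refinement of some trimmers is
#' deliberately not reproduced; the clip-at-window-start rule used here is
#' simpler and unambiguous.)
#'
#' @inheritParams trim_trailing
#' @param window Window length in bases.
#' @return Number of bases kept.
#' @export
#' @examples
#' sliding_window_trim(c(30, 30, 30, 30, 10, 10, 10, 10), 4, 20) # 3
sliding_window_trim <- function(qualities, window, q) {
  n <- length(qualities)
  if (n == 0L) return(0L)
  if (n < window) return(if (mean(qualities) < q) 0L else n)
  cs <- cumsum(c(0, qualities))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  fail <- which(means < q)
  if (!length(fail)) n else fail[1] - 1L
}

#' Quality-control pipeline for a set of reads
#'
#' Applies, in order: trailing trim, sliding-window trim, then drops reads
#' shorter than `trim_minlen`. The number of passed reads is the denominator
#' for all relative abundance estimates downstream.
#'
#' @param reads A list as returned by [read_fastq()] (fields `read_id`,
#'   `sequence`, `qualities`).
#' @param t [bai_thresholds()].
#' @return A list with `reads` (the passed reads, trimmed) and `report`
#'   (fields `input_reads`, `passed_reads`, `trimmed_bases`,
#'   `dropped_short`).
#' @export
qc_pipeline <- function(reads, t = bai_thresholds()) {
  n <- length(reads$read_id)
  lens <- nchar(reads$sequence)
  if (!identical(unname(lens), unname(lengths(reads$qualities))))
    stop("sequence and quality lengths differ")
  kept <- lens
  # reads whose minimum quality clears both thresholds are untouched; only
  # the rest need the per-base scan
  minq <- vapply(reads$qualities, function(q) if (length(q)) min(q) else 0L,
                 0L)
  scan <- which(minq < max(t$trim_trailing_q, t$trim_window_q) | lens == 0L)
  for (i in scan) {
    q <- reads$qualities[[i]]
    k1 <- trim_trailing(q, t$trim_trailing_q)
    k2 <- if (k1 > 0L) sliding_window_trim(q[seq_len(k1)], t$trim_window,
                                           t$trim_window_q) else 0L
    kept[i] <- k2
  }
  pass <- kept >= t$trim_minlen
  out <- list(
    read_id = reads$read_id[pass],
    sequence = substr(reads$sequence[pass], 1L, kept[pass]),
    qualities = lapply(which(pass),
                       function(i) reads$qualities[[i]][seq_len(kept[i])])
  )
  report <- list(input_reads = n, passed_reads = sum(pass),
                 trimmed_bases = sum(lens - kept),
                 dropped_short = sum(!pass))
  list(reads = out, report = report)
}

#' Host-read removal interface
#'
#' Drops reads flagged by the supplied predicate. The built-in default flags
#' nothing (synthetic data contains no host reads); a real deployment plugs
#' in a predicate backed by an alignment against the host genome.
#'
#' @param reads A read list (see [qc_pipeline()]).
#' @param host_filter Function mapping the read list to a logical vector
#'   (TRUE = host read, removed).
#' @return The read list with flagged reads removed; the number removed is
#'   reported via `message()`.
#' @export
remove_host_reads <- function(reads,
                              host_filter = function(r)
                                logical(length(r$read_id))) {
  flag <- host_filter(reads)
  stopifnot(is.logical(flag), length(flag) == length(reads$read_id))
  if (any(flag)) message(sum(flag), " host read(s) removed")
  list(read_id = reads$read_id[!flag],
       sequence = reads$sequence[!flag],
       qualities = reads$qualities[!flag])
}
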