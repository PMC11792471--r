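# Synthetic-data generator: every input the pipeline consumes, with ground
# truth. The defaults define the simulated study conditions (see the methods
# vignette for the reasoning behind each value).

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Parameters of the synthetic reference set, read sets, metabolome and FMT
#' cohort. Defaults are the study conditions used throughout the package's
#' tests and vignette:
#'
#' * `n_clusters`, `genomes_per_cluster`: size of the synthetic bai
#'   reference (clusters of operon-carrying genomes).
#' * `within_cluster_divergence`, `between_cluster_divergence`: per-site
#'   amino-acid substitution rates applied below/above the cluster level, so
#'   expected within-cluster pairwise identity is about
#'   `1 - 2 * within_cluster_divergence`.
#' * `cluster_abundances`: named numeric, cluster id -> per-gene relative
#'   read abundance (the expected fraction of reads originating from each
#'   single bai gene family of that cluster).
#' * `background_fraction`: if `NULL` (default) the background takes all
#'   probability not assigned to bai genes; if set, bai probabilities are
#'   rescaled so the background fraction is exactly this value.
#' * `low_quality_fraction`: fraction of reads emitted with quality strings
#'   that fail the trimming rules.
#' * `phenotype_threshold`: true operon abundance above which a sample's
#'   expected log10(DCA:CA) is `+phenotype_logratio_mean`, below which it is
#'   `-phenotype_logratio_mean`; `phenotype_noise_sd` is the SD of the draw.
#' * Cohort design: `n_samples`, `diagnosis_probs`, per-diagnosis
#'   `carriage_probs` (probability a sample carries the operon at detectable
#'   abundance) and `carrier_abundance_range` (log-uniform per-gene
#'   abundance of carriers). Depth (`n_reads`) and carrier abundances are
#'   scaled jointly so expected per-gene read counts match deep sequencing.
#' * FMT design: `fmt_n_subjects`, `fmt_engraft_fraction`,
#'   `fmt_samples_per_phase`, abundances of engrafting/stable/donor
#'   profiles, and `fmt_response_coupling` (probability that engraftment
#'   and clinical response agree; 1 = perfect coupling).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, n_clusters = 3)
#' cfg$n_clusters
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_clusters = 3L,
    genomes_per_cluster = 2L,
    within_cluster_divergence = 0.05,
    between_cluster_divergence = 0.30,
    gene_length_aa = 300L,
    read_length_nt = 150L,
    n_reads = 5000L,
    background_fraction = NULL,
    cluster_abundances = NULL,
    low_quality_fraction = 0,
    phenotype_threshold = 1e-7,
    phenotype_logratio_mean = 1,
    phenotype_noise_sd = 0,
    n_samples = 100L,
    diagnosis_probs = c(CD = 1 / 3, UC = 1 / 3, nonIBD = 1 / 3),
    carriage_probs = c(CD = 0.70, UC = 0.84, nonIBD = 0.96),
    healthy_state_probs = c(CD = 0.25, UC = 0.50, nonIBD = 0.90),
    carrier_abundance_range = c(1e-3, 5e-3),
    fmt_n_subjects = 10L,
    fmt_engraft_fraction = 0.5,
    fmt_samples_per_phase = 2L,
    fmt_engrafted_abundance = 1e-6,
    fmt_stable_abundance = 1e-7,
    fmt_donor_abundance = 1e-5,
    fmt_response_coupling = 1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  for (f in c("within_cluster_divergence", "between_cluster_divergence",
              "low_quality_fraction", "fmt_engraft_fraction",
              "fmt_response_coupling"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (!is.null(cfg$background_fraction) &&
      (cfg$background_fraction < 0 || cfg$background_fraction > 1))
    stop("background_fraction must be in [0, 1]")
  if (cfg$n_reads <= 0) stop("n_reads must be positive")
  if (!is.null(cfg$cluster_abundances)) {
    ab <- cfg$cluster_abundances
    if (any(ab < 0)) stop("cluster abundances must be nonnegative")
    if (8 * sum(ab) > 1 + 1e-12)
      stop("cluster abundances (x 8 genes) plus background must sum to <= 1")
  }
  structure(cfg, class = "sim_config")
}

.mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  chars
}

#' Generate a synthetic bai reference set with known cluster structure
#'
#' Emits `n_clusters * genomes_per_cluster` genomes, each carrying one
#' sequence per bai gene family, simulated on a star phylogeny: a shared
#' root sequence per family, a cluster ancestor mutated from the root at
#' `between_cluster_divergence`, and each genome mutated from its cluster
#' ancestor at `within_cluster_divergence`. Expected pairwise identities are
#' therefore about `1 - 2w` within and `(1 - b)^2` between clusters.
#'
#' A nucleotide sequence for every gene is produced by seeded reverse
#' translation (uniform codon choice per amino acid), providing the template
#' from which community reads are fragmented.
#'
#' @param config A [sim_config()].
#' @return A list with `db` (a `bai_refdb`, see [build_reference_db()]) and
#'   `truth` (list with the reference table including true `cluster_id` and
#'   nucleotide templates).
#' @export
generate_reference_operons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fams <- bai_families()
  L <- config$gene_length_aa
  w <- config$within_cluster_divergence
  b <- config$between_cluster_divergence
  if (1 - 2 * w < 0.90)
    warning("within-cluster divergence puts expected identity below the ",
            "90% clustering threshold")

  roots <- lapply(fams, function(f) sample(.AA20, L, replace = TRUE))
  names(roots) <- fams

  rows <- list()
  for (k in seq_len(config$n_clusters)) {
    ancestors <- lapply(roots, .mutate_seq, rate = b)
    for (j in seq_len(config$genomes_per_cluster)) {
      genome <- sprintf("C%02dG%02d", k, j)
      for (f in fams) {
        aa <- .mutate_seq(ancestors[[f]], rate = w)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = paste(genome, f, sep = "_"),
          genome_id = genome, family = f,
          origin = "seed_set", cluster_id = k,
          sequence = paste(aa, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  refs <- do.call(rbind, rows)
  refs$nt_sequence <- vapply(refs$sequence, reverse_translate, "",
                             USE.NAMES = FALSE)
  db <- new_bai_refdb(refs[, c("sequence_id", "genome_id", "family",
                               "origin", "sequence")])
  db$cluster_id <- NA_integer_
  list(db = db, truth = list(refs = refs, config = config))
}

#' Reverse-translate an amino-acid sequence
#'
#' Uniform seeded codon choice per residue under the standard genetic code
#' (no codon usage bias).
#'
#' @param aa Amino-acid string (standard 20-letter alphabet).
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  tab <- .codon_table()
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("no codon for residue ", a)
    cods[sample.int(length(cods), 1L)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

.sim_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.sim_env$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    .sim_env$codon_table <- split(names(gc), unname(gc))
  }
  .sim_env$codon_table
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Generate shotgun reads from a synthetic community
#'
#' Reads are in-frame fragments (random offset, random strand) of the
#' reverse-translated bai genes, plus background reads of i.i.d. uniform
#' nucleotides. For a cluster with configured per-gene abundance `a`, each
#' of the eight families contributes reads with probability `a` (split
#' uniformly across the cluster's genomes), so the expected per-family read
#' fraction equals `a`. Quality strings are Phred+33; a `low_quality_fraction`
#' of reads receives qualities that fail the trimming rules.
#'
#' @param config A [sim_config()] with `cluster_abundances` set (or empty for
#'   pure background).
#' @param truth The `truth` element of [generate_reference_operons()].
#' @param sample_id Sample name used in read ids.
#' @param seed Random seed for this sample (defaults to `config$seed`).
#' @return A list with `reads` (data.frame: `read_id`, `sequence`,
#'   `quality` as a Phred+33 string) and `sources` (data.frame tracing every
#'   read to its origin gene or `background`).
#' @export
generate_community_reads <- function(config, truth, sample_id = "S1",
                                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  refs <- truth$refs
  n <- as.integer(config$n_reads)
  rl <- as.integer(config$read_length_nt)
  ab <- config$cluster_abundances
  if (is.null(ab)) ab <- numeric(0)
  if (length(ab) && is.null(names(ab))) names(ab) <- seq_along(ab)

  fams <- bai_families()
  src <- data.frame(cluster_id = rep(as.integer(names(ab) %||% integer(0)),
                                     each = 8L),
                    family = rep(fams, times = length(ab)),
                    prob = rep(unname(ab), each = 8L),
                    stringsAsFactors = FALSE)
  p_bai <- sum(src$prob)
  if (is.null(config$background_fraction)) {
    p_bg <- 1 - p_bai
  } else {
    p_bg <- config$background_fraction
    if (p_bai > 0) src$prob <- src$prob * (1 - p_bg) / p_bai
  }
  probs <- c(src$prob, p_bg)
  if (any(probs < -1e-12)) stop("read source probabilities must be >= 0")
  probs <- pmax(probs, 0)

  counts <- as.vector(rmultinom(1L, n, probs))
  n_src <- nrow(src)
  if (n_src > 0 && any(src$prob * n < 1 & src$prob > 0))
    message("some configured abundances expect < 1 read at this depth")

  seqs <- character(n)
  origin <- character(n)
  o_genome <- rep(NA_character_, n)
  o_family <- rep(NA_character_, n)
  o_cluster <- rep(NA_integer_, n)
  pos <- 1L
  for (i in seq_len(n_src)) {
    ci <- counts[i]
    if (ci == 0L) next
    k <- src$cluster_id[i]
    f <- src$family[i]
    cand <- refs[refs$cluster_id == k & refs$family == f, , drop = FALSE]
    gi <- sample.int(nrow(cand), ci, replace = TRUE)
    for (r in seq_len(ci)) {
      nt <- cand$nt_sequence[gi[r]]
      start <- sample.int(nchar(nt) - rl + 1L, 1L)
      frag <- substr(nt, start, start + rl - 1L)
      if (runif(1) < 0.5) frag <- .revcomp(frag)
      idx <- pos + r - 1L
      seqs[idx] <- frag
      origin[idx] <- "bai"
      o_genome[idx] <- cand$genome_id[gi[r]]
      o_family[idx] <- f
      o_cluster[idx] <- k
    }
    pos <- pos + ci
  }
  n_bg <- counts[n_src + 1L]
  if (n_bg > 0L) {
    # one long i.i.d. uniform nucleotide string, cut into reads
    big <- intToUtf8(sample(c(65L, 67L, 71L, 84L), n_bg * rl, replace = TRUE))
    starts <- seq(1L, by = rl, length.out = n_bg)
    seqs[pos:(pos + n_bg - 1L)] <- substring(big, starts, starts + rl - 1L)
    origin[pos:(pos + n_bg - 1L)] <- "background"
  }

  ord <- sample.int(n)
  seqs <- seqs[ord]; origin <- origin[ord]
  o_genome <- o_genome[ord]; o_family <- o_family[ord]
  o_cluster <- o_cluster[ord]

  # flat quality per read: one Phred level per read (30-40 for passing
  # reads, 5-15 for reads meant to fail the window trim)
  lowq <- runif(n) < config$low_quality_fraction
  qlev <- integer(n)
  qlev[!lowq] <- sample(30:40, sum(!lowq), replace = TRUE)
  qlev[lowq] <- sample(5:15, sum(lowq), replace = TRUE)
  qchars <- strsplit(intToUtf8(33L + 0:45), "")[[1]]
  qual <- strrep(qchars[qlev + 1L], rl)

  ids <- sprintf("%s_r%06d", sample_id, seq_len(n))
  list(reads = data.frame(read_id = ids, sequence = seqs, quality = qual,
                          stringsAsFactors = FALSE),
       sources = data.frame(read_id = ids, origin = origin,
                            genome_id = o_genome, family = o_family,
                            cluster_id = o_cluster,
                            low_quality = lowq, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw cohort-level ground truth: diagnoses, carriage and true abundances
#'
#' Each sample receives a diagnosis, then carries the operon with the
#' diagnosis-specific probability (`carriage_probs`). Carriers fall into one
#' of two carriage states, emulating the two mutually exclusive
#' bai-carrying community states seen in gut cohorts: a "healthy-like" state
#' in which clusters 1 and 2 co-occur, and an "IBD-like" state carrying
#' cluster 3 alone; `healthy_state_probs` gives the per-diagnosis
#' probability of the healthy-like state. Each carried cluster's per-gene
#' abundance is drawn log-uniformly from `carrier_abundance_range`.
#' (With fewer than 3 clusters all carriers carry cluster 1 only.)
#'
#' The per-sample true operon abundance is the summed per-gene abundance
#' across carried clusters, which is what the geometric-mean estimator
#' targets; non-carriers have zero bai abundance.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the cohort draw (defaults to `config$seed + 1`).
#' @return data.frame: `sample_id`, `diagnosis`, `carrier`, `state`
#'   (`healthy_pair`, `ibd_single` or `none`) and `true_operon_abundance`,
#'   with the per-sample per-cluster gene abundance matrix as attribute
#'   `cluster_abundance`.
#' @export
generate_cohort_truth <- function(config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  nk <- config$n_clusters
  dx <- sample(names(config$diagnosis_probs), n, replace = TRUE,
               prob = config$diagnosis_probs)
  carrier <- runif(n) < config$carriage_probs[dx]
  healthy <- carrier & (runif(n) < config$healthy_state_probs[dx])
  state <- ifelse(!carrier, "none",
                  ifelse(healthy, "healthy_pair", "ibd_single"))
  lo <- log10(config$carrier_abundance_range[1])
  hi <- log10(config$carrier_abundance_range[2])
  ab <- matrix(0, nrow = n, ncol = nk,
               dimnames = list(NULL, as.character(seq_len(nk))))
  draw <- function(m) 10^runif(m, lo, hi)
  if (nk >= 3L) {
    ab[healthy, 1L] <- draw(sum(healthy))
    ab[healthy, 2L] <- draw(sum(healthy))
    single <- carrier & !healthy
    ab[single, 3L] <- draw(sum(single))
  } else {
    ab[carrier, 1L] <- draw(sum(carrier))
  }
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), diagnosis = dx,
                    carrier = carrier, state = state,
                    true_operon_abundance = rowSums(ab),
                    stringsAsFactors = FALSE)
  attr(out, "cluster_abundance") <- ab
  out
}

#' Generate the metabolome table from true operon abundances
#'
#' log10(DCA:CA) is drawn from a normal with mean
#' `+phenotype_logratio_mean` when the true operon abundance exceeds
#' `phenotype_threshold` and `-phenotype_logratio_mean` otherwise, with SD
#' `phenotype_noise_sd`. CA is fixed at an arbitrary ion abundance and DCA
#' set so that DCA/CA realizes the drawn ratio.
#'
#' @param truth A cohort truth table ([generate_cohort_truth()]) with columns
#'   `sample_id`, `true_operon_abundance` and optionally `diagnosis`.
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return data.frame: `sample_id`, `dca`, `ca`, `diagnosis`, plus the true
#'   threshold state `above_threshold`.
#' @export
generate_metabolome <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  above <- truth$true_operon_abundance > config$phenotype_threshold
  mu <- ifelse(above, config$phenotype_logratio_mean,
               -config$phenotype_logratio_mean)
  lr <- rnorm(nrow(truth), mu, config$phenotype_noise_sd)
  ca <- 1e6
  data.frame(sample_id = truth$sample_id, dca = ca * 10^lr, ca = ca,
             diagnosis = truth$diagnosis %||% rep(NA_character_, nrow(truth)),
             above_threshold = above, stringsAsFactors = FALSE)
}

#' Generate a synthetic FMT cohort
#'
#' Subjects split into engrafters (pre-FMT operon abundance at the
#' pseudocount floor, post-FMT at `fmt_engrafted_abundance`) and
#' non-engrafters (stable at `fmt_stable_abundance`). Donor profiles sit at
#' `fmt_donor_abundance`, above the patients' pre-FMT mean. Clinical
#' response agrees with engraftment with probability
#' `fmt_response_coupling`.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 3`).
#' @return A list of `fmt_series` objects (see [fmt_series()]), one per
#'   subject, with a `donor_abundances` attribute.
#' @export
generate_fmt_cohort <- function(config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$fmt_n_subjects
  m <- config$fmt_samples_per_phase
  pc <- bai_thresholds()$pseudocount
  n_eng <- round(n * config$fmt_engraft_fraction)
  engraft <- sample(c(rep(TRUE, n_eng), rep(FALSE, n - n_eng)))
  series <- lapply(seq_len(n), function(i) {
    if (engraft[i]) {
      pre <- rep(pc, m)
      post <- rep(config$fmt_engrafted_abundance, m)
    } else {
      pre <- rep(config$fmt_stable_abundance, m)
      post <- rep(config$fmt_stable_abundance, m)
    }
    resp <- if (runif(1) < config$fmt_response_coupling) engraft[i]
            else !engraft[i]
    fmt_series(subject_id = sprintf("P%02d", i), pre = pre, post = post,
               response = resp, engrafted = engraft[i])
  })
  attr(series, "donor_abundances") <- rep(config$fmt_donor_abundance, m)
  series
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param reads The `reads` data.frame from [generate_community_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}
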