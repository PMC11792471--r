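# End-to-end synthetic pipeline: reference -> clustering -> per-sample reads
# -> QC -> translated mapping -> profiles -> metabolome -> cohort statistics,
# with deterministic TSV outputs.

.reads_df_to_list <- function(df) {
  # decode each distinct quality string once (simulated reads have flat
  # per-read qualities, so there are few)
  uq <- unique(df$quality)
  dec <- lapply(uq, function(q) utf8ToInt(q) - 33L)
  list(read_id = df$read_id, sequence = df$sequence,
       qualities = dec[match(df$quality, uq)])
}

#' Run the full synthetic pipeline
#'
#' Generates the synthetic reference set, clusters it, simulates a cohort of
#' read sets coupled to a DCA:CA metabolome through the threshold rule,
#' profiles every sample, and computes the cohort statistics (phenotype AUC,
#' chi-square of diagnosis vs phenotype, per-cluster prevalence, pairwise
#' cluster correlations). When `outdir` is given, all tables are written as
#' TSV with fixed formatting, so two runs with the same config are
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param t [bai_thresholds()].
#' @return A list: `db`, `assignment`, `pairs`, `truth`, `metabolome`,
#'   `profiles`, `phenotype` (labels), `stats` (list with `auc`, `chi2`,
#'   `prevalence`, `correlations`), and `report` (per-sample QC).
#' @export
run_pipeline <- function(config, outdir = NULL, t = bai_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  ref <- generate_reference_operons(config)
  pairs <- pairwise_operon_identity(ref$db, t)
  assignment <- cluster_genomes(pairs, t, genomes = unique(ref$db$genome_id))
  db <- assign_db_clusters(ref$db, assignment)
  clusters <- sort(unique(assignment))

  truth <- generate_cohort_truth(config)
  metab <- generate_metabolome(truth, config)

  cluster_ab <- attr(truth, "cluster_abundance")
  profiles <- vector("list", nrow(truth))
  qc_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cfg_i <- config
    abi <- cluster_ab[i, ]
    cfg_i$cluster_abundances <- if (any(abi > 0)) abi[abi > 0] else NULL
    sim <- generate_community_reads(cfg_i, ref$truth,
                                    sample_id = truth$sample_id[i],
                                    seed = config$seed + 100L + i)
    qc <- qc_pipeline(.reads_df_to_list(sim$reads), t)
    qc$reads <- remove_host_reads(qc$reads)
    hits <- map_reads(qc$reads, db, t)
    profiles[[i]] <- sample_profile(truth$sample_id[i], hits,
                                    qc$report$passed_reads, t,
                                    clusters = clusters)
    qc_rows[[i]] <- data.frame(sample_id = truth$sample_id[i],
                               input_reads = qc$report$input_reads,
                               passed_reads = qc$report$passed_reads,
                               dropped_short = qc$report$dropped_short,
                               stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, qc_rows)

  est_ab <- vapply(profiles, `[[`, 0, "operon_abundance")
  label <- ba_phenotype(metab$dca, metab$ca, t)
  stats <- list()
  if (length(unique(label)) == 2L)
    stats$auc <- mwu_auc(est_ab[label == "low_SBA"],
                         est_ab[label == "high_SBA"])
  tab <- table(metab$diagnosis, label)
  if (nrow(tab) >= 2L && ncol(tab) >= 2L &&
      all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    stats$chi2 <- chi2_association(tab)
  stats$prevalence <- do.call(rbind, lapply(clusters, function(k) {
    pv <- prevalence_by_group(profiles, k, metab$diagnosis)
    data.frame(cluster_id = k, diagnosis = names(pv), prevalence = unname(pv),
               stringsAsFactors = FALSE)
  }))
  logab <- sapply(profiles, function(p)
    setNames(log10(p$clusters$operon_abundance),
             as.character(p$clusters$cluster_id)))
  if (is.matrix(logab) && nrow(logab) >= 2L) {
    combs <- utils::combn(rownames(logab), 2L)
    stats$correlations <- do.call(rbind, lapply(seq_len(ncol(combs)),
      function(ci) {
        a <- combs[1, ci]; b <- combs[2, ci]
        r <- tryCatch(spearman_assoc(logab[a, ], logab[b, ]),
                      error = function(e) NULL)
        if (is.null(r)) return(NULL)
        data.frame(cluster_a = a, cluster_b = b, rho = r$rho,
                   p_value = r$p_value, stringsAsFactors = FALSE)
      }))
  }

  res <- list(db = db, assignment = assignment, pairs = pairs, truth = truth,
              metabolome = metab, profiles = profiles, phenotype = label,
              stats = stats, report = report)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write the pipeline result tables as TSV
#'
#' @param res Result of [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_reference_db(res$db, p("reference_db"))
  write_tsv(res$pairs, p("operon_pairs.tsv"))
  write_tsv(data.frame(genome_id = names(res$assignment),
                       cluster_id = as.integer(res$assignment),
                       stringsAsFactors = FALSE), p("clusters.tsv"))
  write_tsv(res$truth, p("truth.tsv"))
  m <- res$metabolome
  m$dca <- sprintf("%.6g", m$dca)
  write_tsv(m, p("metabolome.tsv"))
  gene_rows <- do.call(rbind, lapply(res$profiles, function(pr)
    data.frame(sample_id = pr$sample_id, family = names(pr$fractions),
               count = as.integer(pr$counts),
               fraction = sprintf("%.6g", pr$fractions),
               stringsAsFactors = FALSE)))
  write_tsv(gene_rows, p("gene_profiles.tsv"))
  ab_rows <- do.call(rbind, lapply(res$profiles, function(pr) {
    cl <- pr$clusters
    rbind(data.frame(sample_id = pr$sample_id, cluster_id = "all",
                     detected = NA,
                     operon_abundance = sprintf("%.6g", pr$operon_abundance),
                     stringsAsFactors = FALSE),
          if (!is.null(cl)) data.frame(
            sample_id = pr$sample_id, cluster_id = as.character(cl$cluster_id),
            detected = cl$detected,
            operon_abundance = sprintf("%.6g", cl$operon_abundance),
            stringsAsFactors = FALSE))
  }))
  write_tsv(ab_rows, p("operon_abundance.tsv"))
  write_tsv(res$report, p("qc_report.tsv"))
  if (!is.null(res$stats$prevalence))
    write_tsv(res$stats$prevalence, p("prevalence.tsv"))
  if (!is.null(res$stats$correlations))
    write_tsv(transform(res$stats$correlations,
                        rho = sprintf("%.6g", rho),
                        p_value = sprintf("%.6g", p_value)),
              p("correlations.tsv"))
  invisible(outdir)
}
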