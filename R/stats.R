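# Cohort statistics layer: DCA:CA phenotype binarization, chi-square
# association, Mann-Whitney U with AUC = U / (n1 * n2), Spearman rank
# correlation, Theil-Sen fits, prevalence/abundance summaries and the FMT
# fold-change analysis.

#' Binarize the bile acid phenotype from DCA and CA ion abundances
#'
#' A sample is `high_SBA` when DCA/CA exceeds the ratio cutoff (default 1,
#' i.e. strictly more DCA than CA) and `low_SBA` otherwise; exact equality
#' is labeled `low_SBA`, since "high" is defined strictly and ties are
#' measure-zero in real intensity data.
#'
#' @param dca,ca Ion abundances (arbitrary units); `ca` must be positive.
#' @param t [bai_thresholds()].
#' @return Character vector of labels (`high_SBA` / `low_SBA`).
#' @export
#' @examples
#' ba_phenotype(c(3, 0.5, 1), c(1, 1, 1))
ba_phenotype <- function(dca, ca, t = bai_thresholds()) {
  if (any(ca <= 0)) stop("CA abundance must be positive to form the ratio")
  if (any(dca < 0)) stop("DCA abundance must be nonnegative")
  ifelse(dca / ca > t$phenotype_ratio_cutoff, "high_SBA", "low_SBA")
}

#' Chi-square association between diagnosis and phenotype
#'
#' Pearson chi-square with expected counts from the row/column margins; no
#' continuity correction for tables larger than 2x2.
#'
#' @param contingency A counts matrix (e.g. diagnosis x phenotype).
#' @return A list: `statistic`, `p_value`, `degrees_of_freedom`, `n`.
#' @export
chi2_association <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be nonnegative")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2x2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  correct <- nrow(m) == 2L && ncol(m) == 2L
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       degrees_of_freedom = unname(ct$parameter), n = sum(m))
}

#' Mann-Whitney U test with AUC
#'
#' Two-sided Mann-Whitney U (midranks for ties, normal approximation with
#' tie correction). The AUC of the receiver operating characteristic is
#' obtained by dividing U by the product of the group sizes, where U counts
#' pairs in which `group2`'s value exceeds `group1`'s (ties count 1/2): an
#' AUC of 1 means `group2` stochastically dominates completely.
#'
#' @param group1,group2 Numeric vectors (e.g. predictor values in the
#'   low- and high-phenotype classes); both nonempty.
#' @return A list: `statistic` (U), `p_value`, `auc`, `n1`, `n2`.
#' @export
#' @examples
#' mwu_auc(c(1, 3), c(2, 4))$auc # 0.75
mwu_auc <- function(group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be nonempty")
  wt <- suppressWarnings(wilcox.test(group2, group1, exact = FALSE,
                                     correct = TRUE))
  u <- unname(wt$statistic)
  list(statistic = u, p_value = wt$p.value,
       auc = u / (length(group1) * length(group2)),
       n1 = length(group1), n2 = length(group2))
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of midranks, p-value via the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Theil-Sen robust line fit
#'
#' Slope is the median of all pairwise slopes (pairs with equal x are
#' skipped); the intercept is the median of `y - slope * x`.
#'
#' @param x,y Numeric vectors; `x` needs at least two distinct values.
#' @return A list: `slope`, `intercept`.
#' @export
#' @examples
#' theil_sen(c(0, 1, 2), c(0, 1, 0)) # slope 0
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L) stop("x must contain at least 2 distinct values")
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  slope <- median(dy[keep] / dx[keep])
  list(slope = slope, intercept = median(y - slope * x))
}

#' Per-group cluster prevalence
#'
#' Prevalence of a cluster in a group of samples is the fraction of samples
#' in which the cluster is detected (reads on at least
#' `min_cluster_genes_detected` of its families).
#'
#' @param profiles A list of `sample_profile` objects with per-cluster
#'   tables.
#' @param cluster_id The cluster to summarize.
#' @param groups Character vector of group labels, one per profile.
#' @return Named numeric vector of per-group prevalences.
#' @export
prevalence_by_group <- function(profiles, cluster_id, groups) {
  stopifnot(length(profiles) == length(groups))
  det <- vapply(profiles, function(p) {
    cl <- p$clusters
    i <- match(cluster_id, cl$cluster_id)
    if (is.na(i)) FALSE else cl$detected[i]
  }, NA)
  tab <- table(groups)
  if (any(tab == 0)) stop("empty group")
  out <- tapply(det, groups, mean)
  setNames(as.numeric(out), names(out))
}

#' Mean abundance of a cluster when detected
#'
#' The arithmetic mean of log10 cluster operon abundance over the samples in
#' which the cluster is detected, reported back on the abundance scale
#' (10^mean).
#'
#' @param profiles A list of `sample_profile` objects.
#' @param cluster_id Cluster to summarize.
#' @return The mean-of-logs abundance (10^mean log10).
#' @export
mean_abundance_when_detected <- function(profiles, cluster_id) {
  ab <- vapply(profiles, function(p) {
    cl <- p$clusters
    i <- match(cluster_id, cl$cluster_id)
    if (is.na(i) || !cl$detected[i]) NA_real_ else cl$operon_abundance[i]
  }, 0)
  ab <- ab[!is.na(ab)]
  if (!length(ab)) stop("cluster ", cluster_id, " detected in no sample")
  10^mean(log10(ab))
}

#' An FMT subject's pre/post series
#'
#' @param subject_id Subject identifier.
#' @param pre,post Per-sample operon abundances before/after FMT (already
#'   pseudocount-floored); both nonempty.
#' @param response Logical clinical-response flag (supplied, not computed).
#' @param engrafted Optional ground-truth engraftment flag (simulation).
#' @return An `fmt_series` object.
#' @export
fmt_series <- function(subject_id, pre, post, response, engrafted = NA) {
  if (!length(pre) || !length(post))
    stop("at least one pre and one post profile required")
  if (any(c(pre, post) <= 0))
    stop("abundances must be positive (pseudocount-floored)")
  structure(list(subject_id = subject_id, pre = pre, post = post,
                 response = isTRUE(response), engrafted = engrafted),
            class = "fmt_series")
}

#' FMT fold change of operon abundance
#'
#' Geometric mean of the post-FMT operon abundances divided by the geometric
#' mean of the pre-FMT abundances of the same subject.
#'
#' @param series An [fmt_series()].
#' @return The fold change (positive).
#' @export
#' @examples
#' s <- fmt_series("P1", pre = 1e-9, post = 1e-6, response = TRUE)
#' fmt_fold_change(s) # 1000
fmt_fold_change <- function(series) {
  stopifnot(inherits(series, "fmt_series"))
  gm <- function(v) 10^mean(log10(v))
  gm(series$post) / gm(series$pre)
}

#' Association between FMT fold change and clinical response
#'
#' Mann-Whitney U / AUC of the per-subject fold changes, non-responders as
#' group 1 and responders as group 2 (AUC 1 = responders' fold changes all
#' larger).
#'
#' @param folds Numeric per-subject fold changes.
#' @param responses Logical per-subject response flags.
#' @return As [mwu_auc()].
#' @export
fmt_response_association <- function(folds, responses) {
  stopifnot(length(folds) == length(responses))
  if (all(responses) || !any(responses))
    stop("both response classes must be present")
  mwu_auc(folds[!responses], folds[responses])
}
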