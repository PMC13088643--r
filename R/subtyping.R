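#' TMM normalization of a bulk count matrix
#'
#' Trimmed-mean-of-M-values scaling factors (log-ratio trim 30%, abundance
#' trim 5%, precision weighting) with the factors normalized to geometric
#' mean 1, plus counts-per-million on the effective library sizes.
#'
#' @param counts sample-by-gene nonnegative integer matrix.
#' @return list: `factors` (named per sample), `cpm` (sample-by-gene CPM on
#'   effective libraries), `effective_lib`.
#' @export
tmm_normalize <- function(counts) {
  if (nrow(counts) < 2L) stopf("need at least 2 samples")
  lib <- rowSums(counts)
  if (any(lib == 0)) stopf("zero library: %s",
                           paste(head(rownames(counts)[lib == 0], 3), collapse = ", "))
  dge <- edgeR::DGEList(counts = t(counts))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  f <- setNames(dge$samples$norm.factors, rownames(counts))
  eff <- lib * f
  cpm <- counts / eff * 1e6
  list(factors = f, cpm = cpm, effective_lib = eff)
}

#' Cluster-averaged, auto-scaled signature matrix
#'
#' Averages expression over the units of a grouping (clusters, patients,
#' samples) to damp cell-to-cell stochasticity, restricts to the signature
#' genes and auto-scales each gene across units.
#'
#' @param expr observations-by-genes expression matrix (one row per sample is
#'   fine for bulk: pass `grouping = rownames`).
#' @param signature a list with `classical_genes` and `basal_genes` (or
#'   `classical`/`basal`).
#' @param grouping unit label per observation.
#' @return genes-by-units auto-scaled matrix with a `units` attribute.
#' @export
signature_matrix <- function(expr, signature, grouping) {
  cls <- signature$classical_genes %||% signature$classical
  bas <- signature$basal_genes %||% signature$basal
  if (!length(cls) || !length(bas)) stopf("signature needs both arms")
  cls_in <- intersect(cls, colnames(expr))
  bas_in <- intersect(bas, colnames(expr))
  if (!length(cls_in)) stopf("no classical signature genes detected")
  if (!length(bas_in)) stopf("no basal signature genes detected")
  if (length(grouping) != nrow(expr)) stopf("grouping must align with expr rows")
  genes <- c(cls_in, bas_in)
  avg <- rowsum(expr[, genes, drop = FALSE], group = grouping)
  avg <- avg / as.vector(table(grouping)[rownames(avg)])
  m <- t(autoscale(avg))           # genes x units, scaled per gene
  attr(m, "arms") <- list(classical = cls_in, basal = bas_in)
  m
}

#' Hierarchical clustering of units (Euclidean distance, complete linkage)
#'
#' @param matrix genes-by-units matrix; columns are clustered.
#' @return an [stats::hclust] tree.
#' @export
cluster_units <- function(matrix) {
  if (ncol(matrix) < 2L) stopf("need at least 2 units")
  if (any(!is.finite(matrix))) stopf("non-finite values in input")
  hclust(dist(t(matrix)), method = "complete")
}

#' Bootstrap clade support for the 2-cut clusters of a dendrogram
#'
#' Resamples rows (features) with replacement, reclusters the columns, and
#' reports for each original 2-cut cluster the fraction of replicates in
#' which it recurs as an exact clade of the resampled tree.
#'
#' @param matrix genes-by-units matrix.
#' @param n_boot bootstrap replicates (default 10000).
#' @param threshold support level at which a cluster is flagged supported
#'   (default 0.95).
#' @param seed integer seed.
#' @param k number of primary clusters cut from the tree (default 2).
#' @return data.frame: cluster, members, support, supported.
#' @export
bootstrap_support <- function(matrix, n_boot = 10000L, threshold = 0.95,
                              seed = 0L, k = 2L) {
  if (nrow(matrix) < 2L) stopf("need at least 2 rows to resample")
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  hc <- cluster_units(matrix)
  cut <- cutree(hc, k = k)
  groups <- split(names(cut), cut)
  set.seed(seed)
  hits <- numeric(length(groups))
  units <- colnames(matrix)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(matrix), replace = TRUE)
    hb <- hclust(dist(t(matrix[rows, , drop = FALSE])), method = "complete")
    clades <- tree_clades(hb, units)
    for (gi in seq_along(groups)) {
      key <- paste(sort(groups[[gi]]), collapse = "\r")
      if (key %in% clades) hits[gi] <- hits[gi] + 1
    }
  }
  support <- hits / n_boot
  data.frame(cluster = as.integer(names(groups)),
             members = vapply(groups, paste, character(1), collapse = ","),
             support = support, supported = support >= threshold,
             stringsAsFactors = FALSE)
}

# all clades (leaf sets of internal nodes) of an hclust tree, keyed by sorted
# member string
tree_clades <- function(hc, labels) {
  n <- length(labels)
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(m)
      if (m < 0) labels[-m] else sets[[m]]))
    sets[[i]] <- members
    out[i] <- paste(sort(members), collapse = "\r")
  }
  out
}

#' Call basal/classical/mixed subtypes from a dendrogram and signature scores
#'
#' The tree is cut into two primary clusters; each cluster takes the label of
#' the arm with the higher mean score over its units; units whose
#' classical-basal score gap is below `tau` are relabeled mixed.
#'
#' @param dendrogram an [stats::hclust] tree over units (e.g. from
#'   [cluster_units()]), or NULL to label units purely by scores.
#' @param scores units-by-2 matrix or data.frame with columns `classical` and
#'   `basal` (auto-scaled score units).
#' @param tau mixed-call margin on the score gap (default 0.5).
#' @return a `subtype_call` data.frame: unit, label, classical, basal,
#'   dendro_cluster.
#' @export
call_subtypes <- function(dendrogram, scores, tau = 0.5) {
  scores <- as.data.frame(scores)
  if (!all(c("classical", "basal") %in% names(scores)))
    stopf("scores must have 'classical' and 'basal' columns")
  units <- rownames(scores)
  if (is.null(units)) stopf("scores must have unit rownames")
  if (!is.null(dendrogram)) {
    cut <- cutree(dendrogram, k = 2)
    if (length(unique(cut)) < 2L) {
      warnf("degenerate single-cluster cut: all units labeled mixed")
      lab <- rep("mixed", length(units))
      return(data.frame(unit = units, label = lab,
                        classical = scores$classical, basal = scores$basal,
                        dendro_cluster = 1L, stringsAsFactors = FALSE))
    }
    cut <- cut[units]
  } else cut <- rep(1L, length(units))
  # cluster-level label by the higher mean arm score
  clab <- vapply(split(seq_along(units), cut), function(idx) {
    if (mean(scores$basal[idx]) > mean(scores$classical[idx])) "basal" else "classical"
  }, character(1))
  lab <- if (!is.null(dendrogram)) clab[as.character(cut)]
         else ifelse(scores$basal > scores$classical, "basal", "classical")
  gap <- abs(scores$classical - scores$basal)
  lab[gap < tau] <- "mixed"
  data.frame(unit = units, label = unname(lab),
             classical = scores$classical, basal = scores$basal,
             dendro_cluster = as.integer(cut), stringsAsFactors = FALSE)
}

#' Per-unit signature arm scores
#'
#' Mean auto-scaled expression of each arm's genes per unit, computed on
#' cluster-averaged expression (see [signature_matrix()]).
#'
#' @param expr observations-by-genes expression.
#' @param signature list with classical/basal gene arms.
#' @param grouping unit per observation.
#' @return units-by-2 data.frame with columns classical, basal.
#' @export
signature_scores <- function(expr, signature, grouping) {
  m <- signature_matrix(expr, signature, grouping)
  arms <- attr(m, "arms")
  data.frame(classical = colMeans(m[arms$classical, , drop = FALSE]),
             basal = colMeans(m[arms$basal, , drop = FALSE]),
             row.names = colnames(m))
}

#' Pseudobulk aggregation: per-group per-gene count sums
#'
#' @param counts observations-by-genes count matrix.
#' @param groups group label per observation (e.g. patient x cluster).
#' @return groups-by-genes summed count matrix; empty groups dropped with a
#'   warning.
#' @export
pseudobulk <- function(counts, groups) {
  if (length(groups) != nrow(counts)) stopf("groups must align with count rows")
  if (is.factor(groups) && any(table(groups) == 0))
    warnf("dropping empty group(s)")
  rowsum(counts, group = as.character(groups))
}

#' Differential expression between two pseudobulk groups
#'
#' log2-CPM (pseudocount 1) per pseudobulk profile, then a per-gene Welch t
#' statistic whose group variances are shrunk halfway toward the mean
#' variance across genes (shrink weight 0.5); total degrees of freedom are
#' twice the Welch-Satterthwaite value, reflecting the information added by
#' shrinkage; Benjamini-Hochberg adjustment.
#'
#' @param pb groups-by-genes pseudobulk count matrix.
#' @param group_a,group_b row names of the two groups (>= 2 replicates each);
#'   log2FC is b vs a.
#' @return a `dgea_table` data.frame: gene, log2fc, t, p, padj.
#' @export
dgea <- function(pb, group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("need at least 2 replicates per group")
  miss <- setdiff(c(group_a, group_b), rownames(pb))
  if (length(miss)) stopf("unknown pseudobulk rows: %s", paste(head(miss, 3), collapse = ", "))
  lcpm <- log2(pb / rowSums(pb) * 1e6 + 1)
  a <- lcpm[group_a, , drop = FALSE]; b <- lcpm[group_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  va_s <- 0.5 * va + 0.5 * mean(va)
  vb_s <- 0.5 * vb + 0.5 * mean(vb)
  se2 <- va_s / na + vb_s / nb
  tstat <- (mb - ma) / sqrt(se2)
  df_w <- se2^2 / ((va_s / na)^2 / (na - 1) + (vb_s / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df = 2 * df_w)
  out <- data.frame(gene = colnames(pb), log2fc = mb - ma, t = tstat,
                    p = p, padj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dgea_table", "data.frame")
  out
}

#' Sigmoid scaling of log fold changes for pathway mapping
#'
#' f(A) = -0.5 + 1 / (1 + exp(-10 A)): odd, strictly increasing, and bounded
#' by 0.5 in absolute value, matching a pathway color scale from -0.5 to 0.5.
#'
#' @param logfc numeric vector of log fold changes.
#' @return scaled values in (-0.5, 0.5).
#' @export
sigmoid_scale <- function(logfc) {
  if (any(!is.finite(logfc))) stopf("inputs must be finite")
  -0.5 + 1 / (1 + exp(-10 * logfc))
}
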