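#' Rank enriched marker genes of a cluster (one-vs-rest Wilcoxon)
#'
#' For each gene, a two-sided Wilcoxon rank-sum test of the cluster's spots
#' against all other spots plus the log2 fold change of means (pseudocount
#' 1e-9). Markers are the positive-logFC genes ordered by ascending p, ties
#' broken by descending logFC then gene id; adjusted p is Benjamini-Hochberg
#' over all tested genes.
#'
#' @param matrix spots-by-genes normalized expression.
#' @param clusters cluster label per spot.
#' @param cluster_id the cluster to profile.
#' @return a `marker_table` data.frame: gene, log2fc, p, padj, rank.
#' @export
rank_markers <- function(matrix, clusters, cluster_id) {
  inside <- which(clusters == cluster_id)
  if (!length(inside)) stopf("cluster '%s' is empty", cluster_id)
  if (length(inside) == 1L) stopf("cluster '%s' has a single spot; test undefined", cluster_id)
  if (length(inside) == nrow(matrix)) stopf("cluster '%s' is the whole dataset", cluster_id)
  outside <- setdiff(seq_len(nrow(matrix)), inside)
  genes <- colnames(matrix)
  p <- numeric(length(genes)); lfc <- numeric(length(genes))
  for (j in seq_along(genes)) {
    xi <- matrix[inside, j]; xo <- matrix[outside, j]
    p[j] <- if (all(xi == xi[1]) && all(xo == xo[1]) && xi[1] == xo[1]) 1
            else suppressWarnings(wilcox.test(xi, xo)$p.value)
    lfc[j] <- log2((mean(xi) + 1e-9) / (mean(xo) + 1e-9))
  }
  padj <- p.adjust(p, "BH")
  tab <- data.frame(gene = genes, log2fc = lfc, p = p, padj = padj,
                    stringsAsFactors = FALSE)
  tab <- tab[tab$log2fc > 0, , drop = FALSE]
  tab <- tab[order(tab$p, -tab$log2fc, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' Full per-gene log2 fold change of a cluster versus the rest
#'
#' The complete signed fold-change vector (pseudocount 1e-9) over all genes,
#' the ranking statistic fed to rank-product meta-analysis and preranked
#' enrichment, where down-regulated genes must keep their low ranks.
#'
#' @param matrix spots-by-genes normalized expression.
#' @param clusters cluster label per spot.
#' @param cluster_id the cluster to profile.
#' @return named numeric vector over all genes.
#' @export
group_log2fc <- function(matrix, clusters, cluster_id) {
  inside <- clusters == cluster_id
  if (!any(inside)) stopf("cluster '%s' is empty", cluster_id)
  if (all(inside)) stopf("cluster '%s' is the whole dataset", cluster_id)
  m_in <- colMeans(matrix[inside, , drop = FALSE])
  m_out <- colMeans(matrix[!inside, , drop = FALSE])
  setNames(log2((m_in + 1e-9) / (m_out + 1e-9)), colnames(matrix))
}

marker_genes <- function(x, top_n) {
  g <- if (is.data.frame(x)) x$gene else as.character(x)
  head(g, top_n)
}

#' Cross-patient marker intersection (UpSet counts + congruent set)
#'
#' Computes the exclusive intersection size for every nonempty patient subset
#' (the counts behind an UpSet plot) over the union of top-N marker genes, and
#' the congruent marker set: genes present in the top-N list of at least
#' `min_patients` patients.
#'
#' @param tables named list: patient -> `marker_table` (or character vector of
#'   genes, best first).
#' @param top_n genes taken from the head of each list (default 50; use 100
#'   for similarity analyses). Clipped with a warning where lists are shorter.
#' @param min_patients membership threshold for the congruent set; defaults to
#'   all patients.
#' @return an `intersection_report`: `exclusive` data.frame (patients, size),
#'   `congruent` gene vector, `membership` logical gene-by-patient matrix.
#' @export
intersect_markers <- function(tables, top_n = 50L, min_patients = length(tables)) {
  if (length(tables) < 2L) stopf("need at least 2 patients")
  if (is.null(names(tables))) names(tables) <- sprintf("P%02d", seq_along(tables))
  top_n <- check_count(top_n, "top_n")
  sets <- lapply(tables, function(tb) {
    g <- marker_genes(tb, top_n)
    g
  })
  short <- vapply(tables, function(tb) length(if (is.data.frame(tb)) tb$gene else tb),
                  numeric(1)) < top_n
  if (any(short)) warnf("top_n clipped for %d patient(s) with shorter lists", sum(short))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (!is.matrix(membership)) membership <- matrix(membership, nrow = length(universe))
  dimnames(membership) <- list(universe, names(tables))
  congruent <- universe[rowSums(membership) >= min_patients]
  exclusive <- NULL
  if (length(tables) > 24L) {
    warnf("more than 24 patients: exclusive subset enumeration refused")
  } else if (length(universe)) {
    mask <- as.integer(membership %*% 2^(seq_along(sets) - 1))
    tab <- table(mask)
    combo <- vapply(as.integer(names(tab)), function(m)
      paste(names(sets)[bitwAnd(m, 2^(seq_along(sets) - 1)) > 0], collapse = "&"),
      character(1))
    exclusive <- data.frame(patients = combo, size = as.integer(tab),
                            stringsAsFactors = FALSE)
    exclusive <- exclusive[order(-exclusive$size, exclusive$patients), ]
    rownames(exclusive) <- NULL
  } else {
    exclusive <- data.frame(patients = character(0), size = integer(0))
  }
  structure(list(exclusive = exclusive, congruent = congruent,
                 membership = membership, top_n = top_n,
                 min_patients = min_patients),
            class = "intersection_report")
}

#' Pairwise Jaccard similarity of marker gene sets
#'
#' J(A,B) = |A intersect B| / |A union B|; diagonal 1; symmetric. A pair of
#' empty sets is defined as 0 with a warning.
#'
#' @param sets named list of character gene sets.
#' @return symmetric numeric matrix.
#' @export
jaccard_matrix <- function(sets) {
  if (!length(sets)) stopf("sets must be nonempty")
  if (is.null(names(sets))) names(sets) <- sprintf("set%d", seq_along(sets))
  n <- length(sets)
  J <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  warned <- FALSE
  for (i in seq_len(n)) for (j in i:n) {
    a <- unique(sets[[i]]); b <- unique(sets[[j]])
    u <- length(union(a, b))
    if (u == 0) {
      if (!warned) { warnf("pair of empty sets: Jaccard defined as 0"); warned <- TRUE }
      J[i, j] <- J[j, i] <- 0
    } else J[i, j] <- J[j, i] <- length(intersect(a, b)) / u
  }
  diag(J)[vapply(sets, function(s) length(unique(s)) > 0, logical(1))] <- 1
  J
}

#' PCA embedding of clusters from their pairwise Jaccard similarities
#'
#' @param matrix square symmetric Jaccard matrix (rows = clusters).
#' @param n_components components to keep (default 3).
#' @return as [pca_reduce()].
#' @export
jaccard_pca <- function(matrix, n_components = 3L) {
  if (nrow(matrix) != ncol(matrix) || any(abs(matrix - t(matrix)) > 1e-12))
    stopf("input must be square and symmetric")
  pca_reduce(matrix, n_components = n_components)
}

#' Penalized rank-product meta-analysis across comparisons
#'
#' Within each comparison, genes are ranked ascending by score so the most
#' up-regulated gene receives the highest rank number (ties get average
#' ranks); genes absent from a comparison receive rank 1 — the penalty for
#' inconsistent up-regulation. The meta-order is by descending product of
#' rank numbers, ties broken by gene id; the gene with the largest product is
#' meta-rank 1.
#'
#' @param lists named list: comparison -> named numeric vector (gene -> score,
#'   larger = more up-regulated).
#' @return a `rank_meta_result` data.frame: gene, one rank column per
#'   comparison, rank_product, meta_rank.
#' @export
rank_product <- function(lists) {
  if (length(lists) < 2L) stopf("need at least 2 comparisons")
  if (is.null(names(lists))) names(lists) <- sprintf("cmp%d", seq_along(lists))
  for (nm in names(lists))
    if (!length(lists[[nm]])) stopf("comparison '%s' is empty", nm)
  universe <- sort(unique(unlist(lapply(lists, names))))
  if (!length(universe)) stopf("scores must be named by gene")
  ranks <- matrix(1, nrow = length(universe), ncol = length(lists),
                  dimnames = list(universe, names(lists)))
  for (j in seq_along(lists)) {
    sc <- lists[[j]]
    r <- rank(sc, ties.method = "average")   # ascending: top gene = highest number
    ranks[names(sc), j] <- r
  }
  prod <- apply(ranks, 1, prod)
  ord <- order(-prod, universe)
  out <- data.frame(gene = universe[ord], ranks[ord, , drop = FALSE],
                    rank_product = prod[ord],
                    meta_rank = seq_along(universe),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rank_meta_result", "data.frame")
  out
}
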