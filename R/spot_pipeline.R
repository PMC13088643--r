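#' Quality-filter spots by detected-gene count and an exclusion list
#'
#' Removes spots detecting fewer than `min_genes` genes (strictly fewer: a
#' spot at exactly the threshold is retained) and spots named in
#' `exclusion_ids`, the stand-in for morphology/fold-based manual exclusion.
#'
#' @param dataset a `spot_dataset`.
#' @param min_genes minimum detected (nonzero) genes per spot; default 200.
#' @param exclusion_ids spot ids to drop regardless of depth.
#' @return filtered `spot_dataset`; `qc_flags` records the removal reason for
#'   every input spot.
#' @export
filter_spots <- function(dataset, min_genes = 200L, exclusion_ids = character()) {
  stopifnot(inherits(dataset, "spot_dataset"))
  min_genes <- check_count(min_genes, "min_genes", min = 0L)
  detected <- rowSums(dataset$counts > 0)
  excluded <- rownames(dataset$counts) %in% exclusion_ids
  low <- detected < min_genes
  reason <- ifelse(excluded, "excluded",
                   ifelse(low, sprintf("low_genes(%d)", detected), ""))
  keep <- !(excluded | low)
  if (!any(keep)) stopf("all %d spots removed by QC", nrow(dataset$counts))
  out <- subset_spots(dataset, rownames(dataset$counts)[keep])
  out$qc_flags <- data.frame(spot_id = rownames(dataset$counts), pass = keep,
                             reason = reason, stringsAsFactors = FALSE)
  out
}

#' Library-size normalize and log-transform
#'
#' Scales each spot to 10,000 total counts and applies log1p, so spots with
#' proportional counts map to identical profiles.
#'
#' @param x a `spot_dataset` or a spots-by-genes count matrix.
#' @return dense spots-by-genes matrix of log-normalized expression.
#' @export
normalize_log <- function(x) {
  counts <- if (inherits(x, "spot_dataset")) x$counts else as.matrix(x)
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    bad <- rownames(counts)[lib == 0] %||% which(lib == 0)
    stopf("all-zero spot(s): %s", paste(head(bad, 3), collapse = ", "))
  }
  log1p(counts / lib * 1e4)
}

#' Select highly variable genes by dispersion
#'
#' Dispersion is variance/mean of normalized expression on the count scale:
#' log-transformed input is de-logged (expm1) first, so that overdispersion
#' beyond Poisson — not low-abundance log-scale noise — drives selection.
#' The top `n` genes are returned, ties broken by gene identifier so
#' selection is deterministic.
#'
#' @param matrix spots-by-genes normalized matrix (log1p scale, as returned
#'   by [normalize_log()]).
#' @param n number of genes; clipped to the number available.
#' @return character vector of gene ids, highest dispersion first.
#' @export
select_hvg <- function(matrix, n = 2000L) {
  n <- check_count(n, "n")
  e <- expm1(matrix)
  mu <- colMeans(e)
  v <- apply(e, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ids <- colnames(matrix) %||% as.character(seq_along(disp))
  ord <- order(-disp, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Auto-scale a matrix per gene (column): mean 0, sample SD 1
#'
#' Constant genes map to zero; values are clipped to +/-10.
#'
#' @param matrix numeric matrix, observations in rows, genes in columns.
#' @return scaled matrix of the same shape.
#' @export
autoscale <- function(matrix) {
  if (any(!is.finite(matrix))) stopf("autoscale requires finite entries")
  mu <- colMeans(matrix)
  s <- apply(matrix, 2, sd)
  s[s == 0 | is.na(s)] <- Inf   # constant columns -> 0 after centering
  out <- sweep(sweep(matrix, 2, mu, "-"), 2, s, "/")
  pmin(pmax(out, -10), 10)
}

#' Principal component analysis with a fixed sign convention
#'
#' Columns are centered; components are sorted by decreasing variance and
#' each component's sign is fixed so its largest-magnitude loading is
#' positive. Rank-deficient inputs are truncated with a warning.
#'
#' @param matrix observations-by-features numeric matrix.
#' @param n_components number of components (default 30).
#' @return list with `scores`, `loadings`, `explained_variance` (fraction per
#'   kept component), `sdev`.
#' @export
pca_reduce <- function(matrix, n_components = 30L) {
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(matrix)))
    stopf("n_components exceeds min(dim(matrix))")
  p <- prcomp(matrix, center = TRUE, scale. = FALSE, rank. = n_components)
  keep <- which(p$sdev[seq_len(ncol(p$x))] > 1e-10)
  if (length(keep) < n_components) {
    warnf("rank-deficient input: keeping %d of %d requested components",
          length(keep), n_components)
  }
  scores <- p$x[, keep, drop = FALSE]
  load <- p$rotation[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  totvar <- sum(p$sdev^2)
  list(scores = scores, loadings = load,
       explained_variance = p$sdev[keep]^2 / totvar, sdev = p$sdev[keep])
}

#' Build an undirected k-nearest-neighbor graph
#'
#' Union of the directed kNN relations under Euclidean distance; unweighted;
#' distance ties broken by index.
#'
#' @param embedding observations-by-dimensions matrix.
#' @param k neighbors per observation (default 10); must be < n.
#' @return an [igraph::graph] object with vertex names from rownames.
#' @export
knn_graph <- function(embedding, k = 10L) {
  k <- check_count(k, "k")
  n <- nrow(embedding)
  if (k >= n) stopf("k (%d) must be smaller than the number of points (%d)", k, n)
  d <- as.matrix(dist(embedding))
  edges <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])          # ties broken by index via order stability
    nb <- (seq_len(n)[-i])[ord][seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(rownames(embedding)))
    igraph::V(g)$name <- rownames(embedding)
  g
}

#' Louvain community detection on a spot graph
#'
#' @param graph an igraph object.
#' @param resolution Louvain resolution (default 0.8).
#' @param seed integer seed; the partition is deterministic given it.
#' @param restarts randomized restarts; the highest-modularity partition wins.
#' @return a `cluster_result`: `labels` (named integer per vertex),
#'   `modularity`, `params`.
#' @export
louvain_cluster <- function(graph, resolution = 0.8, seed = 0L, restarts = 5L) {
  if (igraph::vcount(graph) == 0) stopf("empty graph")
  if (!is.null(igraph::V(graph)$name)) {
    # canonical vertex order makes the partition independent of input order
    graph <- igraph::permute(graph, order(order(igraph::V(graph)$name)))
  }
  nm <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  if (igraph::ecount(graph) == 0) {
    warnf("graph has no edges: each node is its own community")
    labels <- setNames(seq_len(igraph::vcount(graph)), nm)
    return(structure(list(labels = labels, modularity = 0,
                          params = list(resolution = resolution, seed = seed)),
                     class = "cluster_result"))
  }
  set.seed(seed)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(max(1L, restarts))) {
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    q <- igraph::modularity(graph, igraph::membership(cl))
    if (q > best_q) { best_q <- q; best <- cl }
  }
  labels <- setNames(as.integer(igraph::membership(best)), nm)
  structure(list(labels = labels,
                 modularity = igraph::modularity(graph, igraph::membership(best)),
                 params = list(resolution = resolution, seed = seed)),
            class = "cluster_result")
}

#' Annotate clusters with canonical marker panels
#'
#' Scores each cluster by the mean auto-scaled expression of each panel's
#' genes and assigns the argmax panel. A cluster is flagged `mixed` when the
#' second-best score reaches `margin` times the best (both positive), and
#' `ambiguous` when no panel scores above zero.
#'
#' @param matrix spots-by-genes normalized expression.
#' @param clusters cluster label per spot (named or aligned to rows).
#' @param panels named list: cell type -> canonical marker genes.
#' @param margin mixed-call margin as a fraction of the best score (default 0.75).
#' @return data.frame: cluster, assigned type, best/second scores, purity flag,
#'   plus a `scores` attribute (cluster x panel matrix).
#' @export
annotate_clusters <- function(matrix, clusters, panels, margin = 0.75) {
  if (!length(panels)) stopf("panels must be nonempty")
  if (length(clusters) != nrow(matrix)) stopf("clusters must align with matrix rows")
  z <- autoscale(matrix)
  panel_use <- lapply(panels, function(g) {
    found <- intersect(g, colnames(matrix))
    if (!length(found)) stopf("panel has no genes present in the matrix")
    if (length(found) < length(g))
      warnf("dropping %d panel genes absent from the matrix", length(g) - length(found))
    found
  })
  cls <- sort(unique(clusters))
  scores <- matrix(NA_real_, length(cls), length(panels),
                   dimnames = list(as.character(cls), names(panels)))
  for (ci in seq_along(cls)) {
    rows <- which(clusters == cls[ci])
    if (!length(rows)) stopf("empty cluster: %s", cls[ci])
    for (pa in names(panel_use))
      scores[ci, pa] <- mean(z[rows, panel_use[[pa]], drop = FALSE])
  }
  out <- data.frame(cluster = cls, stringsAsFactors = FALSE)
  out$type <- colnames(scores)[max.col(scores, ties.method = "first")]
  out$score <- apply(scores, 1, max)
  out$second <- apply(scores, 1, function(r) sort(r, decreasing = TRUE)[2])
  out$purity <- ifelse(out$score <= 0, "ambiguous",
                       ifelse(out$second >= margin * out$score & out$second > 0,
                              "mixed", "pure"))
  attr(out, "scores") <- scores
  out
}
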