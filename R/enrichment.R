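#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running sum with weight exponent 1: walking
#' down the ranking, set members add |stat| / sum(|stat| over members) and
#' non-members subtract 1 / (N - n); ES is the signed extremum. The null is
#' by gene-label permutation; NES is ES divided by the mean |null ES| of
#' matching sign and p is the add-one permutation tail of the same sign.
#' Sets with fewer than `min_size` detected genes are skipped.
#'
#' @param ranked_stats named numeric vector, gene -> ranking statistic.
#' @param sets named list of gene sets.
#' @param min_size minimum detected genes per set (default 5).
#' @param n_perm permutations (default 1000, >= 100).
#' @param seed integer seed.
#' @return data.frame: set, size, es, nes, p.
#' @export
preranked_gsea <- function(ranked_stats, sets, min_size = 5L, n_perm = 1000L,
                           seed = 0L) {
  if (!length(ranked_stats)) stopf("empty ranking")
  if (is.null(names(ranked_stats)) || anyDuplicated(names(ranked_stats)))
    stopf("ranking must be named with unique gene ids")
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  ord <- order(ranked_stats, decreasing = TRUE)
  stats_sorted <- ranked_stats[ord]
  genes_sorted <- names(stats_sorted)
  N <- length(stats_sorted)
  hit_list <- lapply(sets, function(s) which(genes_sorted %in% s))
  set.seed(seed)
  rows <- list()
  for (nm in names(sets)) {
    hits <- hit_list[[nm]]
    n <- length(hits)
    if (n < min_size || n >= N) next
    es <- gsea_es(stats_sorted, hits)
    null_es <- vapply(seq_len(n_perm), function(b)
      gsea_es(stats_sorted, sample.int(N, n)), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    rows[[nm]] <- data.frame(set = nm, size = n, es = es, nes = nes, p = p,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(set = character(0), size = integer(0), es = numeric(0),
                         nes = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

# signed-extremum running sum on a sorted stat vector; hits are positions
gsea_es <- function(stats_sorted, hits) {
  N <- length(stats_sorted)
  w <- abs(stats_sorted[hits])
  nr <- sum(w)
  inc <- rep(-1 / (N - length(hits)), N)
  inc[hits] <- if (nr > 0) w / nr else 1 / length(hits)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Per-sample gene set score (mean-z difference)
#'
#' Each sample's expression profile is z-scored across genes; the score is
#' the mean z of the set genes minus the mean z of all other genes. Because
#' the z-scoring is within sample, adding a constant to every gene of a
#' sample leaves its score unchanged.
#'
#' @param expr genes-by-samples expression matrix.
#' @param set character gene set (>= 1 gene detected; must not cover all genes).
#' @return named numeric score per sample.
#' @export
sample_set_score <- function(expr, set) {
  inset <- rownames(expr) %in% set
  if (!any(inset)) stopf("no set genes detected")
  if (all(inset)) stopf("set covers all genes; score undefined")
  z <- autoscale(expr)   # columns are samples: z across genes within sample
  colMeans(z[inset, , drop = FALSE]) - colMeans(z[!inset, , drop = FALSE])
}
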