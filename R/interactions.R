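#' Permutation test of ligand-receptor interactions between cell types
#'
#' For each ligand-receptor pair the interaction mean is half the sum of the
#' ligand's mean expression in the sender population and the receptor's mean
#' in the receiver population. A null distribution is built by shuffling the
#' cell-type labels `n_perm` times (the same shuffles across pairs); the
#' add-one permutation p-value is (1 + #\{null >= observed\}) / (n_perm + 1).
#' An interaction is retained when its mean exceeds `mean_cutoff` and p is
#' below `alpha`. Directional: sender -> receiver.
#'
#' @param expr genes-by-cells expression matrix.
#' @param labels cell-type label per cell (column).
#' @param pairs data.frame with columns `ligand` and `receptor`; pairs with
#'   undetected genes are skipped with a warning.
#' @param sender,receiver cell-type labels.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param mean_cutoff interaction-mean retention cutoff (default 0.5).
#' @param seed integer seed.
#' @param subsample optional number of cells sampled (without replacement)
#'   before testing; NULL uses all cells.
#' @return data.frame: ligand, receptor, sender, receiver, mean, p, retained.
#' @export
lr_interaction_test <- function(expr, labels, pairs, sender, receiver,
                                n_perm = 1000L, alpha = 0.05,
                                mean_cutoff = 0.5, seed = 0L,
                                subsample = NULL) {
  if (length(labels) != ncol(expr)) stopf("labels must align with expr columns")
  n_perm <- check_count(n_perm, "n_perm")
  set.seed(seed)
  if (!is.null(subsample) && subsample < ncol(expr)) {
    keep <- sample.int(ncol(expr), subsample)
    expr <- expr[, keep, drop = FALSE]; labels <- labels[keep]
  }
  s_idx <- which(labels == sender); r_idx <- which(labels == receiver)
  if (!length(s_idx)) stopf("no cells with sender label '%s'", sender)
  if (!length(r_idx)) stopf("no cells with receiver label '%s'", receiver)
  detected <- pairs$ligand %in% rownames(expr) & pairs$receptor %in% rownames(expr)
  if (any(!detected)) warnf("skipping %d pair(s) with undetected genes", sum(!detected))
  pairs <- pairs[detected, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(ligand = character(0), receptor = character(0),
                      sender = character(0), receiver = character(0),
                      mean = numeric(0), p = numeric(0), retained = logical(0)))
  n_cells <- ncol(expr)
  # one label shuffle per permutation, shared across pairs: column b holds a
  # permutation of the cells, so null sender/receiver groups stay disjoint
  perm_all <- replicate(n_perm, sample.int(n_cells))
  perm_s <- matrix(perm_all[s_idx, ], nrow = length(s_idx))
  perm_r <- matrix(perm_all[r_idx, ], nrow = length(r_idx))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    lig <- expr[pairs$ligand[i], ]; rec <- expr[pairs$receptor[i], ]
    obs <- 0.5 * (mean(lig[s_idx]) + mean(rec[r_idx]))
    null <- 0.5 * (colMeans(matrix(lig[perm_s], nrow = length(s_idx))) +
                   colMeans(matrix(rec[perm_r], nrow = length(r_idx))))
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
    data.frame(ligand = pairs$ligand[i], receptor = pairs$receptor[i],
               sender = sender, receiver = receiver, mean = obs, p = p,
               retained = obs > mean_cutoff && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
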