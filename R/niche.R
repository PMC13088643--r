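#' Build a gate rule
#' @param marker marker column name.
#' @param op one of ">", "<", ">=", "<=".
#' @param threshold finite numeric threshold.
#' @return a `gate_rule` list.
#' @export
gate_rule <- function(marker, op, threshold) {
  if (!op %in% c(">", "<", ">=", "<=")) stopf("unsupported operator '%s'", op)
  if (!is.finite(threshold)) stopf("threshold must be finite")
  structure(list(marker = marker, op = op, threshold = threshold),
            class = "gate_rule")
}

#' Default cancer-cell gates: MUC1 > 50 and Collagen I < 500
#' @return list of `gate_rule`s.
#' @export
default_gates <- function() {
  list(gate_rule("MUC1", ">", 50), gate_rule("CollagenI", "<", 500))
}

#' Gate cells by a conjunction of marker-intensity rules
#'
#' @param table a `cell_table` data.frame with marker columns and
#'   `region_grade`.
#' @param rules list of [gate_rule()]s (default: MUC1 > 50 and
#'   Collagen I < 500), combined with AND.
#' @return the gated `cell_table`; a `grade_counts` attribute holds retained
#'   cells per grade group. An impossible conjunction yields an empty table
#'   with a warning, not an error.
#' @export
gate_cells <- function(table, rules = default_gates()) {
  keep <- rep(TRUE, nrow(table))
  for (r in rules) {
    if (!r$marker %in% names(table)) stopf("unknown marker '%s'", r$marker)
    v <- table[[r$marker]]
    keep <- keep & switch(r$op, ">" = v > r$threshold, "<" = v < r$threshold,
                          ">=" = v >= r$threshold, "<=" = v <= r$threshold)
  }
  out <- table[keep, , drop = FALSE]
  if (!nrow(out)) warnf("gates retained no cells")
  attr(out, "grade_counts") <- table(factor(out$region_grade))
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Normalize a marker to the median intensity of a reference grade group
#'
#' @param table a `cell_table`.
#' @param marker marker column.
#' @param ref_group reference grade group (default "G1-2", the pooled
#'   G1/G1-2 areas).
#' @return numeric vector: each cell's intensity divided by the reference
#'   median (reference median maps to 1).
#' @export
normalize_to_reference <- function(table, marker, ref_group = "G1-2") {
  if (!marker %in% names(table)) stopf("unknown marker '%s'", marker)
  ref <- table[[marker]][table$region_grade == ref_group]
  if (!length(ref)) stopf("reference group '%s' is empty", ref_group)
  med <- median(ref)
  if (med == 0) stopf("reference median is zero for '%s'", marker)
  table[[marker]] / med
}

#' Kruskal-Wallis test (tie-corrected)
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups of >= 2).
#' @return list with `H` and `p` (chi-square, g - 1 df).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  if (any(sizes < 2L)) stopf("every group needs at least 2 observations")
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with tie
#' correction T = sum(t^3 - t) / (12 (N - 1)); two-sided normal p-values
#' (unadjusted; feed them to [fdr_two_stage()]).
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @return data.frame: group1, group2, z, p.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  if (any(sizes < 2L)) stopf("every group needs at least 2 observations")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[c] <- (rbar[[i]] - rbar[[j]]) / se
    p[c] <- 2 * pnorm(-abs(z[c]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Two-stage step-up FDR control (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1: BH at q' = alpha / (1 + alpha) yields r1 rejections; the null
#' count is estimated as m0 = m - r1; stage 2 reruns BH at q' m / m0.
#' Adjusted p-values are the BH-adjusted values scaled by (m0 / m)(1 + alpha),
#' capped at 1, so `adjusted <= alpha` reproduces the two-stage rejection set.
#'
#' @param pvals numeric p-values in \[0,1\].
#' @param alpha target FDR (default 0.05).
#' @return list: `adjusted`, `rejected` (logical), `m0`.
#' @export
fdr_two_stage <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(adjusted = numeric(0), rejected = logical(0), m0 = 0L))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must lie in [0,1]")
  m <- length(pvals)
  qprime <- alpha / (1 + alpha)
  pbh <- p.adjust(pvals, "BH")
  r1 <- sum(pbh <= qprime)
  m0 <- m - r1
  if (m0 == 0L) {
    adjusted <- rep(0, m)   # stage 1 rejected everything
    return(list(adjusted = adjusted, rejected = rep(TRUE, m), m0 = 0L))
  }
  adjusted <- pmin(1, pbh * (m0 / m) * (1 + alpha))
  list(adjusted = adjusted, rejected = adjusted <= alpha, m0 = m0)
}

#' Spearman correlation with field-standard strength classification
#'
#' Midrank Spearman rho; moderate correlation at rho > 0.3, strong at
#' rho > 0.5 (absolute value).
#'
#' @param x,y paired numeric vectors (>= 3 pairs).
#' @return list: `rho`, `class` in none/moderate/strong.
#' @export
spearman_classify <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stopf("need >= 3 paired observations")
  if (all(x == x[1]) || all(y == y[1])) stopf("constant vector: rho undefined")
  rho <- cor(x, y, method = "spearman")
  cls <- if (abs(rho) > 0.5) "strong" else if (abs(rho) > 0.3) "moderate" else "none"
  list(rho = rho, class = cls)
}

#' Grade-group quantification of gated multiplex markers
#'
#' For each marker: reference-normalized intensities, Kruskal-Wallis across
#' grade groups, Dunn pairwise z/p, and log2 fold change of median normalized
#' intensity vs the reference group. Dunn p-values are pooled across markers
#' and pairs into one two-stage FDR adjustment.
#'
#' @param table a gated `cell_table`.
#' @param markers marker columns to quantify.
#' @param ref_group reference grade group (default "G1-2").
#' @param alpha FDR level (default 0.05).
#' @return list: `tests` (marker-level KW), `pairwise` (Dunn rows with pooled
#'   adjusted p), `log2fc_median` (marker x grade matrix).
#' @export
grade_group_stats <- function(table, markers, ref_group = "G1-2", alpha = 0.05) {
  grades <- sort(unique(table$region_grade))
  tests <- list(); pw <- list()
  fc <- matrix(NA_real_, length(markers), length(grades),
               dimnames = list(markers, grades))
  for (m in markers) {
    v <- normalize_to_reference(table, m, ref_group)
    kw <- kruskal_wallis(v, table$region_grade)
    tests[[m]] <- data.frame(marker = m, H = kw$H, p = kw$p,
                             stringsAsFactors = FALSE)
    d <- dunn_posthoc(v, table$region_grade)
    d$marker <- m
    pw[[m]] <- d
    med <- tapply(v, table$region_grade, median)
    fc[m, names(med)] <- log2(med / med[[ref_group]])
  }
  pairwise <- do.call(rbind, pw)
  fdr <- fdr_two_stage(pairwise$p, alpha = alpha)
  pairwise$padj <- fdr$adjusted
  pairwise$rejected <- fdr$rejected
  rownames(pairwise) <- NULL
  list(tests = do.call(rbind, tests), pairwise = pairwise, log2fc_median = fc)
}
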