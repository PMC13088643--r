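#' Spearman distance between spot expression profiles
#'
#' d(i, j) = (1 - rho_spearman(i, j)) / 2, computed with midranks, so
#' identical profiles are at distance 0 and perfectly reversed rank profiles
#' at distance 1.
#'
#' @param matrix spots-by-genes expression (typically over HVGs; >= 3 genes).
#' @return symmetric spots-by-spots distance matrix with zero diagonal.
#' @export
spearman_distance <- function(matrix) {
  if (ncol(matrix) < 3L) stopf("need at least 3 genes")
  const <- apply(matrix, 1, function(r) all(r == r[1]))
  if (any(const)) {
    bad <- rownames(matrix)[const] %||% which(const)
    stopf("constant spot profile(s): %s", paste(head(bad, 3), collapse = ", "))
  }
  ranks <- t(apply(matrix, 1, rank))        # midranks
  rho <- cor(t(ranks))
  d <- (1 - rho) / 2
  diag(d) <- 0
  pmin(pmax(d, 0), 1)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and embeds on the top eigenvectors;
#' components with nonpositive eigenvalues are truncated and padded with
#' zeros so the output always has `n_components` columns.
#'
#' @param dist_matrix square symmetric nonnegative distance matrix.
#' @param n_components dimensions to return (default 3).
#' @return spots-by-`n_components` coordinate matrix.
#' @export
classical_mds <- function(dist_matrix, n_components = 3L) {
  dm <- as.matrix(dist_matrix)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8) || any(dm < 0))
    stopf("input must be a square symmetric nonnegative matrix")
  n_components <- check_count(n_components, "n_components")
  fit <- suppressWarnings(cmdscale(dm, k = min(n_components, nrow(dm) - 1), eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < n_components) {
    pad <- matrix(0, nrow(dm), n_components - (if (is.null(pts)) 0 else ncol(pts)))
    pts <- cbind(pts, pad)
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  pts[, seq_len(n_components), drop = FALSE]
}

# shortest Hamiltonian path through k points: exhaustive for k <= 8,
# greedy + 2-opt beyond
shortest_path_order <- function(centers) {
  k <- nrow(centers)
  d <- as.matrix(dist(centers))
  path_len <- function(ord) sum(d[cbind(ord[-k], ord[-1])])
  if (k <= 8L) {
    perms <- all_permutations(k)
    perms <- perms[perms[, 1] < perms[, k], , drop = FALSE]  # undirected dedupe
    lens <- apply(perms, 1, path_len)
    return(perms[which.min(lens), ])
  }
  ord <- integer(k); used <- logical(k); ord[1] <- 1L; used[1] <- TRUE
  for (i in 2:k) {
    cand <- which(!used)
    ord[i] <- cand[which.min(d[ord[i - 1], cand])]
    used[ord[i]] <- TRUE
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(k - 2)) for (j in (i + 1):(k - 1)) {
      new <- c(ord[seq_len(i)], rev(ord[(i + 1):j]), ord[(j + 1):k])
      if (path_len(new) < path_len(ord) - 1e-12) { ord <- new; improved <- TRUE }
    }
  }
  ord
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 1L
  for (i in seq_len(k)) for (s in seq_len(nrow(sub))) {
    row <- integer(k); row[i] <- k
    row[-i] <- sub[s, ]
    out[r, ] <- row; r <- r + 1L
  }
  out
}

# arc-length resample a polyline to m points
resample_curve <- function(curve, m = 100L) {
  seg <- sqrt(rowSums((curve[-1, , drop = FALSE] - curve[-nrow(curve), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(curve[rep(1, m), , drop = FALSE])
  grid <- seq(0, s[length(s)], length.out = m)
  apply(curve, 2, function(col) approx(s, col, xout = grid, ties = "ordered")$y)
}

# project points onto a polyline; returns arc-length position and distance
project_on_curve <- function(points, curve) {
  nseg <- nrow(curve) - 1L
  seg_start <- curve[-nrow(curve), , drop = FALSE]
  seg_vec <- curve[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  s0 <- c(0, cumsum(seg_len))[seq_len(nseg)]
  n <- nrow(points)
  best_d2 <- rep(Inf, n); best_s <- numeric(n)
  for (j in seq_len(nseg)) {
    rel <- sweep(points, 2, seg_start[j, ], "-")
    tt <- if (seg_len2[j] > 0) pmin(pmax(drop(rel %*% seg_vec[j, ]) / seg_len2[j], 0), 1) else rep(0, n)
    proj <- outer(tt, seg_vec[j, ])
    d2 <- rowSums((rel - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s0[j] + tt[upd] * seg_len[j]
  }
  list(s = best_s, d2 = best_d2, total = sum(seg_len))
}

# Extend both ends of a polyline so points clamped onto an endpoint regain
# distinct arc positions. The end direction is taken a few resampled points
# inward (robust to terminal wiggle) and the extension only spans the points
# that actually project onto that endpoint.
extend_curve <- function(curve, points) {
  pr <- project_on_curve(points, curve)
  m <- nrow(curve)
  a <- min(5L, m - 1L)
  d1 <- curve[1, ] - curve[1 + a, ]
  n1 <- sqrt(sum(d1^2))
  clamped <- pr$s <= 1e-12
  if (n1 > 0 && any(clamped)) {
    u <- d1 / n1
    ext <- max(0, max(sweep(points[clamped, , drop = FALSE], 2, curve[1, ], "-") %*% u)) + 1e-9
    curve <- rbind(curve[1, ] + u * ext, curve)
  }
  m <- nrow(curve)
  a <- min(5L, m - 1L)
  d2 <- curve[m, ] - curve[m - a, ]
  n2 <- sqrt(sum(d2^2))
  clamped <- pr$s >= pr$total - 1e-12
  if (n2 > 0 && any(clamped)) {
    u <- d2 / n2
    ext <- max(0, max(sweep(points[clamped, , drop = FALSE], 2, curve[m, ], "-") %*% u)) + 1e-9
    curve <- rbind(curve, curve[m, ] + u * ext)
  }
  curve
}

#' Infer a linear pseudotime trajectory through a low-dimensional embedding
#'
#' Seeded k-means (10 restarts) summarizes the cloud into k centroids; the
#' shortest Hamiltonian path through the centroids (exhaustive for k <= 8)
#' gives the initial piecewise-linear backbone, refined as a principal curve:
#' points are projected onto the curve, ordered by arc length, the curve is
#' recomputed as moving averages along that order, resampled to 100 points,
#' until the mean curve shift drops below 1e-4 or 10 iterations. Pseudotime
#' is each spot's normalized arc-length position (min 0, max 1).
#'
#' @param coords spots-by-dimensions embedding (e.g. from [classical_mds()]).
#' @param k number of k-means clusters for the backbone (default 4).
#' @param seed integer seed.
#' @return a `trajectory`: pseudotime (named), backbone curve, mds_coords,
#'   params.
#' @export
infer_trajectory <- function(coords, k = 4L, seed = 0L) {
  coords <- as.matrix(coords)
  k <- check_count(k, "k", min = 2L)
  if (k >= nrow(coords)) stopf("k (%d) must be below the number of spots (%d)", k, nrow(coords))
  set.seed(seed)
  km <- suppressWarnings(kmeans(coords, centers = k, nstart = 10, iter.max = 50))
  ord <- shortest_path_order(km$centers)
  curve <- resample_curve(km$centers[ord, , drop = FALSE], 100L)
  window <- max(3L, ceiling(0.1 * nrow(coords)))
  for (it in seq_len(10L)) {
    pr <- project_on_curve(coords, curve)
    o <- order(pr$s)
    sm <- apply(coords[o, , drop = FALSE], 2, running_mean, w = window)
    new_curve <- resample_curve(sm, 100L)
    shift <- mean(sqrt(rowSums((new_curve - curve)^2)))
    curve <- new_curve
    if (shift < 1e-4) break
  }
  curve <- extend_curve(curve, coords)
  pr <- project_on_curve(coords, curve)
  s <- pr$s
  pt <- (s - min(s)) / max(max(s) - min(s), .Machine$double.eps)
  structure(list(pseudotime = setNames(pt, rownames(coords)),
                 backbone = curve, mds_coords = coords,
                 params = list(k = k, seed = seed)),
            class = "trajectory")
}

# centered running mean with shrinking windows at the edges
running_mean <- function(x, w) {
  half <- floor(w / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Orient a trajectory so the classical program is early
#'
#' Flips pseudotime when the mean classical-arm score in the first pseudotime
#' quartile is below that in the last quartile's complement — i.e. classical
#' expression must decline along pseudotime. Idempotent.
#'
#' @param traj a `trajectory`.
#' @param expr spots-by-genes expression matrix covering the trajectory spots.
#' @param signature list with classical/basal arms.
#' @return the (possibly flipped) `trajectory`, with `orientation_anchor` set.
#' @export
orient_trajectory <- function(traj, expr, signature) {
  stopifnot(inherits(traj, "trajectory"))
  cls <- signature$classical_genes %||% signature$classical
  cls_in <- intersect(cls, colnames(expr))
  if (!length(cls_in)) stopf("classical signature genes not detected")
  z <- autoscale(expr[names(traj$pseudotime), cls_in, drop = FALSE])
  score <- rowMeans(z)
  pt <- traj$pseudotime
  early <- mean(score[pt <= quantile(pt, 0.25)])
  late <- mean(score[pt >= quantile(pt, 0.75)])
  if (early < late) {
    traj$pseudotime <- 1 - traj$pseudotime
    traj$backbone <- traj$backbone[rev(seq_len(nrow(traj$backbone))), , drop = FALSE]
  }
  traj$orientation_anchor <- "classical"
  traj
}

#' LOESS-style marker kinetics along pseudotime
#'
#' Degree-0 local regression: at each grid point the span-fraction nearest
#' observations get tricube weights w = (1 - (d/dmax)^3)^3 and their weighted
#' mean is reported.
#'
#' @param pseudotime numeric vector in \[0,1\].
#' @param values expression values aligned with `pseudotime` (>= 5 points).
#' @param span fraction of points per window (default 0.75).
#' @param grid number of evaluation points on \[0,1\] (default 100).
#' @return a `kinetic_curve` data.frame: grid, value.
#' @export
loess_kinetics <- function(pseudotime, values, span = 0.75, grid = 100L) {
  n <- length(pseudotime)
  if (n < 5L) stopf("need at least 5 points")
  if (length(values) != n) stopf("values must align with pseudotime")
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  if (span < 2 / n) stopf("span smaller than 2/n")
  g <- seq(0, 1, length.out = check_count(grid, "grid", min = 2L))
  m <- max(2L, ceiling(span * n))
  out <- vapply(g, function(x0) {
    d <- abs(pseudotime - x0)
    idx <- order(d)[seq_len(m)]
    dmax <- max(d[idx])
    if (dmax == 0) return(mean(values[idx]))
    w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
    if (sum(w) == 0) w <- rep(1, length(idx))
    sum(w * values[idx]) / sum(w)
  }, numeric(1))
  structure(data.frame(grid = g, value = out),
            class = c("kinetic_curve", "data.frame"),
            span = span)
}
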