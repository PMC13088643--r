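# Independent oracles and small fixtures used across the suite.
# Each oracle is a deliberately naive re-derivation, kept free of the
# package's own code paths.

# adjusted Rand index from the contingency-table closed form
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  si <- sum(choose(tab, 2))
  e <- sr * sc / choose(n, 2)
  (si - e) / ((sr + sc) / 2 - e)
}

# brute-force rank product: average ranks ascending in score, absent -> 1
rank_product_oracle <- function(lists) {
  universe <- sort(unique(unlist(lapply(lists, names))))
  prod <- setNames(rep(1, length(universe)), universe)
  for (sc in lists) {
    r <- setNames(rep(1, length(universe)), universe)
    r[names(sc)] <- rank(sc, ties.method = "average")
    prod <- prod * r
  }
  universe[order(-prod, universe)]
}

# elementwise Jaccard via raw set operations
jaccard_oracle <- function(sets) {
  n <- length(sets)
  J <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a <- unique(sets[[i]]); b <- unique(sets[[j]])
    u <- length(unique(c(a, b)))
    J[i, j] <- if (u == 0) 0 else sum(a %in% b) / u
  }
  J
}

# exclusive UpSet subset counts by scanning genes one at a time
exclusive_oracle <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  key <- vapply(universe, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), character(1))
  table(key)
}

# Newman modularity of a labeled partition at resolution gamma
modularity_oracle <- function(adj, membership, gamma = 1) {
  m2 <- sum(adj)                       # 2m for an undirected adjacency matrix
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - gamma * deg[i] * deg[j] / m2
  q / m2
}

# exhaustive best-partition modularity for small graphs (set partitions via
# restricted growth strings)
best_modularity_oracle <- function(adj, gamma = 1) {
  n <- nrow(adj)
  best <- -Inf
  part <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) {
      q <- modularity_oracle(adj, part, gamma)
      if (q > best) best <<- q
      return(invisible())
    }
    for (g in seq_len(kmax + 1)) {
      part[i] <<- g
      recurse(i + 1, max(kmax, g))
    }
  }
  recurse(1L, 0L)
  best
}

# Kruskal-Wallis H with tie correction, from the definition
kw_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(groups)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair, from the published formula
dunn_oracle <- function(values, groups, g1, g2) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- table(groups)
  ties <- table(values)
  Tc <- sum(ties^3 - ties) / (12 * (N - 1))
  (rbar[[g1]] - rbar[[g2]]) /
    sqrt((N * (N + 1) / 12 - Tc) * (1 / ni[[g1]] + 1 / ni[[g2]]))
}

# literal two-stage step-up procedure: stage-1 BH at q/(1+q), estimate m0,
# stage-2 BH at (q/(1+q)) * m/m0; returns the rejection set
bky_oracle <- function(p, q = 0.05) {
  m <- length(p)
  bh_reject <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    k <- which(p[o] <= thr)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh_reject(p, q1))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(p, q1 * m / (m - r1))
}

# shortest Hamiltonian path over k=4 centroids by listing all 12 undirected
# orderings explicitly
path_oracle_k4 <- function(centers) {
  d <- as.matrix(dist(centers))
  perms <- list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,4,1,3),
                c(3,1,2,4), c(3,2,1,4))
  lens <- vapply(perms, function(o) d[o[1],o[2]] + d[o[2],o[3]] + d[o[3],o[4]],
                 numeric(1))
  perms[[which.min(lens)]]
}

# exact Wilcoxon rank-sum p by enumerating all group assignments (no ties)
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# weighted (n-at-risk) log-rank statistic for two groups, from the definition
gbw_oracle <- function(time, event, group) {
  lev <- sort(unique(group))
  ev_times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (tj in ev_times) {
    at <- time >= tj
    Nj <- sum(at); n1 <- sum(at & group == lev[1])
    dj <- sum(event == 1 & time == tj)
    d1 <- sum(event == 1 & time == tj & group == lev[1])
    U <- U + Nj * (d1 - dj * n1 / Nj)
    if (Nj > 1)
      V <- V + Nj^2 * dj * (Nj - dj) / (Nj - 1) * (n1 / Nj) * (1 - n1 / Nj)
  }
  list(stat = U^2 / V, p = pchisq(U^2 / V, 1, lower.tail = FALSE))
}

# small default cohort shared by recovery tests (generated once per run)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config(seed = 0L))
    cache
  }
})
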