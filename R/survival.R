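#' Kaplan-Meier product-limit survival curve
#'
#' @param time positive event/censoring times.
#' @param event 1 = death, 0 = censored.
#' @return data.frame: time, n_risk, n_event, surv; S(0) = 1 and S is
#'   nonincreasing.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stopf("need at least one subject")
  if (any(time <= 0)) stopf("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time), n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Gehan-Breslow-Wilcoxon test between survival groups
#'
#' Weighted log-rank test with weight equal to the total number at risk at
#' each event time (Breslow convention), emphasizing early survival
#' differences; the statistic is the quadratic form of the weighted
#' observed-minus-expected vector, chi-square with g - 1 df.
#'
#' @param time positive times.
#' @param event 1 = death, 0 = censored.
#' @param group group label per subject (>= 2 groups, >= 1 event in total).
#' @return list: `statistic`, `df`, `p`.
#' @export
gehan_breslow_wilcoxon <- function(time, event, group) {
  group <- as.factor(group)
  g <- nlevels(group)
  if (g < 2L) stopf("need at least 2 groups")
  if (sum(event) < 1) stopf("no events observed")
  ev_times <- sort(unique(time[event == 1]))
  U <- numeric(g); V <- matrix(0, g, g)
  for (tj in ev_times) {
    at_risk <- time >= tj
    Nj <- sum(at_risk)
    if (Nj < 1) next
    nij <- tapply(at_risk, group, sum); nij[is.na(nij)] <- 0
    dj <- sum(event == 1 & time == tj)
    dij <- tapply(event == 1 & time == tj, group, sum); dij[is.na(dij)] <- 0
    w <- Nj
    U <- U + w * (dij - dj * nij / Nj)
    if (Nj > 1) {
      frac <- nij / Nj
      cov_j <- (diag(frac, g) - outer(frac, frac)) * dj * (Nj - dj) / (Nj - 1)
      V <- V + w^2 * cov_j
    }
  }
  idx <- seq_len(g - 1)
  Vi <- V[idx, idx, drop = FALSE]
  # generalized inverse guards degenerate configurations
  eg <- eigen(Vi, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  if (!any(pos)) return(list(statistic = 0, df = g - 1L, p = 1))
  Vinv <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / eg$values[pos], sum(pos)) %*% t(eg$vectors[, pos, drop = FALSE])
  stat <- drop(t(U[idx]) %*% Vinv %*% U[idx])
  list(statistic = stat, df = g - 1L, p = pchisq(stat, df = g - 1L, lower.tail = FALSE))
}
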