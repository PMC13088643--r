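toy_cells <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = sprintf("c%03d", 1:n),
             MUC1 = runif(n, 0, 200), CollagenI = runif(n, 0, 1000),
             GLUT1 = rlnorm(n, 4, 0.5),
             region_grade = sample(c("G1-2", "G2", "G2-3"), n, replace = TRUE),
             patient_id = "P01", stringsAsFactors = FALSE)
}

test_that("gating applies the default conjunction and matches brute force", {
  cells <- toy_cells(200)
  gated <- gate_cells(cells)
  manual <- cells[cells$MUC1 > 50 & cells$CollagenI < 500, ]
  expect_equal(gated$cell_id, manual$cell_id)
  expect_equal(sum(attr(gated, "grade_counts")), nrow(manual))

  # random rules match a brute-force row filter
  rules <- list(gate_rule("GLUT1", ">=", 50), gate_rule("MUC1", "<", 150))
  g2 <- gate_cells(cells, rules)
  expect_equal(g2$cell_id,
               cells$cell_id[cells$GLUT1 >= 50 & cells$MUC1 < 150])

  expect_warning(gate_cells(cells, list(gate_rule("MUC1", ">", 1e9))),
                 "no cells")
  expect_error(gate_cells(cells, list(gate_rule("NOPE", ">", 1))), "unknown")
  expect_error(gate_rule("MUC1", "!=", 1), "operator")
})

test_that("reference normalization divides by the reference-group median", {
  cells <- data.frame(cell_id = c("a", "b", "c"), M = c(2, 4, 6),
                      region_grade = c("G1-2", "G2", "G2-3"))
  v <- normalize_to_reference(cells, "M", "G1-2")
  expect_equal(v, c(1, 2, 3))
  # scale invariance
  cells2 <- cells; cells2$M <- cells2$M * 37
  expect_equal(normalize_to_reference(cells2, "M", "G1-2"), v)
  cells$M[1] <- 0
  expect_error(normalize_to_reference(cells, "M", "G1-2"), "zero")
})

test_that("Kruskal-Wallis H matches hand computation and simulates at level", {
  v <- c(2.3, 1.1, 5.5, 4.2, 3.3, 6.6, 7.7, 0.5, 8.8)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, kw_oracle(v, g), tolerance = 1e-10)
  expect_equal(kw$p, pchisq(kw$H, 2, lower.tail = FALSE), tolerance = 1e-12)

  # identical multisets across groups -> H = 0
  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0, tolerance = 1e-12)

  set.seed(2)
  rej <- mean(replicate(2000, kruskal_wallis(runif(45),
                                             rep(1:3, each = 15))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.01)
  expect_error(kruskal_wallis(1:4, c(1, 1, 1, 2)), "at least 2")
})

test_that("Dunn z equals the published formula including tie correction", {
  set.seed(3)
  v <- c(sample(1:10, 15, replace = TRUE))   # ties on purpose
  g <- rep(c("a", "b", "c"), each = 5)
  d <- dunn_posthoc(v, g)
  for (i in seq_len(nrow(d)))
    expect_equal(d$z[i], dunn_oracle(v, g, d$group1[i], d$group2[i]),
                 tolerance = 1e-12)
  expect_equal(d$p, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)

  # two identical groups give z = 0; antisymmetry under order swap
  v2 <- c(1, 2, 3, 1, 2, 3, 9, 9, 9)
  d2 <- dunn_posthoc(v2, rep(c("a", "b", "c"), each = 3))
  expect_equal(d2$z[d2$group1 == "a" & d2$group2 == "b"], 0, tolerance = 1e-12)
  zab <- dunn_oracle(v2, rep(c("a", "b", "c"), each = 3), "a", "c")
  zba <- dunn_oracle(v2, rep(c("a", "b", "c"), each = 3), "c", "a")
  expect_equal(zab, -zba)
})

test_that("two-stage FDR reproduces the literal published procedure", {
  expect_equal(fdr_two_stage(rep(1, 10))$rejected, rep(FALSE, 10))
  expect_equal(fdr_two_stage(rep(1e-10, 10))$rejected, rep(TRUE, 10))

  set.seed(4)
  for (rep in 1:20) {
    p <- c(runif(sample(5:15, 1)), runif(sample(2:5, 1), 0, 0.01))
    p <- sample(p)
    got <- fdr_two_stage(p, alpha = 0.05)
    expect_identical(got$rejected, bky_oracle(p, 0.05))
    # adjusted p consistent with the rejection set
    expect_identical(got$adjusted <= 0.05, got$rejected)
    expect_true(all(got$adjusted >= 0 & got$adjusted <= 1))
  }
  expect_equal(length(fdr_two_stage(numeric(0))$adjusted), 0L)
})

test_that("Spearman classifier applies the 0.3/0.5 thresholds on midranks", {
  res <- spearman_classify(1:10, (1:10)^3)
  expect_equal(res$rho, 1)
  expect_equal(res$class, "strong")

  set.seed(5)
  x <- sample(1:5, 30, replace = TRUE); y <- sample(1:5, 30, replace = TRUE)
  res2 <- spearman_classify(x, y)
  expect_equal(res2$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(res2$class,
               if (abs(res2$rho) > 0.5) "strong"
               else if (abs(res2$rho) > 0.3) "moderate" else "none")
  expect_error(spearman_classify(rep(1, 5), 1:5), "constant")
})

test_that("Kaplan-Meier estimator matches hand-computed product limits", {
  # all events at distinct times
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(1, 2/3, 1/3, 0))
  expect_equal(km$surv[1], 1)
  expect_true(all(diff(km$surv) <= 0))

  # censored 6-subject example: times 1,2+,3,4+,5,6 (+ = censored)
  km2 <- km_curve(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
  # hand product-limit: S(1)=5/6, S(3)=5/6*3/4, S(5)=5/6*3/4*1/2, S(6)=0
  expect_equal(km2$surv[km2$time == 1], 5/6)
  expect_equal(km2$surv[km2$time == 3], 5/6 * 3/4)
  expect_equal(km2$surv[km2$time == 5], 5/6 * 3/4 * 1/2)
  expect_equal(km2$surv[km2$time == 6], 0)

  # no events: survival stays 1
  expect_true(all(km_curve(c(2, 4), c(0, 0))$surv == 1))
})

test_that("Gehan-Breslow-Wilcoxon matches a from-scratch weighted log-rank", {
  time <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1)
  group <- rep(c("a", "b"), 5)
  got <- gehan_breslow_wilcoxon(time, event, group)
  want <- gbw_oracle(time, event, group)
  expect_equal(got$statistic, want$stat, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # label swap leaves the statistic unchanged
  swapped <- gehan_breslow_wilcoxon(time, event,
                                    ifelse(group == "a", "b", "a"))
  expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)
  expect_error(gehan_breslow_wilcoxon(time, rep(0, 10), group), "events")
})

test_that("planted grade effects survive the pooled two-stage FDR while
           unshifted markers stay at the nominal rate", {
  shift_hits <- 0; null_rej <- numeric(0)
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    cfg <- multiplex_config(
      n_cells = c(`G1-2` = 80L, `G2` = 80L, `G2-3` = 80L),
      grade_shifts = list(GLUT1 = c(`G1-2` = 1, `G2` = 1.5, `G2-3` = 2)),
      stroma_fraction = 0, seed = 100L + s)
    cells <- generate_multiplex_cells(cfg)$cells
    st <- grade_group_stats(cells, c("GLUT1", "LDHA", "MLPH"))
    top <- st$pairwise[st$pairwise$marker == "GLUT1" &
                         st$pairwise$group1 == "G1-2" &
                         st$pairwise$group2 == "G2-3", ]
    if (top$padj < 0.05) shift_hits <- shift_hits + 1
    expect_gt(st$log2fc_median["GLUT1", "G2-3"], 0)   # planted direction
    null_rej <- c(null_rej,
                  st$pairwise$rejected[st$pairwise$marker == "MLPH"])
  }
  expect_gte(shift_hits / n_rep, 0.9)
  expect_lte(mean(null_rej), 0.1)
})
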