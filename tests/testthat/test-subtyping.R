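test_that("TMM factors behave like the published scheme on controlled inputs", {
  set.seed(1)
  base <- rpois(200, 50) + 1
  counts <- rbind(s1 = base, s2 = base, s3 = base)
  tm <- tmm_normalize(counts)
  expect_equal(unname(tm$factors), rep(1, 3), tolerance = 1e-12)

  # doubled library, identical composition: identical normalized profiles
  counts2 <- rbind(s1 = base, s2 = 2L * base)
  tm2 <- tmm_normalize(counts2)
  expect_equal(tm2$cpm["s1", ], tm2$cpm["s2", ], tolerance = 1e-12)

  # geometric mean of factors is 1
  set.seed(2)
  counts3 <- matrix(rnbinom(5 * 300, mu = 40, size = 5), 5, 300,
                    dimnames = list(sprintf("s%d", 1:5), NULL))
  counts3[1, 1:30] <- counts3[1, 1:30] * 20L
  tm3 <- tmm_normalize(counts3)
  expect_equal(exp(mean(log(tm3$factors))), 1, tolerance = 1e-10)

  # step-by-step hand computation of the trimmed mean of M-values on a
  # 3-sample, 20-gene instance (reference = first sample, as used when the
  # reference's factor is computed against itself -> 1 before renorm)
  set.seed(3)
  small <- matrix(rnbinom(3 * 20, mu = 100, size = 10) + 1L, 3, 20,
                  dimnames = list(c("r", "a", "b"), NULL))
  tm4 <- tmm_normalize(small)
  hand_factor <- function(obs, ref) {
    No <- sum(obs); Nr <- sum(ref)
    keep <- obs > 0 & ref > 0
    M <- log2((obs / No) / (ref / Nr))[keep]
    A <- 0.5 * log2((obs / No) * (ref / Nr))[keep]
    w <- 1 / ((No - obs) / (No * obs) + (Nr - ref) / (Nr * ref))[keep]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * 0.30) + 1; hiL <- n + 1 - loL       # rank-based trims
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    k <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(w[k] * M[k]) / sum(w[k]))
  }
  # reference library: upper quartile of the count fractions closest to the
  # mean upper quartile; factors then renormalized to geometric mean 1
  uq <- apply(small, 1, quantile, probs = 0.75) / rowSums(small)
  ref <- rownames(small)[which.min(abs(uq - mean(uq)))]
  raw <- vapply(rownames(small), function(s)
    hand_factor(small[s, ], small[ref, ]), numeric(1))
  want <- raw / exp(mean(log(raw)))
  expect_equal(unname(tm4$factors[rownames(small)]), unname(want),
               tolerance = 1e-6)

  expect_error(tmm_normalize(rbind(a = c(0, 0), b = c(1, 2))), "zero library")
})

test_that("signature matrix averages by unit then auto-scales per gene", {
  expr <- rbind(c(1, 2, 3, 4), c(3, 4, 5, 6), c(10, 10, 0, 0))
  colnames(expr) <- c("c1", "c2", "b1", "b2")
  rownames(expr) <- c("u1a", "u1b", "u2")
  sig <- list(classical = c("c1", "c2"), basal = c("b1", "b2"))
  m <- signature_matrix(expr, sig, c("u1", "u1", "u2"))
  # oracle: mean within unit, then z-score per gene across units (n = 2)
  avg <- rbind(u1 = colMeans(expr[1:2, ]), u2 = expr[3, ])
  z <- apply(avg, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(unname(m), unname(t(z)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single unit: constant per gene -> zeros
  m1 <- signature_matrix(expr[1, , drop = FALSE], sig, "u1")
  expect_true(all(m1 == 0))

  expect_error(signature_matrix(expr[, 1:2], sig, c("u1", "u1", "u2")),
               "basal")
})

test_that("complete-linkage clustering merges by hand-computed heights", {
  m <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("f", c("a", "b", "c")))
  hc <- cluster_units(m)
  expect_equal(hc$height, c(1, 3))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_true(all(diff(hc$height) >= 0))

  # two well-separated blobs: the 2-cut recovers them
  set.seed(4)
  blob <- cbind(matrix(rnorm(20, 0, 0.1), 5, 4), matrix(rnorm(20, 10, 0.1), 5, 4))
  colnames(blob) <- sprintf("u%d", 1:8)
  cut <- cutree(cluster_units(blob), 2)
  expect_equal(length(unique(cut[1:4])), 1L)
  expect_equal(length(unique(cut[5:8])), 1L)
  expect_error(cluster_units(matrix(c(1, NaN), 1, 2)), "finite")
})

test_that("bootstrap support is high for planted structure, low for noise", {
  set.seed(5)
  planted <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
                   matrix(rnorm(40, 5, 0.2), 10, 4))
  planted <- cbind(planted, planted + rnorm(80, 0, 0.2))
  colnames(planted) <- sprintf("u%d", 1:8)
  planted[, 5:8] <- planted[, 5:8] + 8   # two well-separated unit groups
  sup <- bootstrap_support(planted, n_boot = 500L, seed = 1L)
  expect_true(all(sup$support > 0.95))

  noise <- matrix(rnorm(160), 20, 8, dimnames = list(NULL, sprintf("u%d", 1:8)))
  sup0 <- bootstrap_support(noise, n_boot = 500L, seed = 1L)
  expect_true(all(sup0$support < 0.95))
  expect_error(bootstrap_support(planted[1, , drop = FALSE], 500L), "2 rows")
})

test_that("subtype calls follow scores with a mixed margin", {
  scores <- data.frame(classical = c(2, -2, 0.1), basal = c(-2, 2, 0.0),
                       row.names = c("u1", "u2", "u3"))
  calls <- call_subtypes(NULL, scores, tau = 0.5)
  expect_equal(calls$label, c("classical", "basal", "mixed"))

  # equal scores are always mixed
  eq <- call_subtypes(NULL, data.frame(classical = 1, basal = 1,
                                       row.names = "u"), tau = 0.5)
  expect_equal(eq$label, "mixed")
})

test_that("subtype recovery on synthetic bulk cohorts is near perfect", {
  acc_pure <- acc_mixed <- numeric(5)
  for (s in 1:5) {
    bk <- generate_bulk_cohort(bulk_config(seed = s))
    expr <- log2(tmm_normalize(bk$cohort$counts)$cpm + 1)
    grouping <- rownames(bk$cohort$counts)
    sc <- signature_scores(expr, bk$truth$planted_signatures, grouping)
    dend <- cluster_units(signature_matrix(expr, bk$truth$planted_signatures,
                                           grouping))
    calls <- call_subtypes(dend, sc, tau = 0.5)
    truth <- bk$cohort$true_subtype[calls$unit]
    pure <- truth %in% c("classical", "basal")
    acc_pure[s] <- mean(calls$label[pure] == truth[pure])
    acc_mixed[s] <- mean(calls$label[!pure] == "mixed")
  }
  expect_gte(mean(acc_pure), 0.95)
  expect_gte(mean(acc_mixed), 0.8)
})

test_that("pseudobulk sums by group and conserves totals", {
  counts <- rbind(c(1, 2), c(3, 4), c(5, 6))
  rownames(counts) <- sprintf("s%d", 1:3)
  pb <- pseudobulk(counts, c("a", "a", "b"))
  expect_equal(unname(pb["a", ]), c(4, 6))
  expect_equal(sum(pb), sum(counts))
  ident <- pseudobulk(counts, rownames(counts))
  expect_equal(unname(ident[rownames(counts), ]), unname(counts))
})

test_that("DGEA recovers a planted two-fold change and is null-calibrated", {
  set.seed(6)
  n <- 12; ng <- 500
  counts <- t(replicate(n, rnbinom(ng, mu = 1000, size = 50)))
  counts[7:12, 1] <- rnbinom(6, mu = 2000, size = 50)
  rownames(counts) <- sprintf("pb%02d", 1:n)
  colnames(counts) <- sprintf("g%03d", 1:ng)
  dg <- dgea(counts, rownames(counts)[1:6], rownames(counts)[7:12])
  expect_gt(dg$log2fc[1], 0.7); expect_lt(dg$log2fc[1], 1.3)
  expect_lt(dg$padj[1], 0.05)

  # identical groups: logFC ~ 0
  same <- dgea(counts[, -1], rownames(counts)[c(1, 3, 5)],
               rownames(counts)[c(2, 4, 6)])
  expect_lt(mean(abs(same$log2fc)), 0.15)
  expect_equal(mean(same$log2fc), 0, tolerance = 0.05)

  # null p-values approximately uniform
  set.seed(7)
  mu <- exp(rnorm(2000, log(50), 0.3))
  null_counts <- t(replicate(12, rnbinom(2000, mu = mu, size = 10)))
  rownames(null_counts) <- sprintf("pb%02d", 1:12)
  colnames(null_counts) <- sprintf("g%04d", 1:2000)
  dg0 <- dgea(null_counts, rownames(null_counts)[1:6], rownames(null_counts)[7:12])
  expect_gt(suppressWarnings(ks.test(dg0$p, "punif"))$p.value, 0.01)

  expect_error(dgea(counts, rownames(counts)[1], rownames(counts)[2:4]),
               "2 replicates")
})

test_that("sigmoid fold-change scaling matches its closed form and bounds", {
  expect_equal(sigmoid_scale(0), 0)
  expect_equal(sigmoid_scale(0.2), -0.5 + 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(sigmoid_scale(0.2), 0.38079707797788, tolerance = 1e-10)
  a <- seq(-6, 6, by = 0.01)
  expect_equal(sigmoid_scale(-a), -sigmoid_scale(a), tolerance = 1e-12)
  expect_true(all(abs(sigmoid_scale(seq(-50, 50, by = 0.01))) <= 0.5))
  # strictly increasing wherever doubles can resolve the increments
  expect_true(all(diff(sigmoid_scale(seq(-1.5, 1.5, by = 0.01))) > 0))
  expect_true(all(diff(sigmoid_scale(a)) >= 0))
  expect_error(sigmoid_scale(NA_real_), "finite")
})
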