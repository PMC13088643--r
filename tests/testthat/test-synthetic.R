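test_that("cohort generation is reproducible and validates its configuration", {
  cfg <- cohort_config(n_patients = 2L, spots_per_patient = 40L, n_genes = 300L,
                       seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$latent_t, b$truth$latent_t)

  expect_error(cohort_config(n_genes = 100L), "smaller than")
  expect_error(cohort_config(dirichlet_purity = 0), "positive")
  expect_error(cohort_config(continuum_fraction = 1.5), "\\[0, 1\\]")
})

test_that("spot mixtures sum to one and become one-hot at infinite purity", {
  sim <- generate_cohort(cohort_config(n_patients = 2L, spots_per_patient = 50L,
                                       n_genes = 300L, seed = 1L))
  expect_true(all(abs(rowSums(sim$truth$spot_mixture) - 1) < 1e-12))

  pure <- generate_cohort(cohort_config(n_patients = 2L, spots_per_patient = 50L,
                                        n_genes = 300L, dirichlet_purity = 1e9,
                                        seed = 1L))
  expect_true(all(apply(pure$truth$spot_mixture, 1, max) > 1 - 1e-3))
})

test_that("latent t covers cancer spots uniformly and only cancer spots", {
  sim <- default_sim()
  tt <- sim$truth$latent_t
  dom <- sim$truth$spot_dominant_type
  expect_true(all(is.na(tt[dom != "cancer"])))
  expect_true(all(!is.na(tt[dom == "cancer"])))
  ks <- suppressWarnings(ks.test(tt[dom == "cancer"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted markers are highest in their own type in the program matrix", {
  sim <- default_sim()
  prog <- sim$truth$program_means
  for (ty in rownames(prog)) {
    for (g in sim$truth$planted_markers[[ty]]) {
      own <- prog[ty, g]
      expect_true(all(own > prog[rownames(prog) != ty, g]))
    }
  }
  # marker lists are disjoint across types
  all_m <- unlist(sim$truth$planted_markers)
  expect_equal(anyDuplicated(all_m), 0L)
})

test_that("mean detected genes per spot matches a direct Monte-Carlo NB oracle", {
  cfg <- cohort_config(n_patients = 2L, spots_per_patient = 100L,
                       n_genes = 400L, seed = 3L)
  sim <- generate_cohort(cfg)
  observed <- mean(rowSums(sim$dataset$counts > 0))

  # oracle: simulate spots straight from the NB model with a flat program
  # (background genes dominate), using the same library/abundance model
  set.seed(99)
  n_mc <- 2000
  det <- numeric(n_mc)
  gene_w <- exp(rnorm(cfg$n_genes, 0, 1))
  for (i in seq_len(n_mc)) {
    lib <- rlnorm(1, log(cfg$library_size_mean) - 0.35^2 / 2, 0.35)
    mu <- lib * gene_w / sum(gene_w)
    det[i] <- sum(rnbinom(cfg$n_genes, mu = mu, size = 1 / cfg$nb_dispersion) > 0)
  }
  expect_lt(abs(observed - mean(det)) / mean(det), 0.15)
})

test_that("multiplex generator plants monotone grade shifts and is seeded", {
  cfg <- multiplex_config(seed = 5L)
  a <- generate_multiplex_cells(cfg)
  b <- generate_multiplex_cells(cfg)
  expect_identical(a$cells, b$cells)

  # planted 2x median shift recovered on the normalized scale (log-normal
  # median is exp(meanlog), so the ratio of medians is the planted shift)
  big <- multiplex_config(
    n_cells = c(`G1-2` = 2000L, `G2` = 2000L, `G2-3` = 2000L),
    grade_shifts = list(GLUT1 = c(`G1-2` = 1, `G2` = 1.5, `G2-3` = 2)),
    stroma_fraction = 0, seed = 8L)
  cells <- generate_multiplex_cells(big)$cells
  v <- normalize_to_reference(cells, "GLUT1", "G1-2")
  med_top <- median(v[cells$region_grade == "G2-3"])
  expect_lt(abs(med_top - 2), 0.15)

  # no planted shift: Kruskal-Wallis rejects at roughly the nominal rate
  null_cfg <- function(s) multiplex_config(
    n_cells = c(`G1-2` = 60L, `G2` = 60L, `G2-3` = 60L),
    grade_shifts = list(), stroma_fraction = 0, seed = s)
  rej <- vapply(1:200, function(s) {
    cells <- generate_multiplex_cells(null_cfg(s))$cells
    kruskal_wallis(cells$MLPH, cells$region_grade)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)

  expect_error(multiplex_config(sdlog = -1), "positive")
  expect_error(multiplex_config(markers = "MUC1", base_median = c(MUC1 = -1)),
               "positive")
})

test_that("bulk cohort generator orders survival by hazard and is seeded", {
  cfg <- bulk_config(seed = 2L)
  a <- generate_bulk_cohort(cfg)
  b <- generate_bulk_cohort(cfg)
  expect_identical(a$cohort$counts, b$cohort$counts)
  expect_identical(a$cohort$survival_time, b$cohort$survival_time)
  expect_true(all(a$cohort$survival_time > 0))
  expect_true(all(a$cohort$event %in% c(0L, 1L)))

  # hazard ratio 3: classical survival stochastically dominates basal
  big <- generate_bulk_cohort(bulk_config(
    n_per_subtype = c(classical = 100L, basal = 100L),
    hazard = c(classical = 0.02, basal = 0.06), seed = 4L))
  km_c <- km_curve(big$cohort$survival_time[big$cohort$true_subtype == "classical"],
                   big$cohort$event[big$cohort$true_subtype == "classical"])
  km_b <- km_curve(big$cohort$survival_time[big$cohort$true_subtype == "basal"],
                   big$cohort$event[big$cohort$true_subtype == "basal"])
  med <- function(km) km$time[which(km$surv <= 0.5)[1]]
  expect_lt(med(km_b), med(km_c))

  expect_error(bulk_config(hazard = c(classical = -1, basal = 1, mixed = 1)),
               "positive")

  # equal hazards: the GBW test rejects at roughly the nominal rate
  rej <- vapply(1:200, function(s) {
    bk <- generate_bulk_cohort(bulk_config(
      n_per_subtype = c(classical = 30L, basal = 30L),
      hazard = c(classical = 0.04, basal = 0.04), seed = 1000L + s))
    gr <- bk$cohort$true_subtype
    gehan_breslow_wilcoxon(bk$cohort$survival_time, bk$cohort$event, gr)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("fixtures round-trip losslessly with a checksum manifest", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(cohort_config(n_patients = 2L, spots_per_patient = 30L,
                                       n_genes = 300L, seed = 6L))
  manifest <- write_fixture(sim$dataset, dir, truth = sim$truth)
  back <- read_fixture(dir)
  expect_identical(unname(back$counts), unname(sim$dataset$counts))
  expect_identical(rownames(back$counts), rownames(sim$dataset$counts))
  expect_identical(back$genes, sim$dataset$genes)
  expect_equal(back$coords$x, sim$dataset$coords$x)
  expect_identical(unname(back$patient_id), unname(sim$dataset$patient_id))

  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(nchar(manifest$md5) == 32))
  expect_true("signatures.gmt" %in% manifest$file)
  sig <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_identical(sig$classical, sim$truth$planted_signatures$classical)

  # truncated file is an error, not a silent partial load
  file.remove(file.path(dir, "genes.tsv"))
  expect_error(read_fixture(dir), "missing")

  # an empty dataset writes valid empty files rather than crashing
  dir2 <- withr::local_tempdir()
  empty <- subset_spots(sim$dataset, character(0))
  write_fixture(empty, dir2)
  back2 <- read_fixture(dir2)
  expect_equal(nrow(back2$counts), 0L)
  expect_equal(ncol(back2$counts), ncol(sim$dataset$counts))
})
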