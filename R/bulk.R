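#' Configure the synthetic bulk RNA-seq + survival cohort generator
#'
#' Emulates a bulk tumor cohort with negative-binomial counts mixing
#' classical and basal expression programs, and overall survival drawn from
#' subtype-specific exponential hazards with independent censoring — the
#' substrate for TMM normalization, signature subtyping, and Kaplan-Meier
#' comparison.
#'
#' @param n_per_subtype named counts of samples per true subtype
#'   (`classical`, `basal`, optionally `mixed`).
#' @param n_genes total genes (signature genes are carved from the front).
#' @param signature_size genes per subtype signature arm.
#' @param program_effect fold elevation of a subtype's signature genes in
#'   samples of that subtype; mixed samples sit halfway on both arms.
#' @param nb_dispersion negative-binomial dispersion phi.
#' @param library_size_mean mean library size.
#' @param hazard named per-month exponential death hazards per subtype.
#' @param censor_rate hazard of the independent exponential censoring process.
#' @param admin_censor administrative censoring horizon (months).
#' @param seed integer seed.
#' @return a `bulk_config` list.
#' @export
bulk_config <- function(n_per_subtype = c(classical = 40L, basal = 40L, mixed = 10L),
                        n_genes = 500L,
                        signature_size = 25L,
                        program_effect = 4,
                        nb_dispersion = 0.1,
                        library_size_mean = 2e5,
                        hazard = c(classical = 0.02, basal = 0.06, mixed = 0.035),
                        censor_rate = 0.01,
                        admin_censor = 120,
                        seed = 0L) {
  if (any(hazard <= 0)) stopf("hazard rates must be positive")
  subtypes <- names(n_per_subtype)
  if (is.null(subtypes) || !all(subtypes %in% names(hazard)))
    stopf("every subtype in `n_per_subtype` needs a hazard rate")
  if (2L * signature_size > n_genes)
    stopf("n_genes smaller than the two signature arms")
  structure(list(n_per_subtype = vapply(n_per_subtype, check_count, integer(1),
                                        name = "n_per_subtype"),
                 n_genes = check_count(n_genes, "n_genes"),
                 signature_size = check_count(signature_size, "signature_size"),
                 program_effect = check_positive(program_effect, "program_effect"),
                 nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
                 library_size_mean = check_positive(library_size_mean, "library_size_mean"),
                 hazard = hazard,
                 censor_rate = check_positive(censor_rate, "censor_rate"),
                 admin_censor = check_positive(admin_censor, "admin_censor"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "bulk_config")
}

#' Generate a synthetic bulk cohort with subtype-dependent survival
#'
#' @param config a [bulk_config()].
#' @return list with `cohort` (a `bulk_cohort`: counts sample x gene,
#'   survival_time, event, true_subtype) and `truth` (planted signatures and
#'   hazards).
#' @export
generate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_config"))
  set.seed(derive_seed(config$seed, 97L))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  sig <- list(classical = genes[seq_len(config$signature_size)],
              basal = genes[config$signature_size + seq_len(config$signature_size)])
  gene_w <- exp(rnorm(config$n_genes, 0, 1))
  subtype <- rep(names(config$n_per_subtype), times = config$n_per_subtype)
  n <- length(subtype)
  sample_id <- sprintf("S%03d", seq_len(n))
  counts <- matrix(0L, nrow = n, ncol = config$n_genes,
                   dimnames = list(sample_id, genes))
  pe <- config$program_effect
  for (i in seq_len(n)) {
    eff <- rep(1, config$n_genes)
    w_basal <- switch(subtype[i], classical = 0, basal = 1, mixed = 0.5)
    eff[match(sig$classical, genes)] <- 1 + (pe - 1) * (1 - w_basal)
    eff[match(sig$basal, genes)] <- 1 + (pe - 1) * w_basal
    rel <- gene_w * eff
    lib <- rlnorm(1, log(config$library_size_mean) - 0.3^2 / 2, 0.3)
    mu <- lib * rel / sum(rel)
    counts[i, ] <- rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
  }
  storage.mode(counts) <- "integer"
  death <- rexp(n, rate = config$hazard[subtype])
  cens <- pmin(rexp(n, rate = config$censor_rate), config$admin_censor)
  time <- pmin(death, cens)
  event <- as.integer(death <= cens)
  time <- pmax(time, 1e-6)
  cohort <- structure(list(counts = counts,
                           survival_time = setNames(time, sample_id),
                           event = setNames(event, sample_id),
                           true_subtype = setNames(subtype, sample_id),
                           genes = genes),
                      class = "bulk_cohort")
  truth <- list(planted_signatures = sig,
                survival_hazard_by_subtype = config$hazard,
                bulk_subtype = setNames(subtype, sample_id))
  list(cohort = cohort, truth = truth)
}
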