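#' Configure a synthetic spatial cohort
#'
#' Defines the study conditions for the seeded spot-cohort generator: how many
#' patients and spots, which cell-type expression programs exist, how many
#' congruent (pan-patient) marker genes each program plants, how pure spots are
#' (Dirichlet concentration around the locally dominant type), the
#' negative-binomial dispersion of the counts, and the size of the latent
#' classical-to-basal continuum carried by cancer spots.
#'
#' Defaults emulate, at desk scale, a multi-patient PDAC cohort in which every
#' capture spot mixes several overlapping cells, tissue regions are spatially
#' coherent, and a classical-to-basal transcriptional continuum runs through
#' the cancer compartment.
#'
#' @param n_patients number of patients.
#' @param spots_per_patient spots per patient section.
#' @param n_genes total genes; must exceed the genes consumed by programs.
#' @param cell_types named integer vector: program-gene count per cell type.
#'   Must contain a `cancer` entry large enough to host the two subtype
#'   signatures plus the congruent markers.
#' @param n_congruent_markers_per_type congruent markers planted per type.
#' @param dirichlet_purity concentration on the dominant type; larger is purer.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi mu^2), shared across genes.
#' @param library_size_mean mean total counts per spot (library sizes are
#'   log-normal around this mean).
#' @param continuum_fraction fraction of cancer-dominant spots spread uniformly
#'   along the latent t in \[0,1\]; the remainder sit at the poles.
#' @param signature_size genes per subtype signature arm (classical and basal).
#' @param batch_sd per-patient log-scale batch effect SD.
#' @param program_effect fold elevation of program genes in their own type.
#' @param marker_effect fold elevation of planted congruent markers.
#' @param subtype_effect dynamic range of the subtype signature arms along the
#'   continuum: a classical gene runs from `subtype_effect`-fold at t = 0 down
#'   to baseline at t = 1; basal genes mirror-image.
#' @param background_alpha Dirichlet background concentration added to every
#'   component so mixtures are never degenerate.
#' @param sigmoid_mixing if TRUE the classical/basal mixing follows a sigmoid
#'   in t rather than the default linear ramp.
#' @param seed integer seed; all randomness derives from it.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 6L,
                          spots_per_patient = 400L,
                          n_genes = 1200L,
                          cell_types = c(cancer = 110L, fibroblast = 40L,
                                         acinar_ductal = 40L, immune = 40L,
                                         endocrine = 40L),
                          n_congruent_markers_per_type = 10L,
                          dirichlet_purity = 10,
                          nb_dispersion = 0.1,
                          library_size_mean = 20000,
                          continuum_fraction = 1,
                          signature_size = 50L,
                          batch_sd = 0.1,
                          program_effect = 4,
                          marker_effect = 8,
                          subtype_effect = 8,
                          background_alpha = 0.3,
                          sigmoid_mixing = FALSE,
                          seed = 0L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    spots_per_patient = check_count(spots_per_patient, "spots_per_patient"),
    n_genes = check_count(n_genes, "n_genes"),
    cell_types = cell_types,
    n_congruent_markers_per_type =
      check_count(n_congruent_markers_per_type, "n_congruent_markers_per_type"),
    dirichlet_purity = check_positive(dirichlet_purity, "dirichlet_purity"),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    library_size_mean = check_positive(library_size_mean, "library_size_mean"),
    continuum_fraction = check_fraction(continuum_fraction, "continuum_fraction"),
    signature_size = check_count(signature_size, "signature_size"),
    batch_sd = check_positive(batch_sd, "batch_sd"),
    program_effect = check_positive(program_effect, "program_effect"),
    marker_effect = check_positive(marker_effect, "marker_effect"),
    subtype_effect = check_positive(subtype_effect, "subtype_effect"),
    background_alpha = check_positive(background_alpha, "background_alpha"),
    sigmoid_mixing = isTRUE(sigmoid_mixing),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(names(cell_types)) || any(!nzchar(names(cell_types))))
    stopf("`cell_types` must be a named vector of program-gene counts")
  if (!"cancer" %in% names(cell_types))
    stopf("`cell_types` must include a 'cancer' program")
  cell_types <- vapply(cell_types, check_count, integer(1), name = "cell_types")
  if (any(cell_types < cfg$n_congruent_markers_per_type))
    stopf("every program must be at least as large as the congruent marker count")
  need_cancer <- cfg$n_congruent_markers_per_type + 2L * cfg$signature_size
  if (cell_types[["cancer"]] < need_cancer)
    stopf("cancer program (%d genes) must host %d congruent markers + 2 x %d signature genes",
          cell_types[["cancer"]], cfg$n_congruent_markers_per_type, cfg$signature_size)
  if (sum(cell_types) > cfg$n_genes)
    stopf("n_genes (%d) smaller than total planted program genes (%d)",
          cfg$n_genes, sum(cell_types))
  cfg$cell_types <- cell_types
  class(cfg) <- "cohort_config"
  cfg
}

# classical/basal mixing weight in t: linear ramp by default, sigmoid optional
mixing_weight <- function(t, sigmoid = FALSE) {
  if (!sigmoid) return(t)
  raw <- 1 / (1 + exp(-8 * (t - 0.5)))
  lo <- 1 / (1 + exp(4)); hi <- 1 / (1 + exp(-4))
  (raw - lo) / (hi - lo)
}

# Build the static type-by-gene program multiplier matrix plus gene bookkeeping.
# Cancer subtype-signature genes are recorded at their t = 0.5 mid-continuum
# level here; generate_cohort() applies the t-dependence per spot.
build_programs <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  types <- names(cfg$cell_types)
  prog <- matrix(1, nrow = length(types), ncol = cfg$n_genes,
                 dimnames = list(types, genes))
  planted <- list(); sigs <- list(classical = character(), basal = character())
  pos <- 0L
  for (ty in types) {
    n_prog <- cfg$cell_types[[ty]]
    idx <- pos + seq_len(n_prog); pos <- pos + n_prog
    nm <- cfg$n_congruent_markers_per_type
    marker_idx <- idx[seq_len(nm)]
    prog[ty, marker_idx] <- cfg$marker_effect
    prog[ty, idx[-seq_len(nm)]] <- cfg$program_effect
    planted[[ty]] <- genes[marker_idx]
    if (ty == "cancer") {
      rest <- idx[-seq_len(nm)]
      sigs$classical <- genes[rest[seq_len(cfg$signature_size)]]
      sigs$basal <- genes[rest[cfg$signature_size + seq_len(cfg$signature_size)]]
      # signatures recorded at half strength (t = 0.5) in the static matrix
      prog["cancer", c(sigs$classical, sigs$basal)] <-
        1 + (cfg$subtype_effect - 1) * 0.5
    }
  }
  list(genes = genes, program = prog, planted_markers = planted,
       planted_signatures = sigs)
}

#' Generate a synthetic multi-patient spot cohort with planted ground truth
#'
#' Spots live on a unit square per patient; the locally dominant cell type is
#' assigned by patient-specific Voronoi patches (cancer receives three seed
#' points, every other type one) so neighboring spots share a type and patch
#' boundaries yield genuinely mixed spots. Per-spot compositions are Dirichlet
#' draws concentrated on the dominant type; expected expression is the
#' mixture-weighted sum of type programs, modulated for cancer spots by a
#' latent classical-to-basal coordinate t (classical signature genes ramp down
#' linearly in t, basal genes ramp up); counts are negative binomial on
#' log-normal library sizes with a per-patient log-normal batch effect.
#'
#' @param config a [cohort_config()].
#' @return list with `dataset` (a `spot_dataset`: counts spots x genes,
#'   coords, patient ids, qc flags) and `truth` (a `ground_truth`: dominant
#'   types, mixture matrix, latent t, planted markers and signatures, and the
#'   static type-by-gene program matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pr <- build_programs(config)
  types <- names(config$cell_types)
  K <- length(types)

  set.seed(derive_seed(config$seed, 0L))
  gene_w <- exp(rnorm(config$n_genes, mean = 0, sd = 1))  # baseline abundance
  # canonical markers and subtype signature genes are well-expressed by
  # design: floor their baseline abundance at the cohort median
  anchored <- match(c(unlist(pr$planted_markers),
                      unlist(pr$planted_signatures)), pr$genes)
  gene_w[anchored] <- pmax(gene_w[anchored], 1)

  n_total <- config$n_patients * config$spots_per_patient
  counts <- matrix(0L, nrow = n_total, ncol = config$n_genes)
  coords <- matrix(0, nrow = n_total, ncol = 2)
  mixtures <- matrix(0, nrow = n_total, ncol = K, dimnames = list(NULL, types))
  dominant <- character(n_total)
  latent_t <- rep(NA_real_, n_total)
  patient_id <- character(n_total)
  spot_id <- character(n_total)

  cls <- pr$planted_signatures$classical
  bas <- pr$planted_signatures$basal
  cls_i <- match(cls, pr$genes); bas_i <- match(bas, pr$genes)

  n_seeds <- ifelse(types == "cancer", 3L, 1L)
  row0 <- 0L
  for (p in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, p))
    pid <- sprintf("P%02d", p)
    ns <- config$spots_per_patient
    xy <- cbind(runif(ns), runif(ns))
    seed_xy <- cbind(runif(sum(n_seeds)), runif(sum(n_seeds)))
    seed_type <- rep(types, times = n_seeds)
    d2 <- outer(xy[, 1], seed_xy[, 1], "-")^2 + outer(xy[, 2], seed_xy[, 2], "-")^2
    dom <- seed_type[max.col(-d2, ties.method = "first")]

    batch <- exp(rnorm(config$n_genes, 0, config$batch_sd))
    lib <- rlnorm(ns, meanlog = log(config$library_size_mean) - 0.35^2 / 2,
                  sdlog = 0.35)

    for (s in seq_len(ns)) {
      i <- row0 + s
      alpha <- rep(config$background_alpha, K)
      alpha[match(dom[s], types)] <- alpha[match(dom[s], types)] + config$dirichlet_purity
      mix <- rdirichlet_one(alpha)
      tval <- NA_real_
      if (dom[s] == "cancer") {
        if (runif(1) < config$continuum_fraction) tval <- runif(1)
        else tval <- as.numeric(runif(1) < 0.5)
      }
      # per-spot expected relative expression
      eff <- drop(mix %*% pr$program)
      if (!is.na(tval)) {
        w <- mixing_weight(tval, config$sigmoid_mixing)
        mc <- mix[match("cancer", types)]
        base <- config$subtype_effect
        # replace the static mid-continuum cancer contribution by the t-level
        eff[cls_i] <- eff[cls_i] +
          mc * ((1 + (base - 1) * (1 - w)) - (1 + (base - 1) * 0.5))
        eff[bas_i] <- eff[bas_i] +
          mc * ((1 + (base - 1) * w) - (1 + (base - 1) * 0.5))
      }
      rel <- gene_w * batch * eff
      mu <- lib[s] * rel / sum(rel)
      counts[i, ] <- rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
      coords[i, ] <- xy[s, ]
      mixtures[i, ] <- mix
      dominant[i] <- dom[s]
      latent_t[i] <- tval
      patient_id[i] <- pid
      spot_id[i] <- sprintf("%s_s%04d", pid, s)
    }
    row0 <- row0 + ns
  }

  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(spot_id, pr$genes)
  rownames(mixtures) <- spot_id

  dataset <- structure(list(
    counts = counts,
    coords = data.frame(spot_id = spot_id, x = coords[, 1], y = coords[, 2],
                        stringsAsFactors = FALSE),
    patient_id = setNames(patient_id, spot_id),
    genes = pr$genes,
    qc_flags = data.frame(spot_id = spot_id, pass = TRUE, reason = "",
                          stringsAsFactors = FALSE)
  ), class = "spot_dataset")

  truth <- structure(list(
    spot_dominant_type = setNames(dominant, spot_id),
    spot_mixture = mixtures,
    latent_t = setNames(latent_t, spot_id),
    planted_markers = pr$planted_markers,
    planted_signatures = pr$planted_signatures,
    program_means = pr$program
  ), class = "ground_truth")

  list(dataset = dataset, truth = truth)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes, %d patients\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$patient_id))))
  invisible(x)
}

#' Subset a spot dataset by spot identifiers
#' @param dataset a `spot_dataset`.
#' @param spot_ids spot identifiers to keep, in order.
#' @return the subsetted `spot_dataset`.
#' @export
subset_spots <- function(dataset, spot_ids) {
  stopifnot(inherits(dataset, "spot_dataset"))
  miss <- setdiff(spot_ids, rownames(dataset$counts))
  if (length(miss)) stopf("unknown spot ids: %s", paste(head(miss, 3), collapse = ", "))
  structure(list(
    counts = dataset$counts[spot_ids, , drop = FALSE],
    coords = dataset$coords[match(spot_ids, dataset$coords$spot_id), , drop = FALSE],
    patient_id = dataset$patient_id[spot_ids],
    genes = dataset$genes,
    qc_flags = dataset$qc_flags[match(spot_ids, dataset$qc_flags$spot_id), , drop = FALSE]
  ), class = "spot_dataset")
}
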