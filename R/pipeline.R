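#' Default pipeline configuration
#'
#' Collects every stage parameter at its documented default: QC min genes
#' 200; 30 PCs; kNN 10; Louvain resolution 0.8; 2000 HVGs; top-50 marker
#' lists (100 for similarity analyses); trajectory k 4 with 3 MDS
#' components and LOESS span 0.75; GSEA min set 5; 1000 permutations; alpha
#' 0.05; interaction mean cutoff 0.5; Spearman thresholds 0.3/0.5.
#'
#' @param seed global seed; stage seeds derive from it.
#' @param cohort optional [cohort_config()] override.
#' @param multiplex optional [multiplex_config()] override.
#' @param bulk optional [bulk_config()] override.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0L, cohort = NULL, multiplex = NULL,
                            bulk = NULL) {
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    seed = seed,
    min_genes = 200L, n_pcs = 30L, knn = 10L, resolution = 0.8,
    hvg = 2000L, top_n = 50L, top_n_similarity = 100L,
    k = 4L, ncomp = 3L, span = 0.75,
    n_perm = 1000L, min_set = 5L, n_boot = 1000L,
    alpha = 0.05, mean_cutoff = 0.5, rho_moderate = 0.3, rho_strong = 0.5,
    tau = 0.5,
    cohort = cohort %||% cohort_config(seed = seed),
    multiplex = multiplex %||% multiplex_config(seed = seed),
    bulk = bulk %||% bulk_config(seed = seed)
  ), class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline and write its artifacts
#'
#' Executes simulate, QC, per-patient clustering and annotation, marker
#' meta-analysis (intersection, Jaccard PCA, rank product), subtype calling,
#' classical-to-basal trajectory inference, DGEA + preranked GSEA,
#' ligand-receptor testing, multiplex niche statistics, and bulk survival
#' comparison, logging each stage and writing TSV/JSON artifacts plus a
#' checksum manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param quiet suppress progress messages.
#' @return list of in-memory stage results; artifacts and `manifest.json`
#'   under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) stopf("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, ...) if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  log("simulate", "seed %d", config$seed)
  sim <- run_stage("simulate", function() generate_cohort(config$cohort))
  ds <- sim$dataset; truth <- sim$truth

  log("qc", "min_genes %d", config$min_genes)
  ds <- run_stage("qc", function() filter_spots(ds, min_genes = config$min_genes))
  jsonlite::write_json(list(
    n_input = nrow(sim$dataset$counts), n_pass = nrow(ds$counts),
    min_genes = config$min_genes), file.path(out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA)

  patients <- unique(ds$patient_id)
  panels <- truth$planted_markers
  cluster_rows <- list(); marker_tables <- list(); cancer_sets <- list()
  full_fc <- list()
  for (p in patients) {
    ids <- names(ds$patient_id)[ds$patient_id == p]
    sub <- subset_spots(ds, ids)
    norm <- normalize_log(sub)
    hvg <- select_hvg(norm, config$hvg)
    z <- autoscale(norm[, hvg, drop = FALSE])
    pc <- pca_reduce(z, min(config$n_pcs, min(dim(z)) - 1L))
    g <- knn_graph(pc$scores, k = config$knn)
    cl <- louvain_cluster(g, resolution = config$resolution,
                          seed = derive_seed(config$seed, 1000L + match(p, patients)))
    ann <- annotate_clusters(norm, cl$labels[rownames(norm)], panels)
    lab_map <- setNames(ann$type, ann$cluster)
    cluster_rows[[p]] <- data.frame(
      spot_id = rownames(norm), cluster = cl$labels[rownames(norm)],
      annotation = unname(lab_map[as.character(cl$labels[rownames(norm)])]),
      patient_id = p, stringsAsFactors = FALSE)
    cancer_cl <- ann$cluster[ann$type == "cancer" & ann$purity != "ambiguous"]
    if (length(cancer_cl)) {
      merged <- ifelse(cl$labels[rownames(norm)] %in% cancer_cl, "cancer", "rest")
      mt <- rank_markers(norm, merged, "cancer")
      marker_tables[[p]] <- mt
      cancer_sets[[p]] <- head(mt$gene, config$top_n_similarity)
      full_fc[[p]] <- group_log2fc(norm, merged, "cancer")
    }
    log("cluster", "%s: %d clusters, modularity %.3f", p,
        length(unique(cl$labels)), cl$modularity)
  }
  clusters_df <- do.call(rbind, cluster_rows)
  write_tsv(clusters_df, file.path(out_dir, "clusters.tsv"))

  meta <- NULL
  if (length(marker_tables) >= 2) {
    log("meta", "%d patients with cancer marker tables", length(marker_tables))
    meta <- intersect_markers(marker_tables, top_n = config$top_n)
    write_tsv(meta$exclusive, file.path(out_dir, "upset_counts.tsv"))
    J <- jaccard_matrix(cancer_sets)
    write_tsv(as.data.frame(J), file.path(out_dir, "jaccard.tsv"))
    rp <- rank_product(full_fc)
    write_tsv(rp, file.path(out_dir, "rankmeta.tsv"))
  }

  # subtype cancer spots per patient using the planted signature
  log("subtype", "tau %.2f", config$tau)
  cancer_spots <- names(truth$spot_dominant_type)[
    truth$spot_dominant_type == "cancer"]
  cancer_spots <- intersect(cancer_spots, rownames(ds$counts))
  can <- subset_spots(ds, cancer_spots)
  norm_can <- normalize_log(can)
  sig <- truth$planted_signatures
  sc <- signature_scores(norm_can, sig, can$patient_id)
  dend <- if (nrow(sc) >= 2)
    cluster_units(signature_matrix(norm_can, sig, can$patient_id)) else NULL
  calls <- call_subtypes(dend, sc, tau = config$tau)
  write_tsv(calls, file.path(out_dir, "subtype_calls.tsv"))

  # pseudobulk DGEA basal vs classical + sigmoid pathway map + GSEA
  pb <- pseudobulk(can$counts, can$patient_id)
  basal_u <- calls$unit[calls$label == "basal"]
  classical_u <- calls$unit[calls$label == "classical"]
  dg <- NULL; gsea <- NULL
  if (length(basal_u) >= 2 && length(classical_u) >= 2) {
    dg <- dgea(pb, classical_u, basal_u)
    write_tsv(dg, file.path(out_dir, "dgea.tsv"))
    write_tsv(data.frame(gene = dg$gene, scaled = sigmoid_scale(dg$log2fc)),
              file.path(out_dir, "pathway_map.tsv"))
    sets <- c(truth$planted_markers["cancer"], sig)
    gsea <- preranked_gsea(setNames(dg$t, dg$gene), sets,
                           min_size = config$min_set, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 5L))
    write_tsv(gsea, file.path(out_dir, "gsea_results.tsv"))
  }

  # trajectory over cancer spots
  log("trajectory", "k %d, %d components", config$k, config$ncomp)
  hvg_t <- select_hvg(norm_can, config$hvg)
  dmat <- spearman_distance(norm_can[, hvg_t, drop = FALSE])
  mds <- classical_mds(dmat, config$ncomp)
  traj <- infer_trajectory(mds, k = config$k,
                           seed = derive_seed(config$seed, 7L))
  traj <- orient_trajectory(traj, norm_can, sig)
  write_tsv(data.frame(spot_id = names(traj$pseudotime),
                       pseudotime = unname(traj$pseudotime),
                       mds1 = mds[, 1], mds2 = mds[, 2], mds3 = mds[, 3]),
            file.path(out_dir, "pseudotime.tsv"))

  # ligand-receptor test: planted fibroblast markers as ligands,
  # cancer markers as receptors
  log("interactions", "%d permutations", config$n_perm)
  lr_pairs <- data.frame(ligand = truth$planted_markers$fibroblast
                           %||% truth$planted_markers[[2]],
                         receptor = truth$planted_markers$cancer)
  types <- truth$spot_dominant_type[rownames(ds$counts)]
  inter <- lr_interaction_test(t(normalize_log(ds)), types, lr_pairs,
                               sender = "fibroblast", receiver = "cancer",
                               n_perm = config$n_perm, alpha = config$alpha,
                               mean_cutoff = config$mean_cutoff,
                               seed = derive_seed(config$seed, 11L))
  write_tsv(inter, file.path(out_dir, "interactions.tsv"))

  # multiplex niches
  log("niches", "gating + grade statistics")
  mx <- generate_multiplex_cells(config$multiplex)
  gated <- gate_cells(mx$cells)
  quant_markers <- setdiff(config$multiplex$markers, c("MUC1", "CollagenI"))
  niches <- grade_group_stats(gated, quant_markers, alpha = config$alpha)
  write_tsv(niches$pairwise, file.path(out_dir, "grade_stats.tsv"))

  # bulk survival
  log("survival", "bulk cohort")
  bk <- generate_bulk_cohort(config$bulk)
  tm <- tmm_normalize(bk$cohort$counts)
  bsc <- signature_scores(log2(tm$cpm + 1), bk$truth$planted_signatures,
                          rownames(bk$cohort$counts))
  bdend <- cluster_units(signature_matrix(log2(tm$cpm + 1),
                                          bk$truth$planted_signatures,
                                          rownames(bk$cohort$counts)))
  bcalls <- call_subtypes(bdend, bsc, tau = config$tau)
  # units with low signature expression are excluded from survival
  keep <- bcalls$unit[pmax(bcalls$classical, bcalls$basal) >= 0 |
                        bcalls$label == "mixed"]
  surv_df <- data.frame(sample = keep,
                        time = bk$cohort$survival_time[keep],
                        event = bk$cohort$event[keep],
                        group = bcalls$label[match(keep, bcalls$unit)])
  gbw <- if (length(unique(surv_df$group)) >= 2)
    gehan_breslow_wilcoxon(surv_df$time, surv_df$event, surv_df$group) else NULL
  write_tsv(surv_df, file.path(out_dir, "survival.tsv"))

  files <- list.files(out_dir, recursive = TRUE)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, truth = truth, clusters = clusters_df,
                 meta = meta, subtype_calls = calls, dgea = dg, gsea = gsea,
                 trajectory = traj, interactions = inter, niches = niches,
                 survival = surv_df, gbw = gbw, manifest = manifest))
}
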