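# nicheatlas

Spatial transcriptomics of pancreatic ductal adenocarcinoma (PDAC) reads
each 55 µm capture spot as a mixture of several overlapping cells, so
resolving the tumor's cell types, its basal/classical subtype structure,
and its metabolically active niches takes a chain of statistics rather
than a single tool. `nicheatlas` packages that chain for R users working
with multi-patient spot cohorts:

* **Spot pipeline** — QC (< 200 detected genes removed), library-size +
  log1p normalization, dispersion-ranked highly variable genes,
  auto-scaling, PCA (30 components), kNN graph (k = 10), Louvain
  clustering (resolution 0.8), canonical-marker cluster annotation with
  pure/mixed/ambiguous calls.
* **Marker meta-analysis** — one-vs-rest Wilcoxon marker tables; exclusive
  intersection (UpSet) counts and congruent markers across patients;
  pairwise Jaccard similarity J(A,B) = |A∩B|/|A∪B| with similarity PCA; a
  penalized rank product in which a gene absent from any comparison
  receives rank 1, so only consistently up-regulated genes reach the top
  of the meta-order.
* **Subtyping** — TMM normalization, cluster-averaged auto-scaled
  signature scores, Euclidean/complete hierarchical clustering with
  bootstrap clade support (10,000 / 0.95), automated
  basal / classical / mixed calls (mixed when the score gap < 0.5),
  pseudobulk differential expression with a variance-shrunk Welch t, and
  the pathway-mapping transform f(A) = −0.5 + 1/(1 + e^(−10A)) bounding
  scaled fold changes to (−0.5, 0.5).
* **Trajectory** — Spearman-distance MDS (3 components), k-means (k = 4)
  principal-curve pseudotime oriented so the classical program is early,
  and tricube moving-average (LOESS-style, span 0.75) marker kinetics.
* **Enrichment & interactions** — preranked GSEA (weighted running sum,
  minimum set size 5, permutation NES/p), per-sample gene-set scores, and
  a directional ligand–receptor permutation test (1,000 label shuffles;
  retained when mean interaction > 0.5 and p < 0.05).
* **Niche & survival statistics** — intensity gating (defaults MUC1 > 50 ∧
  Collagen I < 500), reference-median normalization, Kruskal–Wallis +
  Dunn post-hoc with two-stage step-up (Benjamini–Krieger–Yekutieli) FDR,
  Spearman strength classes (0.3 / 0.5), Kaplan–Meier curves and the
  Gehan–Breslow–Wilcoxon weighted log-rank test.
* **Synthetic cohorts** — seeded generators for spot cohorts (Voronoi
  tissue patches, Dirichlet spot mixtures, planted congruent markers, a
  latent classical→basal continuum, negative-binomial counts), multiplex
  cell tables with grade-monotone intensity shifts, and bulk cohorts with
  subtype-dependent survival — every downstream stage has a planted,
  recoverable answer.

`run_pipeline()` chains all stages on a synthetic cohort and writes TSV/JSON
artifacts with a checksum manifest; `write_fixture()` / `read_fixture()`
round-trip cohorts through MatrixMarket + TSV + GMT + JSON.

## Worked example

```r
library(nicheatlas)

sim <- generate_cohort(cohort_config(seed = 0L))
ds  <- filter_spots(sim$dataset)          # QC: < 200 detected genes removed
ds
#> spot_dataset: 2400 spots x 1200 genes, 6 patients

# per-patient cancer markers, then the all-patient top-50 intersection
tabs <- list()
for (p in unique(ds$patient_id)) {
  ids  <- names(ds$patient_id)[ds$patient_id == p]
  norm <- normalize_log(subset_spots(ds, ids))
  type <- ifelse(sim$truth$spot_dominant_type[ids] == "cancer", "cancer", "rest")
  tabs[[p]] <- rank_markers(norm, type, "cancer")
}
rep50 <- intersect_markers(tabs, top_n = 50)
length(rep50$congruent)                                    # congruent markers
#> [1] 11
mean(sim$truth$planted_markers$cancer %in% rep50$congruent) # planted recall
#> [1] 1

# classical -> basal pseudotime over 800 cancer spots
cancer <- names(sim$truth$spot_dominant_type)[
  sim$truth$spot_dominant_type == "cancer"]
set.seed(0); cancer <- sort(sample(intersect(cancer, rownames(ds$counts)), 800))
norm <- normalize_log(subset_spots(ds, cancer))
mds  <- classical_mds(spearman_distance(norm[, select_hvg(norm, 2000)]), 3)
traj <- orient_trajectory(infer_trajectory(mds, k = 4, seed = 0),
                          norm, sim$truth$planted_signatures)
cor(traj$pseudotime[cancer], sim$truth$latent_t[cancer], method = "spearman")
#> [1] 0.9669816

sigmoid_scale(c(-1, 0, 0.2, 1))   # pathway-map fold-change compression
#> [1] -0.5000  0.0000  0.3808  0.5000
```

All 10 planted pan-patient cancer markers are recovered in the top-50
intersection across all six synthetic patients (11 congruent genes in
total — the extra one is a genuinely cancer-enriched program gene), and the
inferred pseudotime tracks the planted continuum at ρ ≈ 0.97. The sigmoid
compresses log fold changes into the (−0.5, 0.5) color scale used for
pathway maps.

See `vignettes/nicheatlas-methods.Rmd` for the models, parameter defaults,
numerical choices, and what the synthetic cohorts do and do not emulate.

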